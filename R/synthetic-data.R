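#' Configuration for a synthetic longitudinal connectome study
#'
#' Defines the simulated study design: two groups followed over three
#' timepoints on a 90-node parcellation, with a group-specific nodal deficit
#' that partially — never completely — recovers over follow-up, and
#' functional matrices built to couple with the structural substrate at a
#' tunable strength.
#'
#' Defaults mirror the design the analysis is built for: 21 patients vs 17
#' controls, timepoints baseline / 1-month / 6-month, a deficit halving the
#' weight of edges incident to 5 affected nodes at baseline, with 50% of the
#' deficit removed at 1 month and 80% at 6 months.
#'
#' @param n_nodes Number of parcellation nodes.
#' @param n_patients,n_controls Group sizes.
#' @param timepoints Three ordered timepoint labels.
#' @param n_affected Number of deficit nodes (drawn reproducibly from `seed`
#'   unless `affected_nodes` is given).
#' @param affected_nodes Optional explicit node indices.
#' @param deficit_scale Multiplier in (0, 1] applied at baseline to patient
#'   edges incident to affected nodes (1 = no deficit).
#' @param recovery_fractions Length-2 vector: fraction of the deficit removed
#'   at the second and third timepoint; nondecreasing, both < 1.
#' @param coupling_strength Share of the functional signal carried by the
#'   (rank-Gaussianised) structural weights, in \[0, 1\].
#' @param subject_noise_sd,measurement_noise_sd Log-scale SDs of the
#'   per-subject (stable across timepoints) and per-scan lognormal edge
#'   noise on structural weights.
#' @param sc_density Connection density of the structural substrate.
#' @param rewire_frac Fraction of substrate edges passed through
#'   degree-preserving swaps (small-world shortcut creation).
#' @param seed Integer seed; every draw in the study derives from it.
#' @return A validated list of class `lc_sim_config`.
#' @export
simulation_config <- function(n_nodes = 90, n_patients = 21, n_controls = 17,
                              timepoints = c("baseline", "1-month", "6-month"),
                              n_affected = 5, affected_nodes = NULL,
                              deficit_scale = 0.5,
                              recovery_fractions = c(0.5, 0.8),
                              coupling_strength = 0.6,
                              subject_noise_sd = 0.25,
                              measurement_noise_sd = 0.1,
                              sc_density = 0.15, rewire_frac = 0.1, seed) {
  if (missing(seed)) abort("`seed` is required.")
  stopifnot(n_nodes >= 4, n_patients >= 2, n_controls >= 2,
            length(timepoints) == 3,
            deficit_scale > 0, deficit_scale <= 1,
            coupling_strength >= 0, coupling_strength <= 1,
            sc_density > 0, sc_density <= 1)
  if (!(length(recovery_fractions) == 2 &&
        recovery_fractions[1] >= 0 &&
        recovery_fractions[2] >= recovery_fractions[1] &&
        recovery_fractions[2] < 1)) {
    abort("`recovery_fractions` must satisfy 0 <= r1 <= r2 < 1 (incomplete recovery).")
  }
  if (!is.null(affected_nodes)) {
    stopifnot(all(affected_nodes >= 1), all(affected_nodes <= n_nodes))
    n_affected <- length(affected_nodes)
  }
  structure(list(n_nodes = n_nodes, n_patients = n_patients,
                 n_controls = n_controls, timepoints = timepoints,
                 n_affected = n_affected, affected_nodes = affected_nodes,
                 deficit_scale = deficit_scale,
                 recovery_fractions = recovery_fractions,
                 coupling_strength = coupling_strength,
                 subject_noise_sd = subject_noise_sd,
                 measurement_noise_sd = measurement_noise_sd,
                 sc_density = sc_density, rewire_frac = rewire_frac,
                 seed = as.integer(seed)),
            class = "lc_sim_config")
}

# Deterministic sub-seed for (subject, timepoint) draws; kept below 2^31.
subseed <- function(seed, i, t = 0L) {
  as.integer((as.numeric(seed) + 1000003 * i + 7919 * t) %% 2147483629)
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Generate a small-world weighted substrate network
#'
#' Ring-lattice construction at an exact edge count (`round(density *
#' N(N-1)/2)`): node pairs are added in order of circular distance, the last
#' partially-filled distance ring being spread evenly around the ring. A
#' fraction of edges is then passed through degree-preserving double-edge
#' swaps — creating the long-range shortcuts of a small-world topology while
#' keeping the lattice's high clustering and exact degree sequence. Weights
#' are lognormal, assigned in a seed-determined random order.
#'
#' @param n_nodes Number of nodes.
#' @param density Connection density in (0, 1].
#' @param seed Integer seed (full determinism).
#' @param rewire_frac Fraction of edges to swap.
#' @param weight_sdlog Log-scale SD of the lognormal edge weights.
#' @return A [weighted_network()].
#' @export
generate_base_connectome <- function(n_nodes, density, seed, rewire_frac = 0.1,
                                     weight_sdlog = 0.5) {
  n <- n_nodes
  n_pairs <- n * (n - 1) / 2
  E <- round_half_up(density * n_pairs)
  if (E < 1 || E > n_pairs) abort("Infeasible density.")
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)

  edges <- matrix(integer(0), ncol = 2)
  d <- 1
  while (nrow(edges) < E) {
    if (d > floor(n / 2)) abort("Infeasible density for ring construction.")
    ring <- if (2 * d == n) {
      cbind(seq_len(n / 2), seq_len(n / 2) + d)
    } else {
      i <- seq_len(n)
      j <- ((i + d - 1) %% n) + 1
      cbind(pmin(i, j), pmax(i, j))
    }
    need <- E - nrow(edges)
    if (nrow(ring) <= need) {
      edges <- rbind(edges, ring)
    } else {
      # spread the partial ring evenly around the circle so the extra
      # degree is not clustered on low node indices
      pick <- unique(round(seq(1, nrow(ring), length.out = need)))
      edges <- rbind(edges, ring[pick, , drop = FALSE])
    }
    d <- d + 1
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  n_swaps <- round(rewire_frac * E)
  if (n_swaps > 0) {
    g <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
  }
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  idx <- which(upper.tri(a) & a > 0)
  w <- matrix(0, n, n)
  w[idx] <- rlnorm(length(idx), meanlog = 0, sdlog = weight_sdlog)
  w <- w + t(w)
  weighted_network(w, validate = FALSE)
}

#' Generate one subject's paired SC/FC matrices
#'
#' Structural weights are the substrate's weights under multiplicative
#' lognormal subject noise (drawn once per subject, stable across
#' timepoints) and scan noise (per subject-timepoint). For patients, edges
#' incident to the affected nodes are additionally multiplied by the
#' deficit factor `deficit_scale + (1 - deficit_scale) * recovery(t)` —
#' the deficit at baseline, linearly released at follow-ups, never fully.
#'
#' Functional edge values mix the rank-Gaussianised structural weights with
#' independent Gaussian noise in proportion `coupling_strength : (1 -
#' coupling_strength)`; node pairs without a direct structural connection
#' mix, in the same proportion, the rank-Gaussianised two-step structural
#' path strength — indirect anatomical routes support organised functional
#' connectivity there. The whole functional matrix is linearly rescaled
#' into (-1, 1), which leaves every correlation-based quantity untouched.
#'
#' @param base Substrate [weighted_network()] from [generate_base_connectome()].
#' @param config An [simulation_config()].
#' @param subject_index Integer, unique per subject within the study.
#' @param subject_id,group Identifiers (`group` is `"patient"` or `"control"`).
#' @param timepoint_index Integer 1..3.
#' @return List with elements `sc` and `fc` ([connectivity_matrix()] objects).
#' @export
generate_subject_matrices <- function(base, config, subject_index, subject_id,
                                      group, timepoint_index) {
  stopifnot(inherits(config, "lc_sim_config"),
            timepoint_index %in% 1:3, group %in% c("patient", "control"))
  n <- n_nodes(base)
  ut <- which(upper.tri(base$weights))
  base_v <- base$weights[ut]
  on_edge <- base_v > 0
  E <- sum(on_edge)
  affected <- config$affected_nodes
  tp <- config$timepoints[timepoint_index]

  restore <- local_seed(subseed(config$seed, subject_index, 0L))
  subj_mult <- exp(rnorm(E, 0, config$subject_noise_sd))
  restore()
  restore2 <- local_seed(subseed(config$seed, subject_index, timepoint_index))
  on.exit(restore2(), add = TRUE)
  meas_mult <- exp(rnorm(E, 0, config$measurement_noise_sd))

  sc_v <- base_v[on_edge] * subj_mult * meas_mult
  if (group == "patient" && length(affected) > 0) {
    recovery <- c(0, config$recovery_fractions)[timepoint_index]
    mult <- config$deficit_scale + (1 - config$deficit_scale) * recovery
    rows <- row(base$weights)[ut][on_edge]
    cols <- col(base$weights)[ut][on_edge]
    hit <- rows %in% affected | cols %in% affected
    sc_v[hit] <- sc_v[hit] * mult
  }
  sc <- matrix(0, n, n)
  sc[ut[on_edge]] <- sc_v
  sc <- sc + t(sc)

  z <- gaussian_resample(sc_v)
  cs <- config$coupling_strength
  mix <- numeric(length(ut))
  mix[on_edge] <- cs * z + (1 - cs) * rnorm(E)
  # node pairs without a direct structural edge still show organised
  # functional connectivity through indirect (two-step) structural paths;
  # this stable backbone is shared by all subjects, the rest is scan noise
  two_step <- (base$weights %*% base$weights)[ut][!on_edge]
  h <- if (length(unique(two_step)) > 2) gaussian_resample(two_step)
       else rep(0, length(two_step))
  mix[!on_edge] <- cs * h + (1 - cs) * rnorm(sum(!on_edge))
  s <- min(1, 0.95 / max(abs(mix)))
  fc <- matrix(0, n, n)
  fc[ut] <- mix * s
  fc <- fc + t(fc)

  list(sc = connectivity_matrix(sc, "structural", subject_id, group, tp),
       fc = connectivity_matrix(fc, "functional", subject_id, group, tp))
}

#' Generate a complete synthetic longitudinal study
#'
#' Builds the full study container: paired functional and structural
#' matrices for every subject at every timepoint, demographic covariates
#' (age, sex, education), and a hemoglobin-like clinical variable that is
#' depressed in patients at baseline and rises over follow-up — giving the
#' change-score analysis something real to find. All randomness derives
#' from `config$seed`; the same config reproduces the study bit for bit.
#'
#' @param config An [simulation_config()].
#' @return Object of class `lc_study`: `manifest` (tibble), `matrices`
#'   (named list of [connectivity_matrix()]), `subjects` (covariate tibble),
#'   `clinical` (long tibble with `hemoglobin`), `base` (the substrate),
#'   `ground_truth` (config + realized affected nodes).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "lc_sim_config"))
  if (is.null(config$affected_nodes)) {
    restore <- local_seed(subseed(config$seed, 0L, 1L))
    config$affected_nodes <- sort(sample.int(config$n_nodes, config$n_affected))
    restore()
  }
  base <- generate_base_connectome(config$n_nodes, config$sc_density,
                                   seed = subseed(config$seed, 0L, 2L),
                                   rewire_frac = config$rewire_frac)
  ids <- c(sprintf("pat%02d", seq_len(config$n_patients)),
           sprintf("ctl%02d", seq_len(config$n_controls)))
  groups <- rep(c("patient", "control"), c(config$n_patients, config$n_controls))
  ns <- length(ids)

  restore <- local_seed(subseed(config$seed, 0L, 3L))
  subjects <- tibble::tibble(
    subject_id = ids, group = groups,
    age = round(rnorm(ns, 35, 8), 1),
    sex = ifelse(rbinom(ns, 1, 0.5) == 1, "male", "female"),
    education = round(pmax(rnorm(ns, 12, 3), 3))
  )
  # hemoglobin-like covariate (g/L): anaemic at baseline in patients,
  # rising toward (but not always reaching) the control level
  hb_mean <- rbind(patient = c(95, 125, 135), control = c(140, 140, 140))
  clinical <- tidyr::expand_grid(subject_id = ids,
                                 timepoint = config$timepoints) |>
    dplyr::left_join(subjects[, c("subject_id", "group")], by = "subject_id")
  tp_idx <- match(clinical$timepoint, config$timepoints)
  clinical$hemoglobin <- round(
    hb_mean[cbind(match(clinical$group, rownames(hb_mean)), tp_idx)] +
      rnorm(nrow(clinical), 0, 6), 1)
  restore()

  matrices <- list()
  rows <- list()
  for (i in seq_len(ns)) {
    for (t in 1:3) {
      mats <- generate_subject_matrices(base, config, i, ids[i], groups[i], t)
      tp <- config$timepoints[t]
      key_sc <- paste(ids[i], tp, "structural", sep = "_")
      key_fc <- paste(ids[i], tp, "functional", sep = "_")
      matrices[[key_sc]] <- mats$sc
      matrices[[key_fc]] <- mats$fc
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = ids[i], group = groups[i], timepoint = tp,
        modality = c("structural", "functional"), key = c(key_sc, key_fc))
    }
  }
  structure(list(manifest = dplyr::bind_rows(rows), matrices = matrices,
                 subjects = subjects, clinical = clinical, base = base,
                 ground_truth = list(config = config,
                                     affected_nodes = config$affected_nodes)),
            class = "lc_study")
}

#' @export
print.lc_study <- function(x, ...) {
  cfg <- x$ground_truth$config
  cat(sprintf(paste0("<lc_study: %d patients + %d controls x %d timepoints, ",
                     "%d nodes, %d matrices>\n"),
              cfg$n_patients, cfg$n_controls, length(cfg$timepoints),
              cfg$n_nodes, length(x$matrices)))
  invisible(x)
}
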