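#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis. Density grids default to
#' the conventional per-modality ranges; the pipeline evaluates the grid you
#' give it, so pass a coarser grid for quick runs and the full
#' [default_density_grid()] for a complete sweep.
#'
#' @param manifest Path to a manifest file (see [read_manifest()]), or `NULL`
#'   when a study object is passed to [run_pipeline()] directly.
#' @param out_dir Output directory for result tables.
#' @param densities_functional,densities_structural Density grids per modality.
#' @param reference_density Density at which per-subject global metrics are
#'   computed for the reproducibility stage.
#' @param family_size Family size for the false-positive adjustment of nodal
#'   tests (defaults to the node count at run time when `NULL`).
#' @param n_perm Permutations for split-half metric comparisons.
#' @param seed Integer seed for every stochastic stage.
#' @return List of class `lc_run_config`.
#' @export
run_config <- function(manifest = NULL, out_dir,
                       densities_functional = c(0.05, 0.10, 0.15, 0.20),
                       densities_structural = c(0.05, 0.10, 0.15),
                       reference_density = 0.10, family_size = NULL,
                       n_perm = 10000, seed) {
  if (missing(seed)) abort("`seed` is required.")
  stopifnot(all(densities_functional > 0), all(densities_functional <= 1),
            all(densities_structural > 0), all(densities_structural <= 1))
  structure(list(manifest = manifest, out_dir = out_dir,
                 densities_functional = densities_functional,
                 densities_structural = densities_structural,
                 reference_density = reference_density,
                 family_size = family_size, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "lc_run_config")
}

metrics_one <- function(cm, densities) {
  purrr::map_dfr(densities, function(d) {
    tn <- threshold_to_density(cm, d)
    met <- network_metrics(tn$net)
    nodal_long <- tidyr::pivot_longer(met$nodal, -"node",
                                      names_to = "metric", values_to = "value")
    global_long <- tidyr::pivot_longer(met$global, dplyr::everything(),
                                       names_to = "metric", values_to = "value")
    global_long$node <- NA_character_
    dplyr::bind_rows(nodal_long, global_long) |>
      dplyr::mutate(subject_id = cm$subject_id, group = cm$group,
                    timepoint = cm$timepoint, modality = cm$modality,
                    density = d, .before = 1)
  })
}

#' Long-format topology metrics for every matrix of a study
#'
#' Thresholds each subject's matrix across its modality's density grid and
#' computes all nodal and global metrics, returning the canonical long table
#' (subject, group, timepoint, modality, density, node, metric, value);
#' global metrics carry `NA` in the node column.
#'
#' @param study An `lc_study`.
#' @param densities_functional,densities_structural Density grids.
#' @return Tibble.
#' @export
study_metrics <- function(study,
                          densities_functional = c(0.05, 0.10, 0.15, 0.20),
                          densities_structural = c(0.05, 0.10, 0.15)) {
  purrr::map_dfr(study$matrices, function(cm) {
    d <- if (cm$modality == "functional") densities_functional
         else densities_structural
    metrics_one(cm, d)
  })
}

#' Average metrics across the density sweep
#'
#' The area-under-curve summary: each subject's metric averaged over the
#' density grid, removing the arbitrary choice of a single density.
#'
#' @param metrics Long table from [study_metrics()].
#' @return Tibble with one row per subject x modality x node x metric.
#' @export
metric_auc <- function(metrics) {
  metrics |>
    dplyr::group_by(.data$subject_id, .data$group, .data$timepoint,
                    .data$modality, .data$node, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

anova_by_node <- function(auc, which_metrics, alpha) {
  auc |>
    dplyr::filter(.data$metric %in% which_metrics) |>
    dplyr::group_by(.data$modality, .data$metric, .data$node) |>
    dplyr::group_modify(function(d, key) {
      tryCatch({
        fit <- rm_anova(d, value, subject_id, group, timepoint)
        tidy(fit)[, c("term", "statistic", "df", "df.error", "p.value")]
      }, longconn_zero_variance = function(e) {
        # e.g. a node whose betweenness is zero for every subject
        tibble::tibble(term = c("group", "time", "group:time"),
                       statistic = NA_real_, df = NA_real_,
                       df.error = NA_real_, p.value = NA_real_)
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant_after_adjustment = .data$p.value < alpha)
}

#' Run the full longitudinal connectome pipeline
#'
#' Executes the stages in order — construct/load, threshold sweep, topology
#' metrics, FC-SC coupling, group x time inference with the false-positive
#' adjustment, and split-half reproducibility — and writes one long-format
#' CSV per stage plus a structured `run_summary.json` carrying the seed and
#' a hash of the configuration. Reruns with the same inputs and config
#' produce byte-identical tables.
#'
#' Stages that need inputs the study does not carry (covariates for the
#' split-half matching, clinical variables for change scores) are recorded
#' as skipped in the run summary; subjects are never silently dropped.
#'
#' @param config An [run_config()].
#' @param study Optional `lc_study` (from [generate_study()] or
#'   [read_study()]); when `NULL`, `config$manifest` is loaded.
#' @return Invisibly, a list of the result tables; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, study = NULL) {
  stopifnot(inherits(config, "lc_run_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  if (is.null(study)) {
    if (is.null(config$manifest)) abort("Either `study` or `config$manifest` is required.")
    study <- read_study(config$manifest)
    say("loaded study from %s", config$manifest)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  n_nodes <- nrow(study$matrices[[1]]$weights)
  family <- if (is.null(config$family_size)) n_nodes else config$family_size
  alpha <- false_positive_adjust(family)
  say("metrics stage: %d matrices", length(study$matrices))

  metrics <- study_metrics(study, config$densities_functional,
                           config$densities_structural)
  auc <- metric_auc(metrics)
  coupling <- coupling_table(study$matrices)
  say("coupling stage: %d scores", nrow(coupling))

  anova_tbl <- anova_by_node(
    auc, c("degree", "efficiency", "betweenness_norm",
           "strength", "char_path_length", "clustering"), alpha)
  coup_fit <- rm_anova(coupling, r, subject_id, group, timepoint)
  coup_tbl <- tidy(coup_fit) |>
    dplyr::mutate(modality = "coupling", metric = "r", node = NA_character_,
                  significant_after_adjustment = .data$p.value < 0.05,
                  .before = 1)
  say("stats stage: %d nodal/global tests at alpha %.4g", nrow(anova_tbl), alpha)

  # post hoc for nodal tests whose group or interaction effect crossed alpha
  flagged <- anova_tbl |>
    dplyr::filter(!is.na(.data$node), .data$term != "time",
                  .data$p.value < alpha) |>
    dplyr::distinct(.data$modality, .data$metric, .data$node)
  posthoc <- purrr::pmap_dfr(flagged, function(modality, metric, node) {
    d <- auc[auc$modality == modality & auc$metric == metric &
               (!is.na(auc$node) & auc$node == node), ]
    posthoc_tests(d, value, subject_id, group, timepoint) |>
      dplyr::mutate(modality = modality, metric = metric, node = node,
                    .before = 1)
  })
  say("posthoc stage: %d flagged node-metrics", nrow(flagged))

  repro <- NULL
  if (!is.null(study$subjects) &&
      all(c("age", "sex", "education") %in% names(study$subjects))) {
    ref_global <- metrics |>
      dplyr::filter(is.na(.data$node), .data$modality == "functional",
                    abs(.data$density - config$reference_density) < 1e-9,
                    .data$metric %in% c("strength", "char_path_length")) |>
      tidyr::pivot_wider(names_from = "metric", values_from = "value")
    cohorts <- dplyr::distinct(study$manifest, .data$group, .data$timepoint)
    repro <- purrr::pmap_dfr(cohorts, function(group, timepoint) {
      keys <- study$manifest[study$manifest$group == group &
                               study$manifest$timepoint == timepoint, ]
      subj <- study$subjects[study$subjects$subject_id %in% keys$subject_id, ]
      tryCatch(
        splithalf_report(
          subj,
          study$matrices[keys$key[keys$modality == "functional"]],
          study$matrices[keys$key[keys$modality == "structural"]],
          ref_global[ref_global$group == group &
                       ref_global$timepoint == timepoint, ],
          seed = config$seed + match(timepoint, unique(cohorts$timepoint)) +
            10L * match(group, unique(cohorts$group)),
          n_perm = config$n_perm) |>
          dplyr::mutate(group = group, timepoint = timepoint, .before = 1) |>
          dplyr::select(-"balance"),
        error = function(e) {
          say("split-half skipped for %s/%s: %s", group, timepoint,
              conditionMessage(e))
          NULL
        })
    })
    say("reproducibility stage: %d cohort splits", nrow(repro))
  } else {
    say("reproducibility stage skipped: no covariates (age/sex/education)")
  }

  changes <- NULL
  if (!is.null(study$clinical)) {
    clin_vars <- setdiff(names(study$clinical),
                         c("subject_id", "group", "timepoint"))
    pat <- coupling[coupling$group == "patient", ] |>
      dplyr::inner_join(study$clinical, by = c("subject_id", "timepoint"))
    tps <- unique(study$manifest$timepoint)
    intervals <- list(c(tps[1], tps[2]), c(tps[1], tps[3]))
    changes <- purrr::map_dfr(intervals, function(iv) {
      purrr::map_dfr(clin_vars, function(v) {
        change_score_correlation(pat, r, .data[[v]], iv[1], iv[2],
                                 subject_id, timepoint) |>
          dplyr::mutate(variable = v, from = iv[1], to = iv[2], .before = 1)
      })
    })
    say("change-score stage: %d correlations", nrow(changes))
  } else {
    say("change-score stage skipped: no clinical table")
  }

  out <- function(x, f) {
    if (!is.null(x)) readr::write_csv(x, file.path(config$out_dir, f))
  }
  out(metrics, "nodal_and_global_metrics.csv")
  out(auc, "metric_auc.csv")
  out(coupling, "coupling.csv")
  out(dplyr::bind_rows(anova_tbl, coup_tbl), "anova.csv")
  out(posthoc, "posthoc.csv")
  out(repro, "reproducibility.csv")
  out(changes, "change_correlations.csv")
  cfg_core <- config[setdiff(names(config), c("out_dir", "manifest"))]
  summary <- list(seed = config$seed,
                  config_hash = rlang::hash(cfg_core),
                  n_matrices = length(study$matrices),
                  n_nodes = n_nodes, family_size = family,
                  alpha = alpha, stages = log)
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(metrics = metrics, auc = auc, coupling = coupling,
                 anova = dplyr::bind_rows(anova_tbl, coup_tbl),
                 posthoc = posthoc, reproducibility = repro,
                 change_correlations = changes, summary = summary))
}
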