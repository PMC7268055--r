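#' Split a cohort into two covariate-matched halves
#'
#' Random halving of the cohort, re-drawn until the halves are matched on
#' the given covariates: continuous covariates (age, education) by
#' two-sample t-test, categorical ones (sex) by chi-square or, when any
#' expected cell count is small, Fisher's exact test — all required to give
#' p > `alpha`. Subgroup sizes differ by at most one.
#'
#' @param subjects Data frame with a `subject_id` column and the covariate
#'   columns.
#' @param continuous,categorical Character vectors naming covariate columns.
#' @param seed Integer seed; the accepted split is deterministic given it.
#' @param max_tries Give up (with an error) after this many draws.
#' @param alpha Balance threshold (default 0.05).
#' @return List of class `lc_split`: `members_a`, `members_b` (subject ids),
#'   `balance` (tibble: covariate, p), `n_tries`.
#' @export
split_cohort <- function(subjects, continuous = c("age", "education"),
                         categorical = "sex", seed, max_tries = 1000,
                         alpha = 0.05) {
  stopifnot(is.data.frame(subjects), "subject_id" %in% names(subjects))
  n <- nrow(subjects)
  if (n < 4) abort("Need at least 4 subjects to split.")
  if (missing(seed)) abort("`seed` is required.")
  covs <- c(continuous, categorical)
  miss <- setdiff(covs, names(subjects))
  if (length(miss) > 0) {
    abort(paste0("Missing covariate columns: ", paste(miss, collapse = ", ")))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  na <- ceiling(n / 2)
  for (try in seq_len(max_tries)) {
    ia <- sample.int(n, na)
    bal <- purrr::map_dbl(covs, function(cv) {
      xa <- subjects[[cv]][ia]; xb <- subjects[[cv]][-ia]
      if (cv %in% categorical) {
        tab <- table(factor(c(xa, xb))[seq_len(n)],
                     rep(c("a", "b"), c(na, n - na)))
        if (nrow(tab) < 2) return(1)
        suppressWarnings(exp_small <- any(chisq.test(tab)$expected < 5))
        if (exp_small) fisher.test(tab)$p.value
        else suppressWarnings(chisq.test(tab)$p.value)
      } else {
        if (sd(c(xa, xb)) == 0) return(1)
        if (sd(xa) == 0 && sd(xb) == 0) return(if (mean(xa) == mean(xb)) 1 else 0)
        t.test(xa, xb)$p.value
      }
    })
    if (all(bal > alpha)) {
      return(structure(list(
        members_a = subjects$subject_id[ia],
        members_b = subjects$subject_id[-ia],
        balance = tibble::tibble(covariate = covs, p = bal),
        n_tries = try), class = "lc_split"))
    }
  }
  abort(sprintf("No covariate-balanced split found in %d tries.", max_tries),
        class = "longconn_no_balanced_split")
}

#' @export
print.lc_split <- function(x, ...) {
  cat(sprintf("<cohort split: %d vs %d subjects, %d draw(s)>\n",
              length(x$members_a), length(x$members_b), x$n_tries))
  print(as.data.frame(x$balance), row.names = FALSE)
  invisible(x)
}

#' Edge-wise mean network of a set of connectivity matrices
#'
#' @param matrices List of [connectivity_matrix()] objects (one modality).
#' @return A [weighted_network()] of the element-wise mean; negative mean
#'   functional edges are clipped to zero for the network container.
#' @export
mean_network <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  w <- Reduce(`+`, purrr::map(matrices, "weights")) / length(matrices)
  weighted_network(pmax(w, 0), validate = FALSE)
}

#' Pattern correlation between two mean networks
#'
#' Pearson correlation between the upper-triangle weight vectors of two
#' networks on the same parcellation — the split-half agreement of mean
#' connectivity patterns.
#'
#' @param net_a,net_b [weighted_network()] objects with equal node count.
#' @return Pearson r.
#' @export
pattern_correlation <- function(net_a, net_b) {
  if (n_nodes(net_a) != n_nodes(net_b)) {
    abort("Node count mismatch.", class = "longconn_dim_mismatch")
  }
  va <- upper_tri_vector(net_a$weights)
  vb <- upper_tri_vector(net_b$weights)
  if (sd(va) == 0 || sd(vb) == 0) {
    abort("Zero-variance weight vector.", class = "longconn_zero_variance")
  }
  cor(va, vb)
}

#' Permutation comparison of a global metric between split halves
#'
#' @param split An [split_cohort()] result.
#' @param metric_values Named numeric vector of the per-subject global metric
#'   (names are subject ids).
#' @param n_perm,seed Passed to [permutation_test_group_metric()].
#' @param exact Passed through (default `"auto"`).
#' @return Two-sided permutation p value.
#' @export
subgroup_metric_comparison <- function(split, metric_values, n_perm = 10000,
                                       seed = NULL, exact = "auto") {
  stopifnot(inherits(split, "lc_split"))
  miss <- setdiff(c(split$members_a, split$members_b), names(metric_values))
  if (length(miss) > 0) {
    abort(paste0("Metric missing for subjects: ", paste(miss, collapse = ", ")))
  }
  permutation_test_group_metric(metric_values[split$members_a],
                                metric_values[split$members_b],
                                n_perm = n_perm, seed = seed, exact = exact)
}

#' Split-half reproducibility report for one cohort at one timepoint
#'
#' Runs the full split-half scheme: draw a covariate-matched halving,
#' correlate the halves' mean functional and structural connectivity
#' patterns, and permutation-test the per-subject global strength and
#' characteristic path length between halves.
#'
#' @param subjects Covariate data frame (see [split_cohort()]).
#' @param fc_matrices,sc_matrices Named lists of [connectivity_matrix()]
#'   objects for these subjects (names or `subject_id` fields must match).
#' @param global_metrics Data frame with columns `subject_id`, `strength`,
#'   `char_path_length` (per-subject global metrics at a reference density).
#' @param seed Integer seed driving both the split and the permutations.
#' @param n_perm Permutations for the metric comparisons.
#' @return One-row tibble: the split sizes, `r_functional`, `r_structural`,
#'   `p_strength`, `p_char_path_length`, and balance p values nested in a
#'   list column.
#' @export
splithalf_report <- function(subjects, fc_matrices, sc_matrices,
                             global_metrics, seed, n_perm = 10000) {
  split <- split_cohort(subjects, seed = seed)
  by_subject <- function(mats) {
    ids <- purrr::map_chr(mats, "subject_id")
    setNames(mats, ids)
  }
  fc <- by_subject(fc_matrices); sc <- by_subject(sc_matrices)
  r_fc <- pattern_correlation(mean_network(fc[split$members_a]),
                              mean_network(fc[split$members_b]))
  r_sc <- pattern_correlation(mean_network(sc[split$members_a]),
                              mean_network(sc[split$members_b]))
  gm <- global_metrics
  sv <- setNames(gm$strength, gm$subject_id)
  lv <- setNames(gm$char_path_length, gm$subject_id)
  p_s <- subgroup_metric_comparison(split, sv, n_perm = n_perm, seed = seed + 1L)
  p_l <- subgroup_metric_comparison(split, lv, n_perm = n_perm, seed = seed + 2L)
  tibble::tibble(n_a = length(split$members_a), n_b = length(split$members_b),
                 r_functional = r_fc, r_structural = r_sc,
                 p_strength = p_s, p_char_path_length = p_l,
                 balance = list(split$balance))
}
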