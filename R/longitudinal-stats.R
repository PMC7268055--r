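# Fast core of the mixed-design ANOVA. Y: subjects x timepoints matrix of a
# single metric (complete cases only); group: factor of length nrow(Y).
# Classical weighted-means (group-first) sums-of-squares decomposition; the
# within-subject design is complete, so the between-subject and
# within-subject strata decompose orthogonally and SS are additive.
rm_anova_core <- function(Y, group) {
  group <- droplevels(as.factor(group))
  S <- nrow(Y); Tt <- ncol(Y); G <- nlevels(group)
  stopifnot(S == length(group), Tt >= 2, G >= 2)
  ng <- tabulate(group)
  if (any(ng < 2)) abort("Need >= 2 subjects per group.")
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  time_means <- colMeans(Y)
  gmean <- tapply(subj_means, group, mean)
  cell <- apply(Y, 2, function(col) tapply(col, group, mean))  # G x T

  ss_group <- Tt * sum(ng * (gmean - grand)^2)
  ss_subj  <- Tt * sum((subj_means - gmean[group])^2)
  ss_time  <- S * sum((time_means - grand)^2)
  inter_dev <- cell - outer(gmean, rep(1, Tt)) -
    outer(rep(1, G), time_means) + grand
  ss_int <- sum(ng * rowSums(inter_dev^2))
  fitted_w <- cell[cbind(as.integer(group)[rep(seq_len(S), Tt)],
                         rep(seq_len(Tt), each = S))]
  ss_werr <- sum((as.vector(Y) - subj_means[rep(seq_len(S), Tt)] -
                    fitted_w + gmean[group][rep(seq_len(S), Tt)])^2)

  df_group <- G - 1; df_subj <- S - G
  df_time <- Tt - 1; df_int <- (G - 1) * (Tt - 1); df_werr <- (S - G) * (Tt - 1)
  ms_subj <- ss_subj / df_subj
  ms_werr <- ss_werr / df_werr
  if (ms_subj <= 0 || ms_werr <= 0) {
    abort("Zero error variance; F is undefined.", class = "longconn_zero_variance")
  }
  eff <- tibble::tibble(
    effect = c("group", "time", "group:time"),
    ss = c(ss_group, ss_time, ss_int),
    df = c(df_group, df_time, df_int),
    ss_error = c(ss_subj, ss_werr, ss_werr),
    df_error = c(df_subj, df_werr, df_werr)
  )
  eff$F <- (eff$ss / eff$df) / (eff$ss_error / eff$df_error)
  eff$p <- pf(eff$F, eff$df, eff$df_error, lower.tail = FALSE)

  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  pooled <- matrix(0, Tt, Tt)
  for (g in levels(group)) {
    Yg <- Y[group == g, , drop = FALSE]
    pooled <- pooled + crossprod(scale(Yg, scale = FALSE))
  }
  pooled <- pooled / (S - G)
  mdiag <- mean(diag(pooled)); mall <- mean(pooled)
  rowm <- rowMeans(pooled)
  num <- (Tt * (mdiag - mall))^2
  den <- (Tt - 1) * (sum(pooled^2) - 2 * Tt * sum(rowm^2) + Tt^2 * mall^2)
  eps <- if (den > 0) num / den else NA_real_

  list(effects = eff, epsilon_gg = eps, n_subjects = S, n_timepoints = Tt,
       n_per_group = setNames(as.integer(ng), levels(group)),
       ss_total = sum((Y - grand)^2))
}

#' Mixed-design two-way repeated-measures ANOVA
#'
#' The study's omnibus test: one between-subject factor (group) crossed with
#' one within-subject factor (time), applied to any scalar network metric
#' observed for every subject at every timepoint. Returns the group-by-time
#' interaction and both main effects, with the between-subject error stratum
#' (subjects within groups) for the group effect and the subject-by-time
#' stratum for time and the interaction.
#'
#' Missing cells are rejected rather than imputed: the analysis is defined
#' for completers. No sphericity correction is applied to the reported p
#' values (three within levels); the Greenhouse-Geisser epsilon is computed
#' and stored for inspection.
#'
#' @param data Data frame in long format.
#' @param value,subject,group,time Column names (tidy-eval) of the metric,
#'   subject identifier, group label, and timepoint label.
#' @return An object of class `lc_rm_anova`; see [tidy()] / [glance()].
#' @examples
#' d <- tidyr::expand_grid(subject = 1:6, time = c("t1", "t2", "t3"))
#' d$group <- ifelse(d$subject <= 3, "a", "b")
#' d$y <- rnorm(nrow(d)) + (d$group == "a")
#' fit <- rm_anova(d, y, subject, group, time)
#' tidy(fit)
#' @export
rm_anova <- function(data, value, subject, group, time) {
  df <- dplyr::transmute(data,
                         .subject = as.character({{ subject }}),
                         .group = as.character({{ group }}),
                         .time = as.character({{ time }}),
                         .value = {{ value }})
  if (anyNA(df$.value)) abort("Missing metric values; completers only.")
  wide <- tidyr::pivot_wider(df, names_from = ".time", values_from = ".value")
  if (anyNA(wide)) {
    bad <- wide$.subject[!stats::complete.cases(wide)]
    abort(paste0("Incomplete subjects (missing timepoints): ",
                 paste(bad, collapse = ", ")),
          class = "longconn_incomplete")
  }
  tps <- unique(df$.time)
  Y <- as.matrix(wide[, tps, drop = FALSE])
  core <- rm_anova_core(Y, wide$.group)
  structure(c(core, list(timepoints = tps)), class = "lc_rm_anova")
}

#' @export
print.lc_rm_anova <- function(x, ...) {
  cat(sprintf("Mixed-design RM-ANOVA: %d subjects (%s), %d timepoints\n",
              x$n_subjects,
              paste(sprintf("%s n=%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", "),
              x$n_timepoints))
  print(as.data.frame(x$effects[, c("effect", "df", "df_error", "F", "p")]),
        row.names = FALSE)
  cat(sprintf("Greenhouse-Geisser epsilon: %.3f\n", x$epsilon_gg))
  invisible(x)
}

#' @rdname rm_anova
#' @param x An `lc_rm_anova` object.
#' @param ... Unused.
#' @export
tidy.lc_rm_anova <- function(x, ...) {
  dplyr::transmute(x$effects,
                   term = .data$effect, sumsq = .data$ss, df = .data$df,
                   df.error = .data$df_error, statistic = .data$F,
                   p.value = .data$p)
}

#' @rdname rm_anova
#' @export
glance.lc_rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_timepoints = x$n_timepoints,
                 epsilon_gg = x$epsilon_gg, ss_total = x$ss_total)
}

# One-way repeated-measures ANOVA across time within a single group.
rm_anova_oneway_core <- function(Y) {
  S <- nrow(Y); Tt <- ncol(Y)
  grand <- mean(Y)
  subj <- rowMeans(Y); tm <- colMeans(Y)
  ss_time <- S * sum((tm - grand)^2)
  ss_err <- sum((Y - outer(subj, rep(1, Tt)) - outer(rep(1, S), tm) + grand)^2)
  df_time <- Tt - 1; df_err <- (S - 1) * (Tt - 1)
  if (ss_time == 0) {
    # no time variation at all: F is 0 by convention, however small the error
    return(list(F = 0, df = df_time, df_error = df_err, p = 1))
  }
  if (ss_err <= 0) {
    abort("Degenerate variance.", class = "longconn_zero_variance")
  }
  Fv <- (ss_time / df_time) / (ss_err / df_err)
  list(F = Fv, df = df_time, df_error = df_err,
       p = pf(Fv, df_time, df_err, lower.tail = FALSE))
}

#' Post-hoc comparisons after a significant omnibus effect
#'
#' Where the omnibus mixed ANOVA flags a metric, the convention is to unpack
#' it with (a) a two-sample t-test between the groups at each timepoint
#' (cross-sectional contrasts) and (b) a one-way repeated-measures ANOVA
#' across time within each group (within-group contrasts). p values are
#' returned raw; compare them against [false_positive_adjust()] as
#' appropriate for the family.
#'
#' @inheritParams rm_anova
#' @return Tibble: `contrast` ("cross-sectional"/"within-group"), `level`
#'   (the timepoint or group), `statistic`, `df`, `p`.
#' @export
posthoc_tests <- function(data, value, subject, group, time) {
  df <- dplyr::transmute(data,
                         .subject = as.character({{ subject }}),
                         .group = as.character({{ group }}),
                         .time = as.character({{ time }}),
                         .value = {{ value }})
  cross <- df |>
    dplyr::group_by(.data$.time) |>
    dplyr::group_modify(function(d, key) {
      gs <- split(d$.value, d$.group)
      if (length(gs) != 2) abort("Exactly two groups required.")
      if (all(vapply(gs, function(v) var(v) == 0, logical(1))) &&
          mean(gs[[1]]) == mean(gs[[2]])) {
        return(tibble::tibble(statistic = 0,
                              df = length(d$.value) - 2, p = 1))
      }
      tt <- t.test(gs[[1]], gs[[2]], var.equal = TRUE)
      tibble::tibble(statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p = tt$p.value)
    }) |>
    dplyr::ungroup() |>
    dplyr::transmute(contrast = "cross-sectional", level = .data$.time,
                     statistic = .data$statistic, df = .data$df, p = .data$p)
  within <- df |>
    dplyr::group_by(.data$.group) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(d, names_from = ".time", values_from = ".value")
      Y <- as.matrix(wide[, setdiff(names(wide), ".subject"), drop = FALSE])
      res <- rm_anova_oneway_core(Y)
      tibble::tibble(statistic = res$F, df = res$df, p = res$p)
    }) |>
    dplyr::ungroup() |>
    dplyr::transmute(contrast = "within-group", level = .data$.group,
                     statistic = .data$statistic, df = .data$df, p = .data$p)
  dplyr::bind_rows(cross, within)
}

#' False-positive adjustment threshold
#'
#' The per-test significance threshold `1 / n` for a family of `n` tests —
#' the expected number of false positives across the family is then at most
#' one. For nodal tests on a 90-region parcellation this gives
#' `1/90 = 0.011`.
#'
#' @param n_tests_per_family Positive integer family size.
#' @return The per-test alpha.
#' @examples
#' false_positive_adjust(90)  # 0.0111...
#' @export
false_positive_adjust <- function(n_tests_per_family) {
  if (length(n_tests_per_family) != 1 || is.na(n_tests_per_family) ||
      n_tests_per_family < 1 || n_tests_per_family != as.integer(n_tests_per_family)) {
    abort("`n_tests_per_family` must be a positive integer.")
  }
  1 / n_tests_per_family
}

#' Correlation between change scores
#'
#' Pearson correlation between per-subject changes (to_tp minus from_tp) of
#' two variables — e.g. the change in FC-SC coupling against the change in a
#' clinical variable across a treatment interval.
#'
#' @param data Long data frame with one row per subject x timepoint.
#' @param var_a,var_b Columns (tidy-eval) holding the two variables.
#' @param from_tp,to_tp Timepoint labels defining the change interval.
#' @param subject,time Identifier columns (tidy-eval).
#' @return One-row tibble: `r`, `p`, `n`, `df`.
#' @export
change_score_correlation <- function(data, var_a, var_b, from_tp, to_tp,
                                     subject, time) {
  df <- dplyr::transmute(data,
                         .subject = as.character({{ subject }}),
                         .time = as.character({{ time }}),
                         .a = {{ var_a }}, .b = {{ var_b }})
  df <- dplyr::filter(df, .data$.time %in% c(from_tp, to_tp))
  wide <- tidyr::pivot_wider(df, names_from = ".time",
                             values_from = c(".a", ".b"))
  need <- paste0(rep(c(".a_", ".b_"), each = 2), c(from_tp, to_tp))
  if (!all(need %in% names(wide)) || anyNA(wide[need])) {
    abort("Both variables must be observed at both timepoints for every subject.",
          class = "longconn_incomplete")
  }
  da <- wide[[paste0(".a_", to_tp)]] - wide[[paste0(".a_", from_tp)]]
  db <- wide[[paste0(".b_", to_tp)]] - wide[[paste0(".b_", from_tp)]]
  if (sd(da) == 0 || sd(db) == 0) {
    abort("Zero-variance change scores.", class = "longconn_zero_variance")
  }
  ct <- cor.test(da, db)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n = length(da), df = unname(ct$parameter))
}

#' Permutation test for a group difference in a scalar metric
#'
#' Two-sided permutation test on the difference of group means. The observed
#' labelling counts as one permutation in both numerator and denominator, so
#' the p value can never be exactly zero. When the number of distinct
#' reassignments is small (or `exact = TRUE`), all label reassignments are
#' enumerated and the p value is exact; otherwise `n_perm` random
#' reassignments are drawn, reproducibly from `seed`.
#'
#' @param values_a,values_b Numeric vectors of the metric in the two groups.
#' @param n_perm Number of random permutations (>= 100) when not exact.
#' @param seed Integer seed (required for the random path).
#' @param exact `TRUE`, `FALSE`, or `"auto"` (exact when the number of
#'   splits is at most `exact_limit`).
#' @param exact_limit Enumeration ceiling for `"auto"`.
#' @return The two-sided p value.
#' @export
permutation_test_group_metric <- function(values_a, values_b, n_perm = 10000,
                                          seed = NULL, exact = "auto",
                                          exact_limit = 50000) {
  na <- length(values_a); nb <- length(values_b)
  if (na == 0 || nb == 0) abort("Both groups must be non-empty.")
  pooled <- c(values_a, values_b)
  obs <- abs(mean(values_a) - mean(values_b))
  tol <- 1e-12 * max(1, abs(obs))
  n <- na + nb
  n_splits <- choose(n, na)
  do_exact <- isTRUE(exact) || (identical(exact, "auto") && n_splits <= exact_limit)
  if (do_exact) {
    idx <- combn(n, na)
    tot <- sum(pooled)
    diffs <- abs(colSums(matrix(pooled[idx], nrow = na)) / na -
                   (tot - colSums(matrix(pooled[idx], nrow = na))) / nb)
    return(sum(diffs >= obs - tol) / ncol(idx))
  }
  if (n_perm < 100) abort("`n_perm` must be >= 100.")
  if (is.null(seed)) abort("`seed` is required for random permutations.")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    ia <- sample.int(n, na)
    d <- abs(mean(pooled[ia]) - mean(pooled[-ia]))
    if (d >= obs - tol) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}
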