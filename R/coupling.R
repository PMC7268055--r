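#' Extract the nonzero structural edges of a connectivity matrix
#'
#' The coupling analysis is constrained to node pairs with nonzero structural
#' connectivity: this returns the upper-triangle positions with positive
#' weight, in the fixed canonical edge order, together with their weights.
#'
#' @param sc A structural [connectivity_matrix()].
#' @return List with `index` (positions into the upper-triangle vector) and
#'   `values` (the structural weights there).
#' @export
extract_nonzero_sc_edges <- function(sc) {
  stopifnot(inherits(sc, "connectivity_matrix"))
  if (sc$modality != "structural") {
    abort("`sc` must be a structural connectivity matrix.")
  }
  v <- upper_tri_vector(sc$weights)
  idx <- which(v > 0)
  if (length(idx) < 3) {
    abort("Fewer than 3 nonzero structural edges; coupling is undefined.",
          class = "longconn_degenerate_coupling")
  }
  list(index = idx, values = v[idx])
}

#' Rank-based Gaussian resampling (inverse-normal transform)
#'
#' Maps a vector onto standard-normal quantiles by rank: the value with rank
#' *r* among *m* becomes `qnorm((r - 0.375) / (m + 0.25))` (Blom's offset).
#' Ties receive average ranks. The output is a strictly monotone function of
#' the input ranks, so any strictly increasing transform of the input leaves
#' the result unchanged.
#'
#' @param values Numeric vector, length >= 3, not all identical.
#' @return Numeric vector of normal scores.
#' @examples
#' gaussian_resample(c(10, 2, 7))
#' @export
gaussian_resample <- function(values) {
  m <- length(values)
  if (m < 3) abort("Need at least 3 values.", class = "longconn_degenerate_coupling")
  if (length(unique(values)) == 1) {
    abort("All values identical; ranks are degenerate.",
          class = "longconn_degenerate_coupling")
  }
  r <- rank(values, ties.method = "average")
  qnorm((r - 0.375) / (m + 0.25))
}

#' Functional-structural connectivity coupling of one subject
#'
#' The coupling score is the Pearson correlation between the
#' Gaussian-resampled structural weights at nonzero structural edges and the
#' raw (signed) functional values at those same edges. Only the structural
#' vector is resampled; streamline counts are heavily skewed, while
#' correlation-based functional values already live on a bounded,
#' roughly symmetric scale.
#'
#' @param sc Structural [connectivity_matrix()].
#' @param fc Functional [connectivity_matrix()] for the same subject,
#'   timepoint and parcellation.
#' @return One-row tibble: `subject_id`, `group`, `timepoint`, `r`, `n_edges`.
#' @export
compute_coupling <- function(sc, fc) {
  stopifnot(inherits(sc, "connectivity_matrix"), inherits(fc, "connectivity_matrix"))
  if (fc$modality != "functional") abort("`fc` must be functional.")
  if (nrow(sc$weights) != nrow(fc$weights)) {
    abort("Node count mismatch between SC and FC.", class = "longconn_dim_mismatch")
  }
  edges <- extract_nonzero_sc_edges(sc)
  sc_g <- gaussian_resample(edges$values)
  fc_v <- upper_tri_vector(fc$weights)[edges$index]
  if (sd(fc_v) == 0) {
    abort("Functional values at structural edges have zero variance.",
          class = "longconn_degenerate_coupling")
  }
  tibble::tibble(subject_id = sc$subject_id, group = sc$group,
                 timepoint = sc$timepoint,
                 r = cor(sc_g, fc_v), n_edges = length(edges$index))
}

#' Coupling scores for every subject-timepoint of a study
#'
#' @param matrices A named list of [connectivity_matrix()] objects (as built
#'   by [generate_study()] or [read_study()]); SC/FC pairs are matched on
#'   subject and timepoint.
#' @return Tibble with one row per subject x timepoint.
#' @export
coupling_table <- function(matrices) {
  info <- purrr::map_dfr(matrices, function(m) {
    tibble::tibble(subject_id = m$subject_id, timepoint = m$timepoint,
                   modality = m$modality)
  }, .id = "key")
  pairs <- info |>
    tidyr::pivot_wider(names_from = "modality", values_from = "key")
  if (!all(c("functional", "structural") %in% names(pairs))) {
    abort("Need both modalities for every subject-timepoint.")
  }
  purrr::pmap_dfr(pairs, function(subject_id, timepoint, functional, structural) {
    compute_coupling(matrices[[structural]], matrices[[functional]])
  })
}
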