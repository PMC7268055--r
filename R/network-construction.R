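#' Construct a connectivity matrix object
#'
#' A `connectivity_matrix` is one subject's raw (unthresholded) network at one
#' timepoint for one modality. Functional weights are Pearson correlations in
#' \[-1, 1\]; structural weights are nonnegative streamline counts.
#'
#' @param weights Square symmetric numeric matrix, zero diagonal.
#' @param modality `"functional"` or `"structural"`.
#' @param subject_id,group,timepoint Identifiers carried into result tables.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, modality = c("functional", "structural"),
                                subject_id = NA_character_, group = NA_character_,
                                timepoint = NA_character_) {
  modality <- match.arg(modality)
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    abort("`weights` must be a square matrix.", class = "longconn_invalid_matrix")
  }
  if (anyNA(weights)) {
    abort("`weights` must not contain NA/NaN.", class = "longconn_invalid_matrix")
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-8 * max(abs(weights), 1e-12)) {
    bad <- which(abs(weights - t(weights)) == asym, arr.ind = TRUE)[1, ]
    abort(sprintf("Matrix is asymmetric: worst cell (%d, %d), |w_ij - w_ji| = %.3g.",
                  bad[1], bad[2], asym),
          class = "longconn_invalid_matrix")
  }
  if (any(diag(weights) != 0)) {
    warn("Nonzero diagonal entries forced to 0.")
    diag(weights) <- 0
  }
  if (modality == "structural" && any(weights < 0)) {
    abort("Structural weights must be nonnegative.", class = "longconn_invalid_matrix")
  }
  if (modality == "functional" && any(abs(weights) > 1 + 1e-8)) {
    abort("Functional weights must lie in [-1, 1].", class = "longconn_invalid_matrix")
  }
  structure(list(weights = weights, modality = modality, subject_id = subject_id,
                 group = group, timepoint = timepoint),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix: %s, %d nodes, subject %s, %s, %s>\n",
              x$modality, nrow(x$weights), x$subject_id, x$group, x$timepoint))
  invisible(x)
}

#' Functional connectivity matrix from ROI time series
#'
#' Pairwise Pearson correlation between regional BOLD time courses
#' (volumes x ROIs), diagonal set to zero.
#'
#' @param ts Numeric matrix, volumes in rows, ROIs in columns. Column names,
#'   if present, become node labels.
#' @param subject_id,group,timepoint Identifiers.
#' @return A `"functional"` [connectivity_matrix()].
#' @export
functional_matrix_from_timeseries <- function(ts, subject_id = NA_character_,
                                              group = NA_character_,
                                              timepoint = NA_character_) {
  if (!is.matrix(ts)) ts <- as.matrix(ts)
  if (nrow(ts) < 3) abort("Need at least 3 volumes to correlate.")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(ts))) colnames(ts)[bad] else as.character(bad)
    abort(paste0("Constant ROI time series (correlation undefined): ",
                 paste(nm, collapse = ", ")),
          class = "longconn_constant_roi")
  }
  r <- cor(ts)
  diag(r) <- 0
  r <- (r + t(r)) / 2  # guard symmetry against rounding
  connectivity_matrix(r, "functional", subject_id, group, timepoint)
}

# Half-up rounding: round(0.5) in base R is banker's; thresholding needs a
# deterministic, monotone edge-count rule.
round_half_up <- function(x) floor(x + 0.5)

#' Threshold a connectivity matrix to a fixed connection density
#'
#' Retains exactly `round(density * N(N-1)/2)` strongest edges (half-up
#' rounding) with their weights; every other entry becomes zero. Ties in
#' weight are broken by the fixed upper-triangle edge order, which makes
#' thresholding deterministic and the edge sets nested across densities.
#'
#' For functional matrices, negative correlations are set to zero before
#' ranking: the path-length machinery downstream requires nonnegative
#' weights. (The signed matrix remains available in the input object for
#' edge-level statistics.)
#'
#' @param cm A [connectivity_matrix()].
#' @param density Target connection density in (0, 1].
#' @return A `thresholded_network`: list with `net` (a [weighted_network()]),
#'   `density`, `n_edges`, `modality`, and the subject identifiers.
#' @export
threshold_to_density <- function(cm, density) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!(density > 0 && density <= 1)) {
    abort("`density` must lie in (0, 1].", class = "longconn_bad_density")
  }
  w <- cm$weights
  if (cm$modality == "functional") w <- pmax(w, 0)
  n <- nrow(w)
  n_pairs <- n * (n - 1) / 2
  k <- round_half_up(density * n_pairs)
  v <- upper_tri_vector(w)
  pos <- which(v > 0)
  if (k > length(pos)) {
    abort(sprintf(
      "Density %.3f needs %d edges but only %d nonzero edges are available.",
      density, k, length(pos)),
      class = "longconn_insufficient_edges")
  }
  # stable sort: ties in weight keep the fixed upper-triangle order
  keep <- pos[order(-v[pos])[seq_len(k)]]
  out <- matrix(0, n, n)
  ut <- which(upper.tri(out))
  out[ut[keep]] <- v[keep]
  out <- out + t(out)
  labels <- if (!is.null(rownames(w))) rownames(w) else as.character(seq_len(n))
  structure(list(net = weighted_network(out, labels = labels, validate = FALSE),
                 density = density, n_edges = k, modality = cm$modality,
                 subject_id = cm$subject_id, group = cm$group,
                 timepoint = cm$timepoint),
            class = "thresholded_network")
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat(sprintf("<thresholded_network: %s, density %.3f (%d edges), subject %s>\n",
              x$modality, x$density, x$n_edges, x$subject_id))
  invisible(x)
}

#' Default density grids per modality
#'
#' Connection-density ranges conventionally explored for each modality:
#' functional 0.05-0.20, structural 0.05-0.15, step 0.01.
#'
#' @param modality `"functional"` or `"structural"`.
#' @param step Grid step.
#' @return Numeric vector of densities.
#' @export
default_density_grid <- function(modality = c("functional", "structural"),
                                 step = 0.01) {
  modality <- match.arg(modality)
  if (modality == "functional") seq(0.05, 0.20, by = step)
  else seq(0.05, 0.15, by = step)
}

#' Threshold a matrix across a density sweep
#'
#' One [threshold_to_density()] call per density on the inclusive grid
#' `seq(d_min, d_max, by = step)`. Downstream metrics are typically averaged
#' across the sweep (area-under-curve summary) to avoid privileging a single
#' arbitrary density.
#'
#' @param cm A [connectivity_matrix()].
#' @param d_min,d_max Inclusive density range.
#' @param step Grid step (> 0).
#' @return List of `thresholded_network` objects, one per density.
#' @export
density_sweep <- function(cm, d_min = 0.05, d_max = 0.20, step = 0.01) {
  stopifnot(d_min <= d_max, step > 0)
  grid <- seq(d_min, d_max, by = step)
  purrr::map(grid, ~ threshold_to_density(cm, .x))
}
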