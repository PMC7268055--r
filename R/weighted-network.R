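#' Construct a weighted network
#'
#' A `weighted_network` is the elementary object all topology metrics operate
#' on: a symmetric nonnegative weight matrix with a zero diagonal, plus node
#' labels (parcellation region names, by convention 1-based region numbers).
#'
#' @param weights Square numeric matrix; symmetric, nonnegative, zero diagonal.
#' @param labels Optional character vector of node labels; defaults to
#'   `"1" ... "N"` following the usual atlas numbering.
#' @param validate Check invariants (symmetry, nonnegativity, zero diagonal).
#' @return An object of class `weighted_network`: a list with elements
#'   `weights` (matrix) and `labels`.
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 0.5
#' net <- weighted_network(w)
#' nodal_degree(net)
#' @export
weighted_network <- function(weights, labels = NULL, validate = TRUE) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    abort("`weights` must be a numeric matrix.", class = "longconn_invalid_network")
  }
  n <- nrow(weights)
  if (ncol(weights) != n) {
    abort("`weights` must be square.", class = "longconn_invalid_network")
  }
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (length(labels) != n) {
    abort("`labels` length must equal the number of nodes.",
          class = "longconn_invalid_network")
  }
  if (validate) {
    if (anyNA(weights)) {
      abort("`weights` must not contain NA/NaN.", class = "longconn_invalid_network")
    }
    asym <- max(abs(weights - t(weights)))
    scale <- max(abs(weights), 1e-12)
    if (asym > 1e-8 * scale) {
      abort(sprintf("`weights` is not symmetric (max |w_ij - w_ji| = %.3g).", asym),
            class = "longconn_invalid_network")
    }
    if (any(diag(weights) != 0)) {
      abort("`weights` must have a zero diagonal.", class = "longconn_invalid_network")
    }
    if (any(weights < 0)) {
      abort("`weights` must be nonnegative (apply the functional sign policy upstream).",
            class = "longconn_invalid_network")
    }
  }
  structure(list(weights = weights, labels = labels), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- nrow(x$weights)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<weighted_network: %d nodes, %d edges, density %.3f>\n",
              n, m, m / (n * (n - 1) / 2)))
  invisible(x)
}

n_nodes <- function(net) nrow(net$weights)

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Upper-triangle edge vector of a square matrix
#'
#' Returns the strictly-upper-triangle entries in fixed column-major order
#' ((1,2), (1,3), (2,3), (1,4), ...) — the canonical edge ordering used
#' throughout for thresholding tie-breaks and coupling vectors.
#'
#' @param w Square matrix.
#' @return Numeric vector of length `N(N-1)/2`.
#' @export
upper_tri_vector <- function(w) {
  w[upper.tri(w)]
}
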