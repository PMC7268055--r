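#' Weighted shortest path lengths
#'
#' Edge lengths are the reciprocals of the edge weights (a strong connection
#' is a short distance), and the path length between two nodes is the minimum
#' over paths of the summed edge lengths. Unreachable pairs carry `Inf`.
#'
#' @param net A [weighted_network()].
#' @return Symmetric numeric matrix of shortest path lengths; zero diagonal,
#'   `Inf` for unreachable pairs.
#' @examples
#' w <- matrix(0, 2, 2); w[1, 2] <- w[2, 1] <- 0.5
#' shortest_path_lengths(weighted_network(w))  # single edge: 1/0.5 = 2
#' @export
shortest_path_lengths <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  n <- n_nodes(net)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    dimnames(d) <- list(net$labels, net$labels)
    return(d)
  }
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- list(net$labels, net$labels)
  d
}

#' Nodal degree (strength)
#'
#' The weighted degree \eqn{S_i = \sum_j w_{ij}}: the summed weight of all
#' connections of node *i*.
#'
#' @param net A [weighted_network()].
#' @return Named numeric vector, one value per node.
#' @export
nodal_degree <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  setNames(rowSums(net$weights), net$labels)
}

#' Nodal efficiency
#'
#' \eqn{E_i = \frac{1}{N-1}\sum_{j \ne i} 1/L_{ij}}: the mean reciprocal
#' shortest path length from node *i* to every other node. Unreachable pairs
#' contribute zero, so the measure is well defined on disconnected networks.
#'
#' @param net A [weighted_network()].
#' @param lengths Optional precomputed [shortest_path_lengths()] matrix.
#' @return Named numeric vector, one value per node.
#' @export
nodal_efficiency <- function(net, lengths = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (is.null(lengths)) lengths <- shortest_path_lengths(net)
  n <- n_nodes(net)
  inv <- 1 / lengths
  diag(inv) <- 0
  inv[is.infinite(lengths)] <- 0
  setNames(rowSums(inv) / (n - 1), net$labels)
}

#' Nodal betweenness centrality (raw and normalized)
#'
#' Shortest-path betweenness on the weighted graph (edge length = reciprocal
#' weight): \eqn{B_i} accumulates, over all unordered node pairs, the fraction
#' of shortest paths between the pair that pass through *i* as an intermediate.
#' The normalized form is \eqn{b_i = B_i / \langle B \rangle}; when the mean
#' raw betweenness is zero (e.g. a complete graph routes nothing through
#' intermediates) all \eqn{b_i} are set to zero.
#'
#' Implemented with Brandes' accumulation on top of Dijkstra, with a relative
#' tolerance of `1e-12` when detecting equal-length paths: reciprocal weights
#' routinely create ties that exact floating-point comparison would split
#' arbitrarily.
#'
#' @param net A [weighted_network()].
#' @param tol Relative tolerance for shortest-path tie detection.
#' @return A list with numeric vectors `raw` and `normalized`.
#' @export
nodal_betweenness <- function(net, tol = 1e-12) {
  stopifnot(inherits(net, "weighted_network"))
  n <- n_nodes(net)
  w <- net$weights
  len <- ifelse(w > 0, 1 / w, Inf)
  nbrs <- lapply(seq_len(n), function(i) which(w[i, ] > 0))
  B <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    pred <- vector("list", n)
    done <- logical(n)
    order_popped <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      order_popped <- c(order_popped, u)
      for (v in nbrs[[u]]) {
        if (done[v]) next
        alt <- dist[u] + len[u, v]
        eps <- tol * max(1, abs(alt))
        if (!is.finite(dist[v]) || alt < dist[v] - eps) {
          dist[v] <- alt
          sigma[v] <- sigma[u]
          pred[[v]] <- u
        } else if (abs(alt - dist[v]) <= eps) {
          sigma[v] <- sigma[v] + sigma[u]
          pred[[v]] <- c(pred[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(order_popped)) {
      for (u in pred[[v]]) {
        delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])
      }
      if (v != s) B[v] <- B[v] + delta[v]
    }
  }
  B <- B / 2  # each unordered pair visited from both endpoints
  mB <- mean(B)
  b <- if (mB > 0) B / mB else numeric(n)
  list(raw = setNames(B, net$labels), normalized = setNames(b, net$labels))
}

#' Characteristic path length (harmonic-mean form)
#'
#' \deqn{L_{net} = 1 \Big/ \Big[\frac{1}{N(N-1)}\sum_i \sum_{j \ne i} 1/L_{ij}\Big]}
#'
#' The reciprocal of the average reciprocal shortest path length. The
#' harmonic-mean form keeps the measure finite on disconnected networks:
#' unreachable pairs contribute zero to the sum of reciprocals. An edgeless
#' network returns `Inf`.
#'
#' @param lengths A [shortest_path_lengths()] matrix.
#' @return A single number (possibly `Inf`).
#' @export
characteristic_path_length <- function(lengths) {
  n <- nrow(lengths)
  stopifnot(n >= 2)
  inv <- 1 / lengths
  diag(inv) <- 0
  inv[is.infinite(lengths)] <- 0
  s <- sum(inv) / (n * (n - 1))
  if (s == 0) Inf else 1 / s
}

#' Total network strength
#'
#' \eqn{S_{net} = \frac{1}{N}\sum_i S_i}: the mean nodal degree. (Some texts
#' describe this quantity in words as the "sum" of nodal degrees, but the
#' defining formula carries the 1/N factor; the formula is what is computed
#' here.)
#'
#' @param degrees Vector of nodal degrees from [nodal_degree()].
#' @return A single number.
#' @export
network_strength <- function(degrees) {
  mean(degrees)
}

#' Weighted clustering coefficient
#'
#' Per-node geometric-mean-of-triangle-weights clustering (Onnela form):
#' weights are rescaled by the maximum weight, and the clustering of node *i*
#' is the sum over triangles of the geometric mean of the three cube-rooted
#' weights, divided by \eqn{k_i (k_i - 1)} with \eqn{k_i} the binary degree.
#' Nodes with fewer than two neighbours have clustering zero. The network
#' value is the mean over all nodes.
#'
#' @param net A [weighted_network()].
#' @return List with `nodal` (numeric vector) and `network` (scalar mean).
#' @export
weighted_clustering <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  n <- n_nodes(net)
  mx <- max(w)
  if (mx == 0) {
    return(list(nodal = setNames(numeric(n), net$labels), network = 0))
  }
  wh <- (w / mx)^(1 / 3)
  tri <- diag(wh %*% wh %*% wh)  # 2x (sum of geometric-mean triangle weights)
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  list(nodal = setNames(ci, net$labels), network = mean(ci))
}

#' Degree-preserving null network
#'
#' Rewires the binarized topology with degree-sequence-preserving edge swaps
#' (many swaps per edge), then reassigns the original weights in random order
#' onto the rewired edges. Preserves each node's binary degree exactly and
#' the multiset of weights; destroys clustering structure.
#'
#' @param net A [weighted_network()].
#' @param swaps_per_edge Rewiring intensity; total swap attempts are
#'   `swaps_per_edge * n_edges`.
#' @return A [weighted_network()].
#' @keywords internal
rewire_null <- function(net, swaps_per_edge = 10) {
  g <- as_igraph(net)
  m <- igraph::ecount(g)
  if (m < 2) {
    abort("Network has too few edges to rewire.",
          class = "longconn_degenerate_topology")
  }
  wts <- igraph::E(g)$weight
  g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = swaps_per_edge * m))
  a <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
  idx <- which(upper.tri(a) & a > 0)
  wnew <- matrix(0, n_nodes(net), n_nodes(net))
  wnew[idx] <- sample(wts)
  wnew <- wnew + t(wnew)
  weighted_network(wnew, labels = net$labels, validate = FALSE)
}

#' Small-world indices against a rewired null ensemble
#'
#' Compares the network's weighted clustering and harmonic characteristic
#' path length with their means over `n_nulls` degree-preserving rewired
#' null networks: `gamma = C / <C_null>`, `lambda = L / <L_null>`,
#' `sigma = gamma / lambda`. A small-world network has `gamma >> 1`,
#' `lambda ~ 1`, hence `sigma > 1`.
#'
#' @param net A [weighted_network()] with finite characteristic path length.
#' @param n_nulls Number of null networks (>= 1).
#' @param seed Integer seed; the null ensemble is deterministic given it.
#' @return A one-row tibble: `strength`, `char_path_length`, `clustering`,
#'   `gamma`, `lambda`, `sigma`, `n_nulls`.
#' @export
small_world_indices <- function(net, n_nulls = 100, seed) {
  stopifnot(inherits(net, "weighted_network"), n_nulls >= 1)
  if (missing(seed)) abort("`seed` is required: the null ensemble is stochastic.")
  lens <- shortest_path_lengths(net)
  L <- characteristic_path_length(lens)
  if (!is.finite(L)) {
    abort("Characteristic path length is infinite; cannot normalise.",
          class = "longconn_degenerate_topology")
  }
  C <- weighted_clustering(net)$network
  S <- network_strength(nodal_degree(net))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  nulls <- purrr::map(seq_len(n_nulls), function(k) {
    nn <- rewire_null(net)
    c(C = weighted_clustering(nn)$network,
      L = characteristic_path_length(shortest_path_lengths(nn)))
  })
  Cn <- mean(purrr::map_dbl(nulls, "C"))
  Ln <- mean(purrr::map_dbl(nulls, "L"))
  gamma <- C / Cn
  lambda <- L / Ln
  tibble::tibble(strength = S, char_path_length = L, clustering = C,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 n_nulls = n_nulls)
}

#' All nodal and global topology metrics of one network
#'
#' Convenience wrapper computing the full metric set on a single (typically
#' thresholded) network. Small-world indices are optional because they need
#' a null ensemble.
#'
#' @param net A [weighted_network()].
#' @param small_world Compute gamma/lambda/sigma too?
#' @param n_nulls,seed Passed to [small_world_indices()] when `small_world`.
#' @return A list with `nodal` (tibble: node, degree, efficiency,
#'   betweenness_raw, betweenness_norm) and `global` (one-row tibble:
#'   strength, char_path_length, clustering, and the small-world columns
#'   when requested).
#' @export
network_metrics <- function(net, small_world = FALSE, n_nulls = 100, seed = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  lens <- shortest_path_lengths(net)
  deg <- nodal_degree(net)
  eff <- nodal_efficiency(net, lens)
  btw <- nodal_betweenness(net)
  clu <- weighted_clustering(net)
  nodal <- tibble::tibble(
    node = net$labels,
    degree = unname(deg),
    efficiency = unname(eff),
    betweenness_raw = unname(btw$raw),
    betweenness_norm = unname(btw$normalized)
  )
  global <- tibble::tibble(
    strength = network_strength(deg),
    char_path_length = characteristic_path_length(lens),
    clustering = clu$network
  )
  if (small_world) {
    if (is.null(seed)) abort("`seed` is required when `small_world = TRUE`.")
    sw <- small_world_indices(net, n_nulls = n_nulls, seed = seed)
    global <- dplyr::bind_cols(global[, c("strength", "char_path_length", "clustering")],
                               sw[, c("gamma", "lambda", "sigma")])
  }
  list(nodal = nodal, global = global)
}
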