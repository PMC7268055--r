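# Independent brute-force oracle for small weighted graphs: exhaustive
# enumeration of all simple paths between every node pair. Never calls the
# package's shortest-path or betweenness code.

oracle_metrics <- function(w, tol = 1e-9) {
  n <- nrow(w)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  B <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      lens <- list()
      nodes <- list()
      dfs <- function(node, visited, len) {
        if (node == t) {
          lens[[length(lens) + 1]] <<- len
          nodes[[length(nodes) + 1]] <<- visited
          return(invisible())
        }
        for (nb in which(w[node, ] > 0)) {
          if (!(nb %in% visited)) dfs(nb, c(visited, nb), len + 1 / w[node, nb])
        }
      }
      dfs(s, s, 0)
      if (length(lens) == 0) next
      lv <- unlist(lens)
      m <- min(lv)
      D[s, t] <- D[t, s] <- m
      minimal <- which(lv <= m + tol * max(1, m))
      for (k in minimal) {
        inter <- setdiff(nodes[[k]], c(s, t))
        if (length(inter) > 0) B[inter] <- B[inter] + 1 / length(minimal)
      }
    }
  }
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  Si <- rowSums(w)
  Ei <- rowSums(inv) / (n - 1)
  Lnet <- 1 / (sum(inv) / (n * (n - 1)))
  list(D = D, B = B, Si = Si, Ei = Ei, Lnet = Lnet)
}

is_connected_adj <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1
  while (length(frontier) > 0) {
    nxt <- which(colSums(w[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

random_connected_graph <- function(n, p = 0.45) {
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    on <- runif(sum(ut)) < p
    vals <- runif(sum(ut), 0.1, 2)
    w[ut] <- ifelse(on, vals, 0)
    w <- w + t(w)
    if (is_connected_adj(w)) return(w)
  }
}

# small complete-data longitudinal design for ANOVA tests
make_long_data <- function(Y, group, timepoints = paste0("t", seq_len(ncol(Y)))) {
  n <- nrow(Y)
  tidyr::expand_grid(subject = sprintf("s%02d", seq_len(n)),
                     time = timepoints) |>
    dplyr::mutate(group = rep(group, each = length(timepoints)),
                  y = as.vector(t(Y)))
}
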