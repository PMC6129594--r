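# Independent brute-force oracles, deliberately naive: exhaustive simple-path
# enumeration for shortest paths, literal double loops for clustering and
# local efficiency. Used only on tiny graphs.

# Shortest paths by exhaustive enumeration of simple paths (n <= ~7).
brute_shortest_paths <- function(lengths) {
  n <- nrow(lengths)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  explore <- function(node, target, visited, acc) {
    if (node == target) {
      if (acc < best[visited[1], target])
        best[visited[1], target] <<- acc
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (nxt %in% visited) next
      w <- lengths[node, nxt]
      if (!is.finite(w) || nxt == node) next
      explore(nxt, target, c(visited, nxt), acc + w)
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    explore(i, j, i, 0)
  }
  best
}

# Onnela clustering, literal triple loop, weights normalized by max.
brute_clustering <- function(adj) {
  n <- nrow(adj)
  wmax <- max(adj)
  if (wmax == 0) return(list(Cp = 0, C_i = numeric(n)))
  Wn <- adj / wmax
  C_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (h in nb) {
      if (j == h) next
      s <- s + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    }
    C_i[i] <- s / (k * (k - 1))
  }
  list(Cp = mean(C_i), C_i = C_i)
}

# Local efficiency straight from the definition, using the brute
# shortest-path oracle on each neighborhood subgraph.
brute_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    m <- length(nb)
    if (m < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    len <- ifelse(sub > 0, 1 / sub, Inf)
    diag(len) <- 0
    D <- brute_shortest_paths(len)
    inv <- 1 / D
    inv[!is.finite(D)] <- 0
    diag(inv) <- 0
    sum(inv) / (m * (m - 1))
  }, numeric(1))
  mean(vals)
}

# Random symmetric weighted adjacency for property tests.
random_adjacency <- function(n, p = 0.5, wmin = 0.1, wmax = 0.9) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- ut[stats::runif(length(ut)) < p]
  A[on] <- stats::runif(length(on), wmin, wmax)
  A + t(A)
}

as_network <- function(adj, hemisphere = "L") {
  hemispheric_network(hemisphere, adj,
                      sprintf("N%02d", seq_len(nrow(adj))))
}

# Small cohort spec used across tests; clinical link targets a region that
# exists on the reduced parcellation.
tiny_spec <- function(...) {
  defaults <- list(n_patients = 5, n_controls = 6,
                   n_regions_per_hemisphere = 10, edge_density = 0.4,
                   clinical_link = default_clinical_link("R03"),
                   seed = 99L)
  args <- utils::modifyList(defaults, list(...), keep.null = TRUE)
  do.call(synthetic_spec, args)
}
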