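#' Weighted graph metrics for hemispheric networks
#'
#' Edge weights are FA values in `(0, 1]`; topological distance between
#' adjacent nodes is the reciprocal of the weight (the standard convention
#' for FA-weighted connectomes: stronger connections are "shorter").
#' Because weights never exceed 1, every finite shortest-path distance is
#' at least 1, so all efficiency-type metrics lie in `[0, 1]`.
#'
#' Metrics:
#' \itemize{
#'   \item `Lp` — characteristic path length: mean shortest-path distance
#'     over ordered pairs of nodes that are connected; the number of
#'     unreachable (excluded) pairs is reported alongside.
#'   \item `Eg` — global efficiency: mean of `1/d_ij` over all ordered
#'     pairs, with `1/Inf = 0`; identically the mean of nodal efficiency.
#'   \item `Enodal(i)` — nodal efficiency: mean of `1/d_ij` from node `i`
#'     to every other node.
#'   \item `Cp` — weighted clustering coefficient, Onnela geometric-mean
#'     form with weights normalized by the network maximum; nodes with
#'     degree < 2 score 0 and are included in the average.
#'   \item `Eloc` — local efficiency: mean over nodes of the global
#'     efficiency of each node's neighborhood subgraph (original weights,
#'     the node itself excluded); degree < 2 nodes contribute 0.
#' }
#'
#' @name graph_metrics
NULL

#' Convert an FA-weight adjacency to a length matrix
#'
#' `length = 1/weight` for positive weights, `Inf` for absent edges,
#' 0 on the diagonal.
#'
#' @param adjacency square matrix of nonnegative weights
#' @return matrix of edge lengths
#' @export
weight_to_length <- function(adjacency) {
  if (any(adjacency < 0)) stop("negative weights are not allowed")
  len <- ifelse(adjacency > 0, 1 / adjacency, Inf)
  diag(len) <- 0
  len
}

#' All-pairs shortest-path distances
#'
#' Dijkstra on the weighted graph defined by a length matrix (entries are
#' edge lengths; `Inf` marks absent edges). Unreachable pairs keep `Inf`.
#'
#' @param lengths square matrix of nonnegative edge lengths
#' @return symmetric distance matrix with zero diagonal
#' @export
shortest_paths_all <- function(lengths) {
  if (any(lengths < 0)) stop("edge lengths must be nonnegative")
  n <- nrow(lengths)
  ii <- which(upper.tri(lengths) & is.finite(lengths))
  idx <- arrayInd(ii, dim(lengths))
  g <- igraph::make_graph(rbind(idx[, 1], idx[, 2]), n = n,
                          directed = FALSE)
  D <- igraph::distances(g, weights = lengths[ii], algorithm = "dijkstra")
  dimnames(D) <- dimnames(lengths)
  D
}

#' Characteristic path length
#'
#' Mean of finite off-diagonal shortest-path distances (ordered pairs);
#' disconnected pairs are excluded and their count reported.
#'
#' @param D distance matrix from [shortest_paths_all()]
#' @return list with `Lp` and `n_excluded_pairs`
#' @export
characteristic_path_length <- function(D) {
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0) stop("empty network: no finite node pairs")
  list(Lp = mean(fin), n_excluded_pairs = sum(!is.finite(off)))
}

#' Global efficiency
#'
#' @param D distance matrix
#' @return mean of `1/d_ij` over ordered pairs `i != j` (with `1/Inf = 0`)
#' @export
global_efficiency <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  inv <- 1 / D
  inv[!is.finite(D) | row(D) == col(D)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' @param D distance matrix
#' @param i node index (optional; default all nodes)
#' @return vector of `Enodal(i) = mean_j 1/d_ij`
#' @export
nodal_efficiency <- function(D, i = seq_len(nrow(D))) {
  n <- nrow(D)
  if (any(i < 1 | i > n)) stop("node index out of range")
  inv <- 1 / D
  inv[!is.finite(D)] <- 0
  diag(inv) <- 0
  rowSums(inv)[i] / (n - 1)
}

#' Weighted clustering coefficient (Onnela form)
#'
#' Per-node geometric-mean triangle intensity with weights normalized by
#' the network-wide maximum; `Cp` is the mean over all nodes, counting
#' degree < 2 nodes as 0.
#'
#' @param adjacency symmetric weight matrix in `[0, 1]`
#' @return list with `Cp` and per-node vector `C_i`
#' @export
clustering_coefficient <- function(adjacency) {
  check_symmetric(adjacency, "adjacency")
  n <- nrow(adjacency)
  wmax <- max(adjacency)
  k <- rowSums(adjacency > 0)
  if (wmax == 0) return(list(Cp = 0, C_i = numeric(n)))
  W <- (adjacency / wmax)^(1 / 3)
  tri <- diag(W %*% W %*% W)       # 2 x sum of triangle intensities at i
  C_i <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  list(Cp = mean(C_i), C_i = as.numeric(C_i))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors (original weights, the central node excluded); nodes
#' with fewer than two neighbors contribute 0.
#'
#' @param adjacency symmetric weight matrix
#' @return scalar `Eloc`
#' @export
local_efficiency <- function(adjacency) {
  check_symmetric(adjacency, "adjacency")
  n <- nrow(adjacency)
  e <- vapply(seq_len(n), function(i) {
    nb <- which(adjacency[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- adjacency[nb, nb, drop = FALSE]
    global_efficiency(shortest_paths_all(weight_to_length(sub)))
  }, numeric(1))
  mean(e)
}

#' Compute the full metric set for one hemispheric network
#'
#' All distance-based metrics share one all-pairs shortest-path
#' computation. The mean of the nodal-efficiency vector equals `Eg` by
#' construction (both average `1/d` over the same ordered pairs).
#'
#' @param network a `hemispheric_network`
#' @return a `metric_set` list: `Cp`, `Lp`, `Eg`, `Eloc`, `Enodal`
#'   (named vector), `n_connected_pairs`, `n_excluded_pairs`
#' @export
compute_metric_set <- function(network) {
  adj <- network$adjacency
  D <- shortest_paths_all(weight_to_length(adj))
  n <- nrow(D)
  lp <- characteristic_path_length(D)
  en <- nodal_efficiency(D)
  names(en) <- network$node_labels
  structure(list(
    Cp = clustering_coefficient(adj)$Cp,
    Lp = lp$Lp,
    Eg = global_efficiency(D),
    Eloc = local_efficiency(adj),
    Enodal = en,
    n_connected_pairs = n * (n - 1) - lp$n_excluded_pairs,
    n_excluded_pairs = lp$n_excluded_pairs
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set: Cp=%.4f Lp=%.4f Eg=%.4f Eloc=%.4f | %d nodes>\n",
              x$Cp, x$Lp, x$Eg, x$Eloc, length(x$Enodal)))
  invisible(x)
}

#' Long-format metric table for a cohort
#'
#' Runs [construct_subject_networks()] and [compute_metric_set()] (plus,
#' optionally, [normalized_small_world()]) for every subject, returning one
#' row per subject x hemisphere x metric. Nodal-efficiency rows carry the
#' region abbreviation in `node`; global rows leave it `NA`.
#'
#' @param connectomes list of `subject_connectome` objects
#' @param parcellation a [parcellation()]
#' @param threshold fiber-count cutoff, default 3
#' @param n_nulls matched random networks per hemisphere for the
#'   small-world normalization (`gamma`, `lambda`, `sigma` rows);
#'   0 skips normalization
#' @param seed integer seed controlling the null ensembles
#' @return data.frame with columns
#'   `subject_id`, `hemisphere`, `metric`, `node`, `value`
#' @export
cohort_metrics <- function(connectomes, parcellation, threshold = 3,
                           n_nulls = 0, seed = 1L) {
  rows <- lapply(connectomes, function(sc) tryCatch({
    nets <- construct_subject_networks(sc, parcellation, threshold)
    do.call(rbind, lapply(nets, function(net) {
      ms <- compute_metric_set(net)
      glob <- data.frame(subject_id = sc$subject_id,
                         hemisphere = net$hemisphere,
                         metric = c("Cp", "Lp", "Eg", "Eloc"),
                         node = NA_character_,
                         value = c(ms$Cp, ms$Lp, ms$Eg, ms$Eloc),
                         stringsAsFactors = FALSE)
      nod <- data.frame(subject_id = sc$subject_id,
                        hemisphere = net$hemisphere,
                        metric = "Enodal", node = names(ms$Enodal),
                        value = as.numeric(ms$Enodal),
                        stringsAsFactors = FALSE)
      if (n_nulls > 0) {
        set.seed(derive_seed(seed, sc$subject_id, net$hemisphere))
        sw <- normalized_small_world(net, n_nulls = n_nulls)
        glob <- rbind(glob, data.frame(
          subject_id = sc$subject_id, hemisphere = net$hemisphere,
          metric = c("gamma", "lambda", "sigma"), node = NA_character_,
          value = c(sw$gamma, sw$lambda, sw$sigma),
          stringsAsFactors = FALSE))
      }
      rbind(glob, nod)
    }))
  }, error = function(e)
    stop("subject ", sc$subject_id, ": ", conditionMessage(e),
         call. = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Deterministic per-(subject, hemisphere) stream: fold a string key into a
# 31-bit offset added to the master seed.
derive_seed <- function(seed, ...) {
  key <- paste(..., collapse = "|")
  h <- sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}
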