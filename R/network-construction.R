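#' Hemispheric network construction
#'
#' Whole-brain connectomes arrive as two square symmetric matrices: a
#' fiber-number (FN) matrix of streamline counts and a fractional-anisotropy
#' (FA) matrix of edge weights in `[0, 1]`. Construction keeps an edge only
#' when its fiber count is strictly larger than the threshold (default 3,
#' suppressing likely pseudo-connections from tractography noise), discards
#' every inter-hemispheric connection, and returns one weighted network per
#' hemisphere.
#'
#' @name network_construction
NULL

SYMMETRY_TOL <- 1e-8

check_symmetric <- function(m, what = "matrix", tol = SYMMETRY_TOL) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop(what, " is asymmetric beyond tolerance ", format(tol))
  invisible(m)
}

#' Apply the fiber-number threshold to an FA matrix
#'
#' An edge survives iff its fiber count is strictly greater than
#' `threshold`; surviving edges keep their FA weight, all others are set
#' to zero.
#'
#' @param fn square symmetric matrix of nonnegative fiber counts
#' @param fa square symmetric matrix of FA weights in `[0, 1]`
#' @param threshold fiber-count cutoff (strict `>`); default 3
#' @return thresholded FA adjacency matrix
#' @export
apply_fn_threshold <- function(fn, fa, threshold = 3) {
  check_symmetric(fn, "fn")
  check_symmetric(fa, "fa")
  if (!all(dim(fn) == dim(fa))) stop("fn and fa dimensions differ")
  out <- fa
  out[fn <= threshold] <- 0
  diag(out) <- 0
  out
}

#' A single hemispheric weighted network
#'
#' @param hemisphere `"L"` or `"R"`
#' @param adjacency square symmetric FA-weight matrix, zero diagonal
#' @param node_labels region abbreviations in matrix order
#' @return a `hemispheric_network` object
#' @export
hemispheric_network <- function(hemisphere, adjacency, node_labels) {
  stopifnot(hemisphere %in% c("L", "R"))
  check_symmetric(adjacency, "adjacency")
  if (length(node_labels) != nrow(adjacency))
    stop("node_labels length must match adjacency dimension")
  if (any(adjacency < 0) || any(adjacency > 1))
    stop("adjacency weights must lie in [0, 1]")
  diag(adjacency) <- 0
  dimnames(adjacency) <- list(node_labels, node_labels)
  structure(list(hemisphere = hemisphere, adjacency = adjacency,
                 node_labels = node_labels),
            class = "hemispheric_network")
}

#' @export
print.hemispheric_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  e <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat(sprintf("<hemispheric_network %s: %d nodes, %d edges, density %.3f>\n",
              x$hemisphere, n, e, e / (n * (n - 1) / 2)))
  invisible(x)
}

#' Split a whole-brain adjacency into hemispheric networks
#'
#' Removes every inter-hemispheric entry and returns the two
#' intra-hemisphere blocks, with nodes ordered by their position in the
#' parcellation so that homotopic left/right regions occupy the same index
#' in both outputs.
#'
#' @param adjacency whole-brain square symmetric matrix
#' @param parcellation a [parcellation()] matching the matrix dimension
#' @return list with elements `L` and `R`, each a `hemispheric_network`
#' @export
split_hemispheres <- function(adjacency, parcellation) {
  check_symmetric(adjacency, "adjacency")
  parcellation <- validate_parcellation(parcellation)
  if (nrow(adjacency) != nrow(parcellation))
    stop(sprintf("matrix dimension %d does not match parcellation size %d",
                 nrow(adjacency), nrow(parcellation)))
  out <- lapply(c(L = "L", R = "R"), function(h) {
    idx <- parcellation$index[parcellation$hemisphere == h] + 1L
    hemispheric_network(h, adjacency[idx, idx, drop = FALSE],
                        parcellation$abbrev[parcellation$hemisphere == h])
  })
  out
}

#' Construct both hemispheric networks for one subject
#'
#' Composition of [apply_fn_threshold()] and [split_hemispheres()]
#' (the two operations commute).
#'
#' @param connectome a `subject_connectome` (see [generate_subject()]) or a
#'   list with elements `fn` and `fa`
#' @param parcellation a [parcellation()]
#' @param threshold fiber-count cutoff, default 3
#' @return list with elements `L` and `R`
#' @export
construct_subject_networks <- function(connectome, parcellation,
                                       threshold = 3) {
  adj <- apply_fn_threshold(connectome$fn, connectome$fa, threshold)
  split_hemispheres(adj, parcellation)
}
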