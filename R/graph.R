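#' Spatial neighbor networks
#'
#' A `neighbor_graph` is a sparse symmetric binary adjacency matrix over
#' spots, with self-loops, built either from a distance radius or from
#' symmetrized k-nearest neighbors in tissue coordinates. Pruning it with
#' expression-based precluster labels yields the cell-type-aware variant
#' used to compute a second, expression-aware attention stream.
#'
#' @param adjacency sparse n x n 0/1 matrix (dgCMatrix), symmetric, unit
#'   diagonal when `has_self_loops`.
#' @param kind `"radius"` or `"knn"`.
#' @param param the radius or k used.
#' @param has_self_loops logical.
#' @param pruned_with optional fingerprint of the precluster labels used
#'   to prune (set by [prune_to_ctasnn()]).
#' @return An object of class `neighbor_graph`.
#' @keywords internal
neighbor_graph <- function(adjacency, kind, param, has_self_loops = TRUE,
                           pruned_with = NULL) {
  adjacency <- methods::as(methods::as(adjacency, "CsparseMatrix"), "generalMatrix")
  adjacency@x[] <- 1
  structure(list(adjacency = adjacency, kind = kind, param = param,
                 has_self_loops = has_self_loops, pruned_with = pruned_with),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  ne <- (Matrix::nnzero(x$adjacency) - if (x$has_self_loops) n else 0L) / 2
  cat(sprintf("neighbor_graph (%s, param=%s): %d spots, %d undirected edges%s\n",
              x$kind, format(x$param), n, ne,
              if (!is.null(x$pruned_with)) ", cell-type-aware (pruned)" else ""))
  invisible(x)
}

check_coords <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("coords must be n x 2")
  if (!all(is.finite(coords))) stop("coords contain non-finite values")
  coords
}

#' Build a spatial neighbor network from a distance radius
#'
#' Connects every pair of spots whose Euclidean distance is strictly less
#' than `rad_cutoff`, then adds a self-loop to every spot.
#'
#' @param coords n x 2 spot coordinates.
#' @param rad_cutoff positive distance cutoff (strict `<`).
#' @return A `neighbor_graph` of kind `"radius"`.
#' @export
build_radius_graph <- function(coords, rad_cutoff) {
  coords <- check_coords(coords)
  stopifnot(rad_cutoff > 0, nrow(coords) >= 2L)
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  A <- (D < rad_cutoff) * 1
  diag(A) <- 1
  neighbor_graph(methods::as(A, "CsparseMatrix"), "radius", rad_cutoff)
}

#' Build a spatial neighbor network from k nearest neighbors
#'
#' Each spot selects its `k` nearest neighbors by Euclidean distance (ties
#' broken by lower spot index); the directed graph is symmetrized by union
#' and self-loops are added. `k = 6` matches the hexagonal packing of
#' Visium arrays, where each interior spot has six equidistant neighbors.
#'
#' @param coords n x 2 spot coordinates.
#' @param k neighbors per spot, `1 <= k < n`.
#' @return A `neighbor_graph` of kind `"knn"`.
#' @export
build_knn_graph <- function(coords, k = 6) {
  coords <- check_coords(coords)
  n <- nrow(coords)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n (n = ", n, ")")
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]  # order() breaks ties by lower index
    ei <- c(ei, rep.int(i, k)); ej <- c(ej, nb)
  }
  A <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = 1, dims = c(n, n))
  A <- methods::as(A, "CsparseMatrix")
  A@x[] <- 1
  A <- A + Matrix::Diagonal(n)
  A@x[] <- 1
  neighbor_graph(A, "knn", k)
}

#' Precluster spots on expression alone
#'
#' Runs Louvain community detection on a k-nearest-neighbor similarity
#' graph built from the top principal components of the normalized
#' expression matrix — no spatial information is used. The resulting
#' labels identify expression "cell-type" groups used to prune the
#' spatial graph into its cell-type-aware form.
#'
#' @param ds a normalized [spot_dataset()].
#' @param resolution Louvain resolution (default 1.0).
#' @param seed integer RNG seed; the result is deterministic given the seed.
#' @param n_pcs number of principal components (default 30, reduced with a
#'   warning if the data are smaller).
#' @param knn_k neighbors in the expression k-NN graph (default 15).
#' @return Integer vector of 0-based cluster labels.
#' @export
precluster_expression <- function(ds, resolution = 1.0, seed = 0,
                                  n_pcs = 30, knn_k = 15) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (!ds$normalized) stop("precluster_expression expects normalized data")
  n <- nrow(ds$X)
  max_pcs <- min(n - 1L, ncol(ds$X))
  if (n_pcs > max_pcs) {
    warning("reducing n_pcs from ", n_pcs, " to ", max_pcs)
    n_pcs <- max_pcs
  }
  pcs <- stats::prcomp(ds$X, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  k <- min(knn_k, n - 1L)
  g <- knn_igraph(pcs, k)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(comm)) - 1L
}

# undirected union k-NN igraph on rows of Z (used for preclustering and for
# Louvain/Leiden domain calling on embeddings)
knn_igraph <- function(Z, k) {
  n <- nrow(Z)
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  ej <- vapply(seq_len(n), function(i) order(D[i, ])[seq_len(k)], integer(k))
  el <- cbind(rep(seq_len(n), each = k), as.vector(ej))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(igraph::add_vertices(g, max(0L, n - igraph::vcount(g))))
}

#' Prune a spatial graph into its cell-type-aware form
#'
#' Removes every non-loop edge whose endpoints carry different precluster
#' labels. Self-loops are always retained: a spot is its own neighbor.
#'
#' @param graph a `neighbor_graph` with self-loops.
#' @param precluster_labels integer labels per spot (e.g. from
#'   [precluster_expression()]).
#' @return A pruned `neighbor_graph` with `pruned_with` set to a
#'   fingerprint of the labels.
#' @export
prune_to_ctasnn <- function(graph, precluster_labels) {
  stopifnot(inherits(graph, "neighbor_graph"))
  n <- nrow(graph$adjacency)
  if (length(precluster_labels) != n)
    stop("labels length ", length(precluster_labels), " != n spots ", n)
  tr <- methods::as(graph$adjacency, "TsparseMatrix")
  i <- tr@i + 1L; j <- tr@j + 1L
  keep <- (i == j) | (precluster_labels[i] == precluster_labels[j])
  A <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1, dims = c(n, n))
  fp <- sprintf("k%d-%s", length(unique(precluster_labels)),
                substr(paste(precluster_labels, collapse = ""), 1, 32))
  neighbor_graph(A, graph$kind, graph$param, graph$has_self_loops, pruned_with = fp)
}

#' Export a neighbor graph as an edge-list TSV
#'
#' Writes one `(i, j)` row per non-zero adjacency entry (1-based indices).
#'
#' @param graph a `neighbor_graph`.
#' @param path output TSV path.
#' @export
write_edge_list <- function(graph, path) {
  tr <- methods::as(graph$adjacency, "TsparseMatrix")
  utils::write.table(data.frame(i = tr@i + 1L, j = tr@j + 1L),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a neighbor graph back from an edge-list TSV
#'
#' @param path TSV with columns `i`, `j` (1-based spot indices).
#' @param n number of spots (defaults to the largest index seen).
#' @return A `neighbor_graph` with the stored adjacency.
#' @export
read_edge_list <- function(path, n = NULL) {
  el <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(n)) n <- max(el$i, el$j)
  A <- Matrix::sparseMatrix(i = el$i, j = el$j, x = 1, dims = c(n, n))
  neighbor_graph(A, "imported", NA_real_,
                 has_self_loops = all(Matrix::diag(A) == 1))
}
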