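#' Cluster spot embeddings into spatial domains
#'
#' Dispatches on `method`: `"louvain"` and `"leiden"` build a 15-nearest-
#' neighbor graph on the embedding rows and run the corresponding
#' community detection at the given `resolution`; `"gmm"` (alias
#' `"mclust"`) fits a finite Gaussian mixture with `param` components via
#' \pkg{mclust}. All routes are deterministic given `seed`.
#'
#' @param Z n x d embedding matrix.
#' @param method one of `"louvain"`, `"leiden"`, `"gmm"`, `"mclust"`.
#' @param param resolution (louvain/leiden) or number of components (gmm).
#' @param seed RNG seed.
#' @param knn_k neighbors for the embedding graph (default 15).
#' @return A `domain_assignment` list: `labels` (0-based contiguous
#'   integers), `method`, `param`, `refined = FALSE`.
#' @export
cluster_embeddings <- function(Z, method = c("louvain", "leiden", "gmm", "mclust"),
                               param = 1.0, seed = 0, knn_k = 15) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (method %in% c("louvain", "leiden")) {
    g <- knn_igraph(Z, min(knn_k, n - 1L))
    set.seed(seed)
    comm <- if (method == "louvain")
      igraph::cluster_louvain(g, resolution = param)
    else
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = param, n_iterations = 5)
    labels <- as.integer(igraph::membership(comm))
  } else {
    set.seed(seed)
    mclustBIC <- mclust::mclustBIC   # Mclust() looks this up in the caller
    fitted <- mclust::Mclust(Z, G = as.integer(param), verbose = FALSE)
    if (is.null(fitted)) stop("Gaussian mixture fit failed")
    labels <- as.integer(fitted$classification)
  }
  labels <- as.integer(factor(labels)) - 1L   # 0-based, contiguous
  structure(list(labels = labels, method = method, param = param,
                 refined = FALSE, r_refine = NA_real_),
            class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat(sprintf("domain_assignment (%s, param=%s): %d spots, %d domains%s\n",
              x$method, format(x$param), length(x$labels),
              length(unique(x$labels)),
              if (isTRUE(x$refined)) sprintf(", refined (r=%g)", x$r_refine) else ""))
  invisible(x)
}

#' Tune the clustering resolution to reach a target domain count
#'
#' Bisection search on the resolution in `[0.05, 5]` (at most 60
#' community-detection runs), exploiting that the number of communities
#' is non-decreasing in the resolution. Returns the first assignment with
#' exactly `target_k` domains, otherwise the assignment whose domain
#' count is closest, flagged with `warning_closest = TRUE`.
#'
#' @param Z n x d embedding matrix.
#' @param method `"louvain"` or `"leiden"`.
#' @param target_k desired number of domains (at least 2).
#' @param seed RNG seed.
#' @param lo,hi resolution search bounds.
#' @param max_eval evaluation budget (default 60).
#' @return A `domain_assignment` (with `warning_closest` set if inexact).
#' @export
tune_resolution <- function(Z, method = c("louvain", "leiden"), target_k,
                            seed = 0, lo = 0.05, hi = 5.0, max_eval = 60) {
  method <- match.arg(method)
  if (target_k < 2) stop("target_k must be at least 2")
  if (target_k > nrow(Z)) stop("target_k exceeds the number of spots")
  best <- NULL; best_gap <- Inf
  eval_at <- function(res) {
    da <- cluster_embeddings(Z, method, param = res, seed = seed)
    k <- length(unique(da$labels))
    gap <- abs(k - target_k)
    if (gap < best_gap) { best <<- da; best_gap <<- gap }
    list(da = da, k = k)
  }
  e_lo <- eval_at(lo); e_hi <- eval_at(hi)
  if (e_lo$k == target_k) return(e_lo$da)
  if (e_hi$k == target_k) return(e_hi$da)
  n_eval <- 2L
  while (n_eval < max_eval && (hi - lo) > 1e-4) {
    mid <- (lo + hi) / 2
    e <- eval_at(mid); n_eval <- n_eval + 1L
    if (e$k == target_k) return(e$da)
    if (e$k < target_k) lo <- mid else hi <- mid
  }
  best$warning_closest <- TRUE
  warning("no resolution in [", lo, ", ", hi, "] gave exactly ", target_k,
          " domains; returning closest (", length(unique(best$labels)), ")")
  best
}

#' Refine domain labels by neighborhood majority vote
#'
#' A single simultaneous pass over the input labels: each spot is
#' reassigned to the most frequent label among the spots within distance
#' `r_refine` (itself excluded). Ties keep the spot's own label when it
#' is among the modal labels, otherwise the lowest label id wins. Spots
#' with no neighbor in the radius keep their label. The vote is always
#' computed from the pre-refinement labels, so the result does not depend
#' on spot order.
#'
#' @param labels integer labels per spot (0-based).
#' @param coords n x 2 spot coordinates.
#' @param r_refine neighborhood radius in coordinate units (default 50,
#'   matching full-resolution Visium pixel coordinates).
#' @return Refined integer label vector.
#' @export
refine_by_neighborhood <- function(labels, coords, r_refine = 50) {
  stopifnot(r_refine > 0)
  coords <- check_coords(coords)
  n <- nrow(coords)
  if (length(labels) != n) stop("labels length != number of spots")
  labels <- as.integer(labels)
  D <- as.matrix(stats::dist(coords))
  out <- labels
  for (i in seq_len(n)) {
    nb <- which(D[i, ] <= r_refine)
    nb <- nb[nb != i]
    if (!length(nb)) next
    tab <- table(labels[nb])
    modal <- as.integer(names(tab)[tab == max(tab)])
    out[i] <- if (labels[i] %in% modal) labels[i] else min(modal)
  }
  out
}
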