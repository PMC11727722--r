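#' Adjusted Rand index between two labelings
#'
#' Chance-corrected partition agreement,
#' `ARI = (RI - E[RI]) / (max(RI) - E[RI])`, computed via the standard
#' contingency-table form. Invariant to permuting label ids and symmetric
#' in its arguments; 1 iff the partitions are identical up to relabeling.
#'
#' @param labels_a,labels_b label vectors of equal length (>= 2).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 elements")
  ct <- table(labels_a, labels_b)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

cluster_stats <- function(Z, labels) {
  Z <- as.matrix(Z)
  labs <- sort(unique(labels))
  if (length(labs) < 2) stop("need at least 2 clusters")
  cent <- t(vapply(labs, function(l) colMeans(Z[labels == l, , drop = FALSE]),
                   numeric(ncol(Z))))
  list(labs = labs, cent = cent, k = length(labs))
}

#' Davies-Bouldin index
#'
#' For each cluster, the similarity to its most similar other cluster is
#' `(s_i + s_j) / d_ij`, where `s_i` is the mean Euclidean distance of the
#' cluster's points to its centroid and `d_ij` the distance between
#' centroids; DB is the average of these maxima. Lower is better.
#'
#' @param Z n x d data/embedding matrix.
#' @param labels cluster labels (>= 2 non-empty clusters).
#' @return Non-negative scalar.
#' @export
davies_bouldin <- function(Z, labels) {
  cs <- cluster_stats(Z, labels)
  s <- vapply(seq_len(cs$k), function(i) {
    pts <- Z[labels == cs$labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2L, cs$cent[i, ])^2)))
  }, numeric(1))
  d <- as.matrix(stats::dist(cs$cent))
  r <- numeric(cs$k)
  for (i in seq_len(cs$k)) {
    vals <- numeric(0)
    for (j in seq_len(cs$k)) {
      if (i == j) next
      if (d[i, j] == 0)
        stop("coincident centroids for clusters ", cs$labs[i], " and ", cs$labs[j])
      vals <- c(vals, (s[i] + s[j]) / d[i, j])
    }
    r[i] <- max(vals)
  }
  mean(r)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion,
#' `CH = (B / (k - 1)) / (W / (n - k))` with
#' `B = sum_i n_i ||c_i - c||^2` and `W = sum_i sum_{x in i} ||x - c_i||^2`.
#' Higher is better; invariant to global scaling of the coordinates.
#'
#' @inheritParams davies_bouldin
#' @return Non-negative scalar.
#' @export
calinski_harabasz <- function(Z, labels) {
  Z <- as.matrix(Z)
  cs <- cluster_stats(Z, labels)
  n <- nrow(Z)
  if (cs$k >= n) stop("need k < n")
  gmean <- colMeans(Z)
  B <- 0; W <- 0
  for (i in seq_len(cs$k)) {
    pts <- Z[labels == cs$labs[i], , drop = FALSE]
    B <- B + nrow(pts) * sum((cs$cent[i, ] - gmean)^2)
    W <- W + sum(sweep(pts, 2L, cs$cent[i, ])^2)
  }
  if (W == 0) stop("degenerate within-cluster scatter (W = 0)")
  (B / (cs$k - 1)) / (W / (n - cs$k))
}

#' S_Dbw validity index
#'
#' Sum of intra-cluster scattering and inter-cluster density
#' (Halkidi-Vazirgiannis 2001 formulation):
#' `Scat = (1/k) sum_i ||sigma(c_i)|| / ||sigma(D)||` with per-dimension
#' variance vectors, and `Dens_bw` compares the point density at the
#' midpoint of each centroid pair with the density at the two centroids,
#' counting points of the two clusters within a radius equal to the mean
#' cluster standard-deviation norm. Lower is better. Pairs where both
#' centroid densities are zero contribute zero.
#'
#' @inheritParams davies_bouldin
#' @return Non-negative scalar.
#' @export
s_dbw <- function(Z, labels) {
  Z <- as.matrix(Z)
  cs <- cluster_stats(Z, labels)
  k <- cs$k
  sig_all <- apply(Z, 2L, function(col) mean((col - mean(col))^2))
  if (sum(sig_all) == 0) stop("zero global variance")
  sig_i <- lapply(seq_len(k), function(i) {
    pts <- Z[labels == cs$labs[i], , drop = FALSE]
    apply(pts, 2L, function(col) mean((col - mean(col))^2))
  })
  nrm <- vapply(sig_i, function(s) sqrt(sum(s^2)), numeric(1))
  scat <- mean(nrm / sqrt(sum(sig_all^2)))
  stdev <- sqrt(sum(nrm)) / k
  density_at <- function(u, members) {
    d <- sqrt(rowSums(sweep(Z[members, , drop = FALSE], 2L, u)^2))
    sum(d <= stdev)
  }
  dens <- 0; n_pairs <- 0L
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    members <- which(labels %in% cs$labs[c(i, j)])
    dij <- density_at((cs$cent[i, ] + cs$cent[j, ]) / 2, members)
    dmax <- max(density_at(cs$cent[i, ], members),
                density_at(cs$cent[j, ], members))
    dens <- dens + if (dmax > 0) dij / dmax else 0
    n_pairs <- n_pairs + 1L
  }
  dens_bw <- dens / n_pairs
  scat + dens_bw
}

#' Compute a full clustering validity report
#'
#' @param Z n x d embedding matrix.
#' @param labels predicted cluster labels.
#' @param truth optional reference labels; when given, ARI is included.
#' @return A list with `db`, `ch`, `s_dbw` and (optionally) `ari`.
#' @export
metrics_report <- function(Z, labels, truth = NULL) {
  out <- list(db = davies_bouldin(Z, labels),
              ch = calinski_harabasz(Z, labels),
              s_dbw = s_dbw(Z, labels))
  if (!is.null(truth)) out$ari <- adjusted_rand_index(labels, truth)
  out
}
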