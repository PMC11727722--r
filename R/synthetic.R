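#' Specification for a synthetic layered tissue
#'
#' Describes a lattice of spots partitioned into spatially contiguous
#' domains with domain-specific marker-gene programs and Poisson (or
#' Gaussian) count noise — a download-free stand-in for layered tissue
#' such as cortical sections. Nearest-neighbor lattice distance is
#' normalized to 1, so graph radii and refinement radii are interpreted
#' in lattice units.
#'
#' @param rows,cols lattice extent (default 30 x 30).
#' @param k_domains number of domains (>= 2; default 4).
#' @param geometry `"bands"` (horizontal layers) or `"voronoi"` (cells of
#'   k random seed points).
#' @param lattice `"square"` or `"hex"` (offset rows, unit spacing).
#' @param n_genes total genes (default 60).
#' @param markers_per_domain marker genes per domain (default 10; the
#'   marker blocks must fit into `n_genes`).
#' @param baseline_mean baseline Poisson mean per gene (default 1).
#' @param marker_effect additive mean shift of a marker inside its domain
#'   (default `5 * baseline_mean`).
#' @param noise `"poisson"` (counts) or `"gaussian"`.
#' @param noise_sigma Gaussian sd when `noise = "gaussian"`.
#' @param seed RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(rows = 30, cols = 30, k_domains = 4,
                           geometry = c("bands", "voronoi"),
                           lattice = c("square", "hex"),
                           n_genes = 60, markers_per_domain = 10,
                           baseline_mean = 1,
                           marker_effect = 5 * baseline_mean,
                           noise = c("poisson", "gaussian"),
                           noise_sigma = 0.5, seed = 0) {
  geometry <- match.arg(geometry)
  lattice <- match.arg(lattice)
  noise <- match.arg(noise)
  if (k_domains < 2) stop("k_domains must be at least 2")
  if (markers_per_domain * k_domains > n_genes)
    stop("marker blocks (", markers_per_domain * k_domains,
         ") exceed n_genes (", n_genes, ")")
  structure(list(rows = rows, cols = cols, k_domains = k_domains,
                 geometry = geometry, lattice = lattice, n_genes = n_genes,
                 markers_per_domain = markers_per_domain,
                 baseline_mean = baseline_mean, marker_effect = marker_effect,
                 noise = noise, noise_sigma = noise_sigma, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic layered tissue
#'
#' Places spots on a lattice, assigns each to a spatially contiguous
#' domain, and draws counts: every gene has mean `baseline_mean`, and a
#' domain's markers have mean `baseline_mean + marker_effect` inside that
#' domain. Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A raw-count [spot_dataset()] with `truth_labels`, plus an
#'   attribute `marker_map` (list: domain -> marker gene ids).
#' @export
generate_layered_tissue <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  rows <- spec$rows; cols <- spec$cols; k <- spec$k_domains
  rc <- expand.grid(col = seq_len(cols) - 1L, row = seq_len(rows) - 1L)
  if (spec$lattice == "hex") {
    x <- rc$col + 0.5 * (rc$row %% 2)
    y <- rc$row * sqrt(3) / 2
  } else {
    x <- rc$col; y <- rc$row
  }
  coords <- cbind(x = x, y = y)
  n <- nrow(coords)
  if (spec$geometry == "bands") {
    # equal-sized bands along y: spots are in row-major order, so chunking
    # the index range gives contiguous layers of exactly n/k spots
    labels <- floor((seq_len(n) - 1L) * k / n)
  } else {
    seeds <- cbind(stats::runif(k, min(x), max(x)),
                   stats::runif(k, min(y), max(y)))
    d2 <- outer(x, seeds[, 1], "-")^2 + outer(y, seeds[, 2], "-")^2
    labels <- max.col(-d2) - 1L
  }
  labels <- as.integer(labels)
  g <- spec$n_genes
  mu <- matrix(spec$baseline_mean, n, g)
  marker_map <- vector("list", k)
  for (d in seq_len(k) - 1L) {
    idx <- d * spec$markers_per_domain + seq_len(spec$markers_per_domain)
    marker_map[[d + 1L]] <- paste0("gene_", idx)
    mu[labels == d, idx] <- spec$baseline_mean + spec$marker_effect
  }
  X <- if (spec$noise == "poisson") {
    matrix(stats::rpois(n * g, as.vector(mu)), n, g)
  } else {
    pmax(mu + matrix(stats::rnorm(n * g, sd = spec$noise_sigma), n, g), 0)
  }
  ds <- spot_dataset(X, coords,
                     spot_ids = paste0("spot_", seq_len(n)),
                     gene_ids = paste0("gene_", seq_len(g)),
                     truth_labels = labels)
  attr(ds, "marker_map") <- stats::setNames(marker_map, paste0("domain_", seq_len(k) - 1L))
  ds
}

#' Sample points from a union of low-dimensional linear subspaces
#'
#' Draws `k` random (optionally mutually orthogonal) orthonormal bases of
#' dimension `sub_dim` in `ambient_dim` and samples `n_per` points per
#' subspace as `basis %*% coeffs + noise`. Exercises the self-expression
#' premise: with zero noise every point lies exactly in the span of its
#' subspace.
#'
#' @param k number of subspaces.
#' @param sub_dim subspace dimension (< `ambient_dim`).
#' @param ambient_dim ambient dimension.
#' @param n_per points per subspace.
#' @param noise_sigma Gaussian noise sd (0 = exact).
#' @param orthogonal if `TRUE`, bases are carved from one orthonormal
#'   frame, so the subspaces are mutually orthogonal (requires
#'   `k * sub_dim <= ambient_dim`).
#' @param seed RNG seed.
#' @return A list with `X` (n x ambient matrix), `truth` (0-based
#'   subspace index) and `bases` (list of basis matrices).
#' @export
generate_subspace_points <- function(k = 2, sub_dim = 2, ambient_dim = 6,
                                     n_per = 20, noise_sigma = 0,
                                     orthogonal = FALSE, seed = 0) {
  if (sub_dim >= ambient_dim) stop("sub_dim must be < ambient_dim")
  if (orthogonal && k * sub_dim > ambient_dim)
    stop("orthogonal bases need k * sub_dim <= ambient_dim")
  set.seed(seed)
  bases <- vector("list", k)
  if (orthogonal) {
    Q <- qr.Q(qr(matrix(stats::rnorm(ambient_dim^2), ambient_dim)))
    for (i in seq_len(k))
      bases[[i]] <- Q[, (i - 1) * sub_dim + seq_len(sub_dim), drop = FALSE]
  } else {
    for (i in seq_len(k))
      bases[[i]] <- qr.Q(qr(matrix(stats::rnorm(ambient_dim * sub_dim),
                                   ambient_dim)))[, seq_len(sub_dim), drop = FALSE]
  }
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    coeff <- matrix(stats::rnorm(sub_dim * n_per), sub_dim, n_per)
    t(bases[[i]] %*% coeff)
  }))
  if (noise_sigma > 0)
    X <- X + matrix(stats::rnorm(length(X), sd = noise_sigma), nrow(X))
  list(X = X, truth = rep(seq_len(k) - 1L, each = n_per), bases = bases)
}

#' Randomly corrupt a fraction of labels
#'
#' Reassigns exactly `round(frac * n)` randomly chosen spots to a
#' uniformly random *different* label drawn from the labels present in
#' the input. Used to probe neighborhood refinement.
#'
#' @param labels integer label vector.
#' @param frac fraction to corrupt, `0 <= frac < 1`.
#' @param seed RNG seed.
#' @return A list with `labels` (corrupted) and `idx` (corrupted
#'   positions).
#' @export
corrupt_labels <- function(labels, frac, seed = 0) {
  if (frac < 0 || frac >= 1) stop("frac must be in [0, 1)")
  labels <- as.integer(labels)
  n <- length(labels)
  n_flip <- round(frac * n)
  if (n_flip == 0) return(list(labels = labels, idx = integer(0)))
  pool <- sort(unique(labels))
  if (length(pool) < 2) stop("cannot corrupt a single-label vector")
  set.seed(seed)
  idx <- sample.int(n, n_flip)
  out <- labels
  for (i in idx)
    out[i] <- sample(setdiff(pool, labels[i]), 1L)
  list(labels = out, idx = idx)
}
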