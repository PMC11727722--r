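#' Multiscale self-expression loss
#'
#' Under the union-of-subspaces assumption each spot's embedding can be
#' written as a linear combination of the other spots' embeddings
#' (`Z ~ C Z` with a zero diagonal so no spot expresses itself). The
#' multiscale loss averages the self-expression residual over every
#' encoder layer: `L_mss = (1 / 2L) * sum_k || Z_k - C_k Z_k ||_F^2`.
#'
#' @param Z_list list of n x d_k embedding matrices.
#' @param C_list list of n x n self-expression matrices with zero
#'   diagonals (a non-zero diagonal is a contract violation and errors).
#' @return Non-negative scalar.
#' @export
self_expression_loss <- function(Z_list, C_list) {
  L <- length(Z_list)
  if (length(C_list) != L) stop("Z_list and C_list lengths differ")
  for (k in seq_len(L))
    if (any(diag(C_list[[k]]) != 0))
      stop("C_list[[", k, "]] has a non-zero diagonal")
  tot <- 0
  for (k in seq_len(L))
    tot <- tot + sum((Z_list[[k]] - C_list[[k]] %*% Z_list[[k]])^2)
  tot / (2 * L)
}

#' Regularization of the self-expression matrices
#'
#' `L_reg = (1/L) * sum_k || C_k ||_p`, discouraging degenerate (overly
#' sparse or exploding) coefficients. `norm_p = "fro"` (Frobenius norm,
#' the default) is smooth and standard in deep subspace clustering;
#' `"l1"` gives the entrywise absolute sum.
#'
#' @param C_list list of n x n self-expression matrices.
#' @param norm_p `"fro"` or `"l1"`.
#' @return Non-negative scalar.
#' @export
coefficient_regularization <- function(C_list, norm_p = c("fro", "l1")) {
  norm_p <- match.arg(norm_p)
  f <- switch(norm_p,
              fro = function(C) sqrt(sum(C^2)),
              l1 = function(C) sum(abs(C)))
  sum(vapply(C_list, f, numeric(1))) / length(C_list)
}

#' Fuse per-layer self-expression matrices
#'
#' Convex combination with trainable positive weights:
#' `C_F = sum_k tau_k C_k / sum_k tau_k`.
#'
#' @param C_list list of n x n matrices.
#' @param tau positive fusion weights, one per layer.
#' @return Fused n x n matrix.
#' @export
fuse_coefficients <- function(C_list, tau) {
  L <- length(C_list)
  if (length(tau) != L) stop("tau length must match C_list")
  if (any(tau <= 0)) stop("fusion weights tau must be positive")
  out <- 0
  for (k in seq_len(L)) out <- out + tau[k] * C_list[[k]]
  out / sum(tau)
}

#' Build the spectral-clustering affinity from the fused coefficients
#'
#' `Lambda = 0.5 * (|C_F| + |t(C_F)|)`: symmetric, entrywise non-negative,
#' zero diagonal whenever `diag(C_F) = 0`.
#'
#' @param C_F fused self-expression matrix (square).
#' @return Affinity matrix `Lambda`.
#' @export
build_affinity <- function(C_F) {
  C_F <- as.matrix(C_F)
  if (nrow(C_F) != ncol(C_F)) stop("C_F must be square")
  0.5 * (abs(C_F) + abs(t(C_F)))
}

#' Normalized spectral clustering of an affinity matrix
#'
#' Forms the symmetric normalized Laplacian of `Lambda`, takes the
#' eigenvectors of its `m` smallest eigenvalues, row-normalizes them and
#' runs k-means (`nstart = 10`). Deterministic given the seed.
#'
#' @param Lambda symmetric non-negative affinity matrix.
#' @param m number of clusters, `2 <= m <= n`.
#' @param seed RNG seed for k-means.
#' @return Integer vector of 0-based cluster labels.
#' @export
spectral_cluster <- function(Lambda, m, seed = 0) {
  Lambda <- as.matrix(Lambda)
  n <- nrow(Lambda)
  if (m < 2) stop("m must be at least 2")
  if (m > n) stop("m exceeds the number of samples")
  if (any(Lambda < 0)) stop("Lambda must be non-negative")
  if (max(abs(Lambda - t(Lambda))) > 1e-8) stop("Lambda must be symmetric")
  deg <- rowSums(Lambda)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  # m smallest eigenvalues of L_sym = I - D^-1/2 Lambda D^-1/2
  # equal the m largest of the normalized affinity
  Ms <- Lambda * (dinv %o% dinv)
  ev <- eigen((Ms + t(Ms)) / 2, symmetric = TRUE)
  U <- ev$vectors[, seq_len(m), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn > 0, rn, 1)
  set.seed(seed)
  km <- stats::kmeans(U, centers = m, nstart = 10, iter.max = 100)
  as.integer(km$cluster) - 1L
}

#' Fit a single-layer self-expression matrix on frozen embeddings
#'
#' Minimizes `0.5 * ||Z - C Z||_F^2 + beta * pen(C)` over `C` with the
#' diagonal constrained to zero, by Adam gradient descent. With
#' `penalty = "fro2"` (squared Frobenius) the problem is a
#' diagonal-constrained ridge regression with a closed-form solution per
#' row, which the iterative solution converges to; `"fro"` uses the
#' (unsquared) Frobenius norm matching [coefficient_regularization()].
#'
#' @param Z n x d embedding matrix (rows are samples).
#' @param beta regularization strength.
#' @param penalty `"fro2"` or `"fro"`.
#' @param epochs gradient steps (default 2000).
#' @param lr Adam learning rate.
#' @param seed RNG seed for the (tiny) random initialization.
#' @return n x n coefficient matrix with zero diagonal.
#' @export
fit_self_expression <- function(Z, beta = 1, penalty = c("fro2", "fro"),
                                epochs = 2000, lr = 0.01, seed = 0) {
  penalty <- match.arg(penalty)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  set.seed(seed)
  C <- matrix(stats::rnorm(n * n, sd = 1e-4), n, n)
  diag(C) <- 0
  st <- adam_state(list(C = C))
  for (it in seq_len(epochs)) {
    R <- Z - C %*% Z
    g <- -R %*% t(Z)
    g <- g + switch(penalty,
                    fro2 = 2 * beta * C,
                    fro = beta * C / max(sqrt(sum(C^2)), 1e-12))
    diag(g) <- 0
    upd <- adam_step(st, list(C = g), lr)
    st <- upd$state
    C <- upd$params$C
    diag(C) <- 0
  }
  C
}

# --- Adam optimizer over named lists of arrays --------------------------

adam_state <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zero <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(params = params, m = zero, v = zero, t = 0L,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(state, grads, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    state$params[[nm]] <- state$params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = state$params)
}
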