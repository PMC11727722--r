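#' Initialize the self-supervised classifier head
#'
#' Three hidden fully connected layers with ReLU activations followed by
#' a softmax output over the `m` clusters: dimensions
#' `d_in x D1 x D2 x D3 x m`.
#'
#' @param d_in input (embedding) dimension.
#' @param m number of clusters / output classes.
#' @param dims the three hidden widths; default `c(128, 64, 32)`.
#' @param seed RNG seed.
#' @return An object of class `classifier_head`.
#' @export
head_init <- function(d_in, m, dims = c(128, 64, 32), seed = 0) {
  stopifnot(length(dims) == 3, m >= 2)
  set.seed(seed)
  all_dims <- c(d_in, dims, m)
  A <- vector("list", 4L); b <- vector("list", 4L)
  for (l in 1:4) {
    A[[l]] <- matrix(stats::rnorm(all_dims[l] * all_dims[l + 1L],
                                  sd = sqrt(2 / all_dims[l])),
                     all_dims[l], all_dims[l + 1L])
    b[[l]] <- numeric(all_dims[l + 1L])
  }
  structure(list(A = A, b = b, dims = all_dims, m = m),
            class = "classifier_head")
}

relu <- function(x) pmax(x, 0)

head_forward <- function(Z, head) {
  F_ <- vector("list", 5L); F_[[1L]] <- Z
  for (l in 1:3)
    F_[[l + 1L]] <- relu(sweep(F_[[l]] %*% head$A[[l]], 2L, head$b[[l]], "+"))
  logits <- sweep(F_[[4L]] %*% head$A[[4L]], 2L, head$b[[4L]], "+")
  # row softmax with max-shift for numerical stability
  sh <- logits - apply(logits, 1L, max)
  E <- exp(sh)
  P <- E / rowSums(E)
  list(F_ = F_, logits = logits, P = P)
}

# gradient of L_sup wrt head params and wrt Z; dlogits = (P - onehot)/n
head_backward <- function(hf, head, y_clu) {
  n <- nrow(hf$P)
  Y1 <- matrix(0, n, head$m)
  Y1[cbind(seq_len(n), y_clu + 1L)] <- 1
  dlog <- (hf$P - Y1) / n
  dA <- vector("list", 4L); db <- vector("list", 4L)
  dF <- dlog
  for (l in 4:1) {
    dA[[l]] <- crossprod(hf$F_[[l]], dF)
    db[[l]] <- colSums(dF)
    dF <- dF %*% t(head$A[[l]])
    if (l > 1) dF <- dF * (hf$F_[[l]] > 0)
  }
  list(dA = dA, db = db, dZ = dF)
}

#' Classify spots with the self-supervised head
#'
#' @param Z_L n x d_L final embedding matrix.
#' @param head a `classifier_head`.
#' @return n x m row-stochastic matrix of class probabilities.
#' @export
classify_spots <- function(Z_L, head) {
  stopifnot(inherits(head, "classifier_head"))
  if (ncol(Z_L) != head$dims[1L])
    stop("embedding dimension ", ncol(Z_L), " != head input ", head$dims[1L])
  head_forward(as.matrix(Z_L), head)$P
}

#' Self-supervised cross-entropy loss
#'
#' Cross-entropy between the classifier probabilities and the spectral
#' clustering labels used as (pseudo-)targets:
#' `L_sup = -(1/n) sum_i log P(i, y_i)`. Probabilities are clipped to
#' `[1e-12, 1]` before the log, so the loss is always finite. Zero if
#' and only if `P` is one-hot on the cluster labels.
#'
#' @param P n x m row-stochastic probability matrix.
#' @param Y_clu integer cluster labels in `0..m-1`.
#' @return Non-negative scalar.
#' @export
self_supervised_loss <- function(P, Y_clu) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (length(Y_clu) != n) stop("Y_clu length mismatch")
  if (any(Y_clu < 0) || any(Y_clu >= ncol(P)))
    stop("Y_clu labels must lie in 0..m-1")
  p <- pmin(pmax(P[cbind(seq_len(n), as.integer(Y_clu) + 1L)], 1e-12), 1)
  -mean(log(p))
}

#' Assemble the per-epoch loss report
#'
#' Combines the loss components into the total objective
#' `total = L_1 + L_reg + lambda * L_mss + L_sup`, where `lambda` trades
#' off the multiscale self-expression term.
#'
#' @param parts named list (or vector) with `L_att`, `L_1`, `L_mss`,
#'   `L_reg`, `L_sup`.
#' @param lambda trade-off weight for `L_mss`.
#' @return A `loss_report` list with all components, `L_2 = L_mss +
#'   L_reg`, `lambda` and `total`.
#' @export
total_loss <- function(parts, lambda) {
  parts <- as.list(parts)
  need <- c("L_att", "L_1", "L_mss", "L_reg", "L_sup")
  miss <- setdiff(need, names(parts))
  if (length(miss)) stop("missing loss parts: ", paste(miss, collapse = ", "))
  out <- parts[need]
  out$L_2 <- out$L_mss + out$L_reg
  out$lambda <- lambda
  out$total <- out$L_1 + out$L_reg + lambda * out$L_mss + out$L_sup
  structure(out, class = "loss_report")
}
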