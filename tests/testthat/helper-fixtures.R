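# Shared fixtures and independent oracles. Every oracle here is coded
# from the defining formula, not by calling the implementation it checks.

make_tissue <- function(rows = 10, cols = 10, k = 4, n_genes = 40,
                        markers = 8, seed = 1, ...) {
  spec <- synthetic_spec(rows = rows, cols = cols, k_domains = k,
                         n_genes = n_genes, markers_per_domain = markers,
                         seed = seed, ...)
  normalize_log1p(drop_empty_spots(generate_layered_tissue(spec)))
}

# --- brute-force pair-counting ARI oracle --------------------------------
ari_bruteforce <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  s11 <- sum(same_a & same_b)      # pairs together in both
  s00 <- sum(!same_a & !same_b)    # pairs apart in both
  ri <- (s11 + s00) / choose(n, 2)
  # expected RI under random labelings with the same margins
  e11 <- sum(same_a) * sum(same_b) / choose(n, 2)
  e00 <- sum(!same_a) * sum(!same_b) / choose(n, 2)
  e_ri <- (e11 + e00) / choose(n, 2)
  max_ri <- 1
  if (max_ri == e_ri) return(1)
  (ri - e_ri) / (max_ri - e_ri)
}

# --- second implementations of DB / CH, written pairwise -----------------
db_oracle <- function(Z, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  cent <- lapply(labs, function(l) colMeans(Z[labels == l, , drop = FALSE]))
  scatter <- vapply(seq_len(k), function(i) {
    pts <- Z[labels == labs[i], , drop = FALSE]
    mean(apply(pts, 1, function(p) sqrt(sum((p - cent[[i]])^2))))
  }, numeric(1))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (scatter[i] + scatter[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }, numeric(1)))
  }, numeric(1)))
}

ch_oracle <- function(Z, labels) {
  # uses the total-scatter decomposition T = B + W
  n <- nrow(Z)
  labs <- sort(unique(labels))
  k <- length(labs)
  Tm <- sum(sweep(Z, 2, colMeans(Z))^2)
  W <- sum(vapply(labs, function(l) {
    pts <- Z[labels == l, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }, numeric(1)))
  B <- Tm - W
  (B / (k - 1)) / (W / (n - k))
}

# --- hand Welch t --------------------------------------------------------
welch_oracle <- function(x, y) {
  s2x <- var(x) / length(x); s2y <- var(y) / length(y)
  tt <- (mean(x) - mean(y)) / sqrt(s2x + s2y)
  df <- (s2x + s2y)^2 / (s2x^2 / (length(x) - 1) + s2y^2 / (length(y) - 1))
  list(t = tt, p = 2 * pt(-abs(tt), df))
}

# --- diag-constrained ridge closed form ----------------------------------
# argmin_C 0.5||Z - C Z||_F^2 + beta ||C||_F^2, diag(C) = 0, solved row-wise
ridge_selfexpr_oracle <- function(Z, beta) {
  n <- nrow(Z)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    Zi <- Z[idx, , drop = FALSE]
    A <- Zi %*% t(Zi) + 2 * beta * diag(n - 1)
    b <- Zi %*% Z[i, ]
    C[i, idx] <- solve(A, b)
  }
  C
}

# --- dense masked-softmax attention oracle -------------------------------
attention_oracle <- function(H, W, v_s, v_r, A) {
  n <- nrow(H)
  G <- H %*% t(W)
  att <- matrix(0, n, n)
  for (i in seq_len(n)) {
    S_i <- which(A[i, ] != 0)
    e <- vapply(S_i, function(j) {
      plogis(sum(v_s * G[i, ]) + sum(v_r * G[j, ]))
    }, numeric(1))
    att[i, S_i] <- exp(e) / sum(exp(e))
  }
  att
}

# --- per-node message-passing encoder oracle (two layers) ---------------
encode_oracle <- function(X, model, A_att) {
  n <- nrow(X)
  elu_ <- function(x) ifelse(x > 0, x, exp(x) - 1)
  H1 <- matrix(0, n, nrow(model$W[[1]]))
  for (i in seq_len(n)) {
    acc <- 0
    for (j in which(A_att[i, ] != 0))
      acc <- acc + A_att[i, j] * (model$W[[1]] %*% X[j, ])
    H1[i, ] <- elu_(acc)
  }
  H2 <- t(apply(H1, 1, function(h) elu_(model$W[[2]] %*% h)))
  list(H1 = H1, H2 = H2)
}
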