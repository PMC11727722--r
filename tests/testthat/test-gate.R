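make_graph_pair <- function(n = 6, seed = 2, k = 2) {
  set.seed(seed)
  pts <- cbind(runif(n, 0, 3), runif(n, 0, 3))
  snn <- build_knn_graph(pts, k)
  labels <- sample(0:1, n, replace = TRUE)
  list(snn = snn, cta = prune_to_ctasnn(snn, labels), pts = pts)
}

test_that("attention rows are a softmax over each neighborhood", {
  # equal logits: a node with 3 neighbors (incl. itself) gets 1/3 each
  H <- matrix(1, 3, 2)
  W <- diag(2)
  g <- build_radius_graph(cbind(0:2 * 0.1, 0), 1)  # complete graph
  att <- compute_attention(H, W, c(0, 0), c(0, 0), g)
  expect_equal(as.matrix(att), matrix(1 / 3, 3, 3), ignore_attr = TRUE)

  # a single self-loop gives attention 1
  g1 <- build_radius_graph(rbind(c(0, 0), c(100, 0)), 1)
  att1 <- compute_attention(matrix(1, 2, 2), W, c(1, 0), c(0, 1), g1)
  expect_equal(Matrix::diag(att1), c(1, 1))

  # random graph vs the dense masked-softmax oracle
  set.seed(5)
  gp <- make_graph_pair(n = 5, seed = 5)
  H5 <- matrix(rnorm(5 * 4), 5, 4)
  W5 <- matrix(rnorm(3 * 4, sd = 0.5), 3, 4)
  vs <- rnorm(3); vr <- rnorm(3)
  att5 <- as.matrix(compute_attention(H5, W5, vs, vr, gp$snn))
  oracle <- attention_oracle(H5, W5, vs, vr, as.matrix(gp$snn$adjacency))
  expect_equal(att5, oracle, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(unname(rowSums(att5)), rep(1, 5), tolerance = 1e-6)
})

test_that("attention streams combine convexly without renormalization", {
  gp <- make_graph_pair(n = 6, seed = 9)
  H <- matrix(rnorm(6 * 3), 6, 3)
  W <- matrix(rnorm(2 * 3), 2, 3)
  vs <- rnorm(2); vr <- rnorm(2)
  a_sp <- compute_attention(H, W, vs, vr, gp$snn)
  a_aw <- compute_attention(H, W, vs, vr, gp$cta)
  # alpha = 0 reproduces the spatial stream exactly
  expect_equal(as.matrix(combine_attention(a_sp, a_aw, 0)), as.matrix(a_sp))
  # a pruned edge with spatial weight w gets (1 - alpha) * w
  M_sp <- as.matrix(a_sp); M_aw <- as.matrix(a_aw)
  pruned_edges <- which(M_sp > 0 & M_aw == 0)
  if (length(pruned_edges)) {
    comb <- as.matrix(combine_attention(a_sp, a_aw, 0.7))
    expect_equal(comb[pruned_edges], 0.3 * M_sp[pruned_edges], tolerance = 1e-12)
  }
  # identical streams are a fixpoint for any alpha
  expect_equal(as.matrix(combine_attention(a_sp, a_sp, 0.42)), M_sp,
               tolerance = 1e-12)
  expect_error(combine_attention(a_sp, a_aw, 1.3), "alpha")
})

test_that("encoder matches closed forms and a per-node oracle", {
  # isolated spots (self-loops only): layer 1 is elu(W1 x_i) exactly
  far <- rbind(c(0, 0), c(100, 100))
  g <- build_radius_graph(far, 1)
  model <- gate_init(3, hidden_dims = c(2, 2), alpha = 0, seed = 1)
  X <- matrix(rnorm(6), 2, 3)
  enc <- gate_encode(X, g, model = model)
  elu_ <- function(x) ifelse(x > 0, x, exp(x) - 1)
  expect_equal(enc$Z[[1]], elu_(X %*% t(model$W[[1]])), tolerance = 1e-12)

  # zero input: all embeddings are elu(0) = 0
  enc0 <- gate_encode(matrix(0, 2, 3), g, model = model)
  expect_equal(enc0$Z[[2]], matrix(0, 2, 2), ignore_attr = TRUE)

  # 6-spot fixture vs the naive per-node message-passing oracle
  gp <- make_graph_pair(n = 6, seed = 13, k = 3)
  model6 <- gate_init(4, hidden_dims = c(3, 2), alpha = 0, seed = 3)
  model6$v_s[[1]] <- rnorm(3, sd = 0.4); model6$v_r[[1]] <- rnorm(3, sd = 0.4)
  X6 <- matrix(rnorm(24), 6, 4)
  att <- as.matrix(compute_attention(X6, model6$W[[1]], model6$v_s[[1]],
                                     model6$v_r[[1]], gp$snn))
  oracle <- encode_oracle(X6, model6, att)
  enc6 <- gate_encode(X6, gp$snn, model = model6)
  expect_equal(enc6$Z[[1]], oracle$H1, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(enc6$Z[[2]], oracle$H2, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("decoder is tied to the encoder", {
  gp <- make_graph_pair(n = 6, seed = 21, k = 2)
  model <- gate_init(5, hidden_dims = c(4, 3), alpha = 0, seed = 2)
  X <- matrix(rnorm(30), 6, 5)
  enc <- gate_encode(X, gp$snn, model = model)
  # identity C on Z_L reproduces the pretraining reconstruction
  Xhat_direct <- enc$X_hat
  Xhat_via_C <- gate_decode(diag(6) %*% enc$Z[[2]], model, gp$snn, X = X)
  expect_equal(Xhat_via_C, Xhat_direct, tolerance = 1e-12)

  # zero embedding decodes through elu(0) = 0 to exactly zero output
  Xhat0 <- gate_decode(matrix(0, 6, 3), model, gp$snn, X = X)
  expect_equal(Xhat0, matrix(0, 6, 5), ignore_attr = TRUE, tolerance = 1e-12)

  # weight tying: the full autoencoder has exactly the encoder's parameters
  expect_identical(gate_param_count(model, "full"),
                   gate_param_count(model, "encoder"))

  # shared-parameter gradient check: analytic gradient (which sums the
  # encoder and decoder uses of W) matches a finite difference
  gc_ <- spadom:::gate_graph_cache(gp$snn)
  fw <- spadom:::gate_forward(X, model, gc_)
  gr <- spadom:::gate_backward(X, model, gc_, fw, wd_coeff = 0)
  eps <- 1e-6
  loss_at <- function(m) {
    f <- spadom:::gate_forward(X, m, gc_)
    reconstruction_loss(X, f$X_hat)
  }
  for (idx in c(1L, 7L)) {
    mp <- model; mp$W[[2]][idx] <- mp$W[[2]][idx] + eps
    mm <- model; mm$W[[2]][idx] <- mm$W[[2]][idx] - eps
    expect_equal(gr$dW[[2]][idx], (loss_at(mp) - loss_at(mm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("reconstruction and total losses follow their formulas", {
  X <- matrix(rnorm(12), 2, 6)
  expect_equal(reconstruction_loss(X, X), 0)
  expect_equal(reconstruction_loss(matrix(0, 2, 3), matrix(1, 2, 3)), 3)
  set.seed(4)
  A <- matrix(rnorm(40), 10, 4); B <- matrix(rnorm(40), 10, 4)
  expect_equal(reconstruction_loss(A, B), 0.5 * sum((A - B)^2), tolerance = 1e-12)
  expect_error(reconstruction_loss(A, matrix(0, 2, 2)), "shape")

  expect_equal(gate_total_loss(5, list(matrix(0, 2, 2))), 5)
  expect_equal(gate_total_loss(0, list(matrix(1, 2, 2))), 2)
  Ws <- list(matrix(rnorm(6), 2, 3), matrix(rnorm(4), 2, 2))
  expect_equal(gate_total_loss(1.5, Ws, wd_coeff = 0.3),
               1.5 + 0.3 * 0.5 * (sum(Ws[[1]]^2) + sum(Ws[[2]]^2)))
})

test_that("attention rows stay stochastic when the two graphs coincide", {
  gp <- make_graph_pair(n = 12, seed = 31, k = 3)
  model <- gate_init(6, hidden_dims = c(5, 3), alpha = 0.6, seed = 5)
  model$v_s[[1]] <- rnorm(5, sd = 0.3); model$v_r[[1]] <- rnorm(5, sd = 0.3)
  X <- matrix(rnorm(72), 12, 6)
  # ctaSNN == SNN: the convex combination of two identical softmaxes
  gc_ <- spadom:::gate_graph_cache(gp$snn, gp$snn)
  enc <- spadom:::gate_enc_forward(X, model, gc_)
  rs <- Matrix::rowSums(enc$attn[[1]]$A)
  expect_true(all(abs(rs - 1) < 1e-6))
  # alpha = 0 on a genuinely pruned graph
  model0 <- gate_init(6, hidden_dims = c(5, 3), alpha = 0, seed = 5)
  gc0 <- spadom:::gate_graph_cache(gp$snn, gp$cta)
  enc0 <- spadom:::gate_enc_forward(X, model0, gc0)
  expect_true(all(abs(Matrix::rowSums(enc0$attn[[1]]$A) - 1) < 1e-6))
})

test_that("pretraining halves the reconstruction loss on a small tissue", {
  ds <- make_tissue(rows = 10, cols = 10, k = 4, n_genes = 30, markers = 6,
                    seed = 17)
  snn <- build_knn_graph(ds$coords, 6)
  fit <- fit_spadom(ds, snn, m = 4, alpha = 0, hidden_dims = c(64, 16),
                    epochs_pre = 200, epochs_joint = 0, lr = 1e-3, seed = 17)
  ll <- fit$loss_log
  expect_lt(ll$L_att[nrow(ll)], 0.5 * ll$L_att[1])
})
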