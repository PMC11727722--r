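#' Initialize a weight-tied graph attention autoencoder
#'
#' The encoder has `L = length(hidden_dims)` layers. Layers `1..L-1` are
#' graph attention layers; the final layer is a plain linear map with the
#' same nonlinearity. The decoder mirrors the encoder with tied weights
#' (`What_k = t(W_k)`) and shared attention, so it contributes no
#' trainable parameters of its own. Hidden activations are ELU; the final
#' decoder layer is linear so reconstructions can match arbitrary
#' log-normalized values.
#'
#' Per attention layer there are two trainable attention vectors: one
#' scores the transformed features of the receiving spot, the other those
#' of the sending neighbor; their sum is squashed by a sigmoid and
#' normalized across each spot's neighborhood by a softmax.
#'
#' @param input_dim number of input genes.
#' @param hidden_dims encoder layer widths; default `c(512, 30)`.
#' @param alpha mixing weight in `[0, 1]` between the spatial-graph
#'   attention and the cell-type-aware attention (0 = spatial only).
#' @param seed RNG seed for weight initialization.
#' @return An object of class `gate_model`.
#' @export
gate_init <- function(input_dim, hidden_dims = c(512, 30), alpha = 0, seed = 0) {
  stopifnot(input_dim >= 1, length(hidden_dims) >= 2, alpha >= 0, alpha <= 1)
  set.seed(seed)
  dims <- c(input_dim, hidden_dims)
  L <- length(hidden_dims)
  W <- vector("list", L)
  v_s <- vector("list", L - 1L)
  v_r <- vector("list", L - 1L)
  for (k in seq_len(L)) {
    fan_in <- dims[k]; fan_out <- dims[k + 1L]
    s <- sqrt(6 / (fan_in + fan_out))
    W[[k]] <- matrix(stats::runif(fan_out * fan_in, -s, s), fan_out, fan_in)
  }
  for (k in seq_len(L - 1L)) {
    # zero-initialized attention vectors give uniform attention at epoch 0
    v_s[[k]] <- numeric(dims[k + 1L])
    v_r[[k]] <- numeric(dims[k + 1L])
  }
  structure(list(L = L, dims = dims, W = W, v_s = v_s, v_r = v_r,
                 alpha = alpha, activation = "elu"),
            class = "gate_model")
}

#' @export
print.gate_model <- function(x, ...) {
  cat(sprintf("gate_model: %s encoder (tied decoder), alpha = %g\n",
              paste(x$dims, collapse = " -> "), x$alpha))
  invisible(x)
}

#' Count trainable parameters of the autoencoder
#'
#' Because decoder weights are transposes of encoder weights and decoder
#' attention is shared, the full autoencoder has exactly as many trainable
#' parameters as the encoder alone.
#'
#' @param model a `gate_model`.
#' @param part `"full"` (encoder + decoder) or `"encoder"`.
#' @return Integer parameter count.
#' @export
gate_param_count <- function(model, part = c("full", "encoder")) {
  part <- match.arg(part)
  n_enc <- sum(vapply(model$W, length, integer(1))) +
    sum(vapply(model$v_s, length, integer(1))) +
    sum(vapply(model$v_r, length, integer(1)))
  # the decoder reuses every encoder parameter and adds none
  n_enc
}

# --- edge-level graph plumbing ------------------------------------------

# Extract the edge list of a neighbor graph: ei receives from ej
# (row i aggregates over its neighbor set S_i = {j : A[i,j] = 1}).
graph_edge_index <- function(graph) {
  A <- if (inherits(graph, "neighbor_graph")) graph$adjacency else graph
  tr <- methods::as(A, "TsparseMatrix")
  ei <- tr@i + 1L; ej <- tr@j + 1L
  o <- order(ei, ej)
  list(ei = ei[o], ej = ej[o], n = nrow(A))
}

# softmax over each receiving spot's neighborhood; x are edge values
edge_softmax <- function(x, ei, n) {
  w <- exp(x)
  denom <- edge_rowsum(w, ei, n)
  w / denom[ei]
}

# sum edge values grouped by index vector (1..n), returning a length-n vector
edge_rowsum <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# attention forward for one layer on one graph: returns per-edge att and cache
attention_edges <- function(G, v_s, v_r, ei, ej, n) {
  s <- as.vector(G %*% v_s)
  r <- as.vector(G %*% v_r)
  e <- stats::plogis(s[ei] + r[ej])
  att <- edge_softmax(e, ei, n)
  list(att = att, e = e)
}

#' Compute graph attention weights for one layer
#'
#' For every edge `(i, j)` of the graph (including self-loops), the logit
#' is `sigmoid(v_s . (W h_i) + v_r . (W h_j))`, normalized by a softmax
#' over the neighborhood of `i`, so each row of the returned matrix sums
#' to 1 over the neighbor set.
#'
#' @param H_prev n x d input features to the layer.
#' @param W_k layer weight matrix (d_out x d).
#' @param v_s,v_r attention vectors of length d_out.
#' @param graph a `neighbor_graph` with self-loops.
#' @return Sparse n x n matrix of attention weights on the graph edges.
#' @export
compute_attention <- function(H_prev, W_k, v_s, v_r, graph) {
  idx <- graph_edge_index(graph)
  n <- idx$n
  if (length(unique(idx$ei)) < n)
    stop("graph has node(s) with empty neighborhood (missing self-loop?)")
  G <- H_prev %*% t(W_k)
  a <- attention_edges(G, v_s, v_r, idx$ei, idx$ej, n)
  Matrix::sparseMatrix(i = idx$ei, j = idx$ej, x = a$att, dims = c(n, n))
}

#' Combine spatial and cell-type-aware attention
#'
#' Convex combination `(1 - alpha) * att_spatial + alpha * att_aware` on
#' the spatial edge set; the aware stream is 0 on edges pruned from the
#' cell-type-aware graph. The combination is used as-is, with no
#' re-normalization.
#'
#' @param att_spatial,att_aware sparse attention matrices (the aware
#'   pattern must be a subset of the spatial pattern).
#' @param alpha mixing weight in `[0, 1]`.
#' @return Sparse combined attention matrix.
#' @export
combine_attention <- function(att_spatial, att_aware, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  out <- (1 - alpha) * att_spatial + alpha * att_aware
  methods::as(out, "CsparseMatrix")
}

# --- full forward pass ---------------------------------------------------

# Precompute edge bookkeeping shared by every epoch: the SNN edge list and
# the positions of the ctaSNN edges inside it.
gate_graph_cache <- function(snn, ctasnn = NULL) {
  idx <- graph_edge_index(snn)
  cache <- list(ei = idx$ei, ej = idx$ej, n = idx$n, sub = NULL,
                ei_sub = NULL, ej_sub = NULL)
  if (!is.null(ctasnn)) {
    sidx <- graph_edge_index(ctasnn)
    key <- idx$ei + (idx$ej - 1) * as.double(idx$n)
    skey <- sidx$ei + (sidx$ej - 1) * as.double(idx$n)
    pos <- match(skey, key)
    if (anyNA(pos))
      stop("cell-type-aware graph has edges absent from the spatial graph")
    cache$sub <- pos
    cache$ei_sub <- sidx$ei
    cache$ej_sub <- sidx$ej
  }
  cache
}

# Attention for one layer combining the SNN and ctaSNN streams.
# Returns per-SNN-edge combined weights plus everything backward needs.
layer_attention <- function(G, v_s, v_r, gc, alpha) {
  sp <- attention_edges(G, v_s, v_r, gc$ei, gc$ej, gc$n)
  att <- (1 - alpha) * sp$att
  aw <- NULL
  if (alpha > 0 && !is.null(gc$sub)) {
    aw <- list(att = edge_softmax(sp$e[gc$sub], gc$ei_sub, gc$n),
               e = sp$e[gc$sub])
    att[gc$sub] <- att[gc$sub] + alpha * aw$att
  }
  A <- Matrix::sparseMatrix(i = gc$ei, j = gc$ej, x = att, dims = c(gc$n, gc$n))
  list(A = A, att = att, sp = sp, aw = aw)
}

# Encoder forward pass; caches everything the backward pass needs.
gate_enc_forward <- function(X, model, gc) {
  L <- model$L
  H <- vector("list", L + 1L); H[[1L]] <- X
  G <- vector("list", L)
  pre_enc <- vector("list", L)
  attn <- vector("list", L - 1L)
  for (k in seq_len(L)) {
    G[[k]] <- H[[k]] %*% t(model$W[[k]])
    if (k < L) {
      attn[[k]] <- layer_attention(G[[k]], model$v_s[[k]], model$v_r[[k]],
                                   gc, model$alpha)
      pre_enc[[k]] <- as.matrix(attn[[k]]$A %*% G[[k]])
    } else {
      pre_enc[[k]] <- G[[k]]
    }
    H[[k + 1L]] <- elu(pre_enc[[k]])
  }
  list(H = H, G = G, Z = H[-1L], pre_enc = pre_enc, attn = attn)
}

# Tied-weight decoder forward pass; shares the encoder's attention.
gate_dec_forward <- function(Zin, model, enc) {
  L <- model$L
  Hd <- vector("list", L); Hd[[L]] <- Zin
  pre_dec <- vector("list", L)
  V <- vector("list", L)
  for (k in rev(seq_len(L))[-L]) {   # k = L, L-1, ..., 2
    V[[k]] <- Hd[[k]] %*% model$W[[k]]
    pre_dec[[k]] <- as.matrix(enc$attn[[k - 1L]]$A %*% V[[k]])
    Hd[[k - 1L]] <- elu(pre_dec[[k]])
  }
  X_hat <- Hd[[1L]] %*% model$W[[1L]]   # linear output layer
  list(Hd = Hd, V = V, pre_dec = pre_dec, X_hat = X_hat, Zin = Zin)
}

# Full forward pass of encoder + tied decoder. Zin is the decoder input
# (Z_L during pretraining, C_F %*% Z_L once the subspace module is live).
gate_forward <- function(X, model, gc, Zin = NULL) {
  enc <- gate_enc_forward(X, model, gc)
  if (is.null(Zin)) Zin <- enc$Z[[model$L]]
  dec <- gate_dec_forward(Zin, model, enc)
  c(enc, dec)
}

#' Encode spots into per-layer embeddings
#'
#' Runs the encoder: graph attention layers followed by a final plain
#' linear layer, returning the embedding matrix of every encoder layer
#' (the multiscale subspace module consumes all of them) and the
#' reconstruction from the tied decoder.
#'
#' @param X n x g normalized expression matrix.
#' @param graph_snn spatial `neighbor_graph`.
#' @param graph_ctasnn optional cell-type-aware `neighbor_graph` (required
#'   when `model$alpha > 0`).
#' @param model a `gate_model`.
#' @return A list with `Z` (list of n x d_k embeddings, k = 1..L) and
#'   `X_hat` (n x g reconstruction).
#' @export
gate_encode <- function(X, graph_snn, graph_ctasnn = NULL, model) {
  stopifnot(inherits(model, "gate_model"))
  if (ncol(X) != model$dims[1L])
    stop("X has ", ncol(X), " genes but the model expects ", model$dims[1L])
  if (model$alpha > 0 && is.null(graph_ctasnn))
    stop("alpha > 0 requires a cell-type-aware graph")
  gc <- gate_graph_cache(graph_snn, graph_ctasnn)
  fw <- gate_forward(as.matrix(X), model, gc)
  list(Z = fw$Z, X_hat = fw$X_hat)
}

#' Decode an embedding (or its self-expressed version) back to expression
#'
#' Mirrors the encoder with tied weights and shared attention. During
#' pretraining the decoder is fed the final embedding `Z_L`; once the
#' subspace module is active it is fed `C_F %*% Z_L`.
#'
#' @param Zin n x d_L decoder input.
#' @param model a `gate_model`.
#' @param graph_snn,graph_ctasnn the graphs used by the encoder.
#' @param X n x g matrix whose attention should be reused (the attention
#'   weights depend on the encoder inputs).
#' @return n x g reconstruction.
#' @export
gate_decode <- function(Zin, model, graph_snn, graph_ctasnn = NULL, X) {
  gc <- gate_graph_cache(graph_snn, graph_ctasnn)
  fw <- gate_forward(as.matrix(X), model, gc, Zin = as.matrix(Zin))
  fw$X_hat
}

#' Reconstruction loss (residual sum of squares)
#'
#' `0.5 * sum_i || x_i - xhat_i ||^2`.
#'
#' @param X,X_hat matrices of identical shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(X, X_hat) {
  if (!all(dim(X) == dim(X_hat))) stop("X and X_hat shapes differ")
  0.5 * sum((X - X_hat)^2)
}

#' Regularized autoencoder loss
#'
#' Adds a weight-decay penalty on the encoder attention-layer weights:
#' `L_1 = L_att + wd_coeff * 0.5 * sum_k ||W_k||_F^2` over layers
#' `k = 1..L-1`.
#'
#' @param L_att reconstruction loss value.
#' @param W_list encoder weight matrices `W_1..W_{L-1}`.
#' @param wd_coeff weight-decay coefficient; 1.0 reproduces the plain
#'   half-sum penalty.
#' @return Scalar loss.
#' @export
gate_total_loss <- function(L_att, W_list, wd_coeff = 1.0) {
  L_att + wd_coeff * 0.5 * sum(vapply(W_list, function(W) sum(W^2), numeric(1)))
}
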