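#' Transformer baseline configuration
#'
#' Attention-based alternative to the CNN-LSTM, trained under the same
#' protocol. The spectrum is embedded token-wise by a 1-D convolution
#' (kernel 3, ReLU) plus a trainable positional embedding, passed through
#' pre-norm Transformer encoder blocks (multi-head self-attention with
#' residual, then a position-wise feed-forward network -- GELU expansion
#' back to the embedding width -- with residual), pooled by global average,
#' and regressed through the same 50-unit ReLU / batch-norm / dropout head.
#'
#' Defaults follow the full-scale protocol: embedding width 32, four
#' blocks, 8 heads of key dimension 32, feed-forward width 64, dropout 0.2,
#' Adam at 5.5e-4, early-stopping patience 3 with best-weight restore and
#' plateau decay (factor 0.1, patience 3, floor 1e-6), up to 300 epochs,
#' batch 32. `test_mode = TRUE` shrinks the network for desk-scale runs.
#'
#' @param embed_dim Token embedding width (constant through the blocks).
#' @param n_blocks Number of encoder blocks.
#' @param n_heads,key_dim Attention heads and per-head key dimension.
#' @param ff_units Feed-forward expansion width.
#' @param dropout Dropout rate (attention, pooling and head).
#' @param head_units,n_outputs,learning_rate,batch_size,epochs,patience As
#'   in [cnn_lstm_config()].
#' @param test_mode Use a reduced preset.
#' @return A `transformer_config` list.
#' @export
transformer_config <- function(embed_dim = 32, n_blocks = 4, n_heads = 8,
                               key_dim = 32, ff_units = 64, dropout = 0.2,
                               head_units = 50, n_outputs = 16,
                               learning_rate = 5.5e-4, batch_size = 32,
                               epochs = 300, patience = 3,
                               test_mode = FALSE) {
  if (test_mode) {
    if (missing(embed_dim)) embed_dim <- 8
    if (missing(n_blocks)) n_blocks <- 2
    if (missing(n_heads)) n_heads <- 2
    if (missing(key_dim)) key_dim <- 4
    if (missing(ff_units)) ff_units <- 16
    if (missing(epochs)) epochs <- 30
  }
  structure(
    list(arch = "transformer", embed_dim = as.integer(embed_dim),
         n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
         key_dim = as.integer(key_dim), ff_units = as.integer(ff_units),
         dropout = dropout, head_units = as.integer(head_units),
         n_outputs = as.integer(n_outputs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         patience = as.integer(patience), kernel = 3L,
         lr_factor = 0.1, lr_patience = 3, min_lr = 1e-6),
    class = "transformer_config"
  )
}

transformer_init <- function(cfg, n_bands) {
  D <- cfg$embed_dim
  hk <- cfg$n_heads * cfg$key_dim
  p <- list()
  p$emb_W <- glorot(cfg$kernel * 1, D, c(cfg$kernel * 1, D))
  p$emb_b <- numeric(D)
  p$pos <- array(stats::rnorm(n_bands * D, 0, 0.02), c(n_bands, D))
  for (i in seq_len(cfg$n_blocks)) {
    pre <- paste0("blk", i, "_")
    p[[paste0(pre, "ln1_gamma")]] <- rep(1, D)
    p[[paste0(pre, "ln1_beta")]] <- numeric(D)
    p[[paste0(pre, "Wq")]] <- glorot(D, hk)
    p[[paste0(pre, "Wk")]] <- glorot(D, hk)
    p[[paste0(pre, "Wv")]] <- glorot(D, hk)
    p[[paste0(pre, "Wo")]] <- glorot(hk, D)
    p[[paste0(pre, "bo")]] <- numeric(D)
    p[[paste0(pre, "ln2_gamma")]] <- rep(1, D)
    p[[paste0(pre, "ln2_beta")]] <- numeric(D)
    p[[paste0(pre, "ff1_W")]] <- glorot(D, cfg$ff_units)
    p[[paste0(pre, "ff1_b")]] <- numeric(cfg$ff_units)
    p[[paste0(pre, "ff2_W")]] <- glorot(cfg$ff_units, D)
    p[[paste0(pre, "ff2_b")]] <- numeric(D)
  }
  p$head_W <- glorot(D, cfg$head_units)
  p$head_b <- numeric(cfg$head_units)
  p$bnh_gamma <- rep(1, cfg$head_units)
  p$bnh_beta <- numeric(cfg$head_units)
  p$bnh_mean <- numeric(cfg$head_units)
  p$bnh_var <- rep(1, cfg$head_units)
  p$out_W <- glorot(cfg$head_units, cfg$n_outputs)
  p$out_b <- numeric(cfg$n_outputs)
  p
}

# multi-head self-attention over one batch; X2 is (B*T, D) row-major in
# sample-major blocks? No -- we keep (B, T, D) arrays and loop samples for
# the (T x T) attention maps. Dropout on attention probabilities.
mhsa_fwd <- function(X3, Wq, Wk, Wv, Wo, bo, cfg, training) {
  d <- dim(X3); B <- d[1]; T <- d[2]
  kd <- cfg$key_dim; nh <- cfg$n_heads
  X2 <- bt_mat(X3)
  Q <- X2 %*% Wq; K <- X2 %*% Wk; V <- X2 %*% Wv
  Q3 <- unbt_mat(Q, B, T); K3 <- unbt_mat(K, B, T); V3 <- unbt_mat(V, B, T)
  O3 <- array(0, c(B, T, nh * kd))
  Ps <- vector("list", B)
  Dmask <- vector("list", B)
  for (b in seq_len(B)) {
    Pb <- vector("list", nh); Mb <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * kd + 1):(h * kd)
      Qh <- matrix(Q3[b, , cols], T, kd)
      Kh <- matrix(K3[b, , cols], T, kd)
      Vh <- matrix(V3[b, , cols], T, kd)
      S <- tcrossprod(Qh, Kh) / sqrt(kd)
      P <- softmax_rows(S)
      dp <- dropout_fwd(P, cfg$dropout, training)
      O3[b, , cols] <- dp$out %*% Vh
      Pb[[h]] <- P; Mb[h] <- list(dp$mask)
    }
    Ps[[b]] <- Pb; Dmask[[b]] <- Mb
  }
  O2 <- bt_mat(O3)
  out2 <- O2 %*% Wo + matrix(bo, nrow(O2), length(bo), byrow = TRUE)
  list(out = unbt_mat(out2, B, T), X2 = X2, Q3 = Q3, K3 = K3, V3 = V3,
       O2 = O2, Ps = Ps, Dmask = Dmask, dims = d)
}

mhsa_bwd <- function(ca, Wq, Wk, Wv, Wo, cfg, dY3) {
  d <- ca$dims; B <- d[1]; T <- d[2]
  kd <- cfg$key_dim; nh <- cfg$n_heads
  dY2 <- bt_mat(dY3)
  dWo <- crossprod(ca$O2, dY2)
  dbo <- colSums(dY2)
  dO2 <- dY2 %*% t(Wo)
  dO3 <- unbt_mat(dO2, B, T)
  dQ3 <- array(0, c(B, T, nh * kd))
  dK3 <- dQ3; dV3 <- dQ3
  for (b in seq_len(B)) {
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * kd + 1):(h * kd)
      Qh <- matrix(ca$Q3[b, , cols], T, kd)
      Kh <- matrix(ca$K3[b, , cols], T, kd)
      Vh <- matrix(ca$V3[b, , cols], T, kd)
      P <- ca$Ps[[b]][[h]]
      mask <- ca$Dmask[[b]][[h]]
      Pd <- if (is.null(mask)) P else P * mask
      dOh <- matrix(dO3[b, , cols], T, kd)
      dPd <- tcrossprod(dOh, Vh)
      dVh <- crossprod(Pd, dOh)
      dP <- if (is.null(mask)) dPd else dPd * mask
      dS <- softmax_rows_bwd(P, dP) / sqrt(kd)
      dQ3[b, , cols] <- dS %*% Kh
      dK3[b, , cols] <- crossprod(dS, Qh)
      dV3[b, , cols] <- dVh
    }
  }
  dQ2 <- bt_mat(dQ3); dK2 <- bt_mat(dK3); dV2 <- bt_mat(dV3)
  dX2 <- dQ2 %*% t(Wq) + dK2 %*% t(Wk) + dV2 %*% t(Wv)
  list(dX = unbt_mat(dX2, B, T),
       dWq = crossprod(ca$X2, dQ2), dWk = crossprod(ca$X2, dK2),
       dWv = crossprod(ca$X2, dV2), dWo = dWo, dbo = dbo)
}

transformer_forward <- function(params, X, cfg, training = FALSE) {
  B <- nrow(X); T <- ncol(X)
  X3 <- array(X, c(B, T, 1L))
  ca <- list(B = B, T = T)
  ca$emb <- conv1d_fwd(X3, params$emb_W, params$emb_b, cfg$kernel)
  ca$remb <- relu_fwd(ca$emb$out)
  E <- ca$remb$out
  pos <- params$pos
  E <- E + aperm(array(t(pos), c(dim(pos)[2], T, B)), c(3, 2, 1))
  ca$blocks <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    pre <- paste0("blk", i, "_")
    bc <- list()
    bc$ln1 <- layernorm_fwd(bt_mat(E), params[[paste0(pre, "ln1_gamma")]],
                            params[[paste0(pre, "ln1_beta")]])
    bc$att <- mhsa_fwd(unbt_mat(bc$ln1$out, B, T),
                       params[[paste0(pre, "Wq")]], params[[paste0(pre, "Wk")]],
                       params[[paste0(pre, "Wv")]], params[[paste0(pre, "Wo")]],
                       params[[paste0(pre, "bo")]], cfg, training)
    E1 <- E + bc$att$out
    bc$ln2 <- layernorm_fwd(bt_mat(E1), params[[paste0(pre, "ln2_gamma")]],
                            params[[paste0(pre, "ln2_beta")]])
    bc$ff1 <- dense_fwd(bc$ln2$out, params[[paste0(pre, "ff1_W")]],
                        params[[paste0(pre, "ff1_b")]])
    bc$gelu <- gelu_fwd(bc$ff1$out)
    bc$ff2 <- dense_fwd(bc$gelu$out, params[[paste0(pre, "ff2_W")]],
                        params[[paste0(pre, "ff2_b")]])
    E <- E1 + unbt_mat(bc$ff2$out, B, T)
    ca$blocks[[i]] <- bc
  }
  ca$gap <- gap_fwd(E)
  ca$dog <- dropout_fwd(ca$gap$out, cfg$dropout, training)
  ca$hd <- dense_fwd(ca$dog$out, params$head_W, params$head_b)
  ca$rh <- relu_fwd(ca$hd$out)
  ca$bn <- batchnorm_fwd(ca$rh$out, params$bnh_gamma, params$bnh_beta,
                         params$bnh_mean, params$bnh_var, training)
  ca$doh <- dropout_fwd(ca$bn$out, cfg$dropout, training)
  ca$out <- dense_fwd(ca$doh$out, params$out_W, params$out_b)
  if (training) {
    ca$bn_updates <- list(bnh = list(mean = ca$bn$new_mean,
                                     var = ca$bn$new_var))
  }
  list(out = ca$out$out, cache = ca)
}

transformer_backward <- function(params, ca, dOut, cfg) {
  B <- ca$B; T <- ca$T
  g <- list()
  d <- dense_bwd(ca$out, params$out_W, dOut)
  g$out_W <- d$dW; g$out_b <- d$db
  dx <- dropout_bwd(ca$doh, d$dX)
  bn <- batchnorm_bwd(ca$bn, params$bnh_gamma, dx)
  g$bnh_gamma <- bn$dgamma; g$bnh_beta <- bn$dbeta
  dx <- relu_bwd(ca$rh, bn$dX)
  d <- dense_bwd(ca$hd, params$head_W, dx)
  g$head_W <- d$dW; g$head_b <- d$db
  dx <- dropout_bwd(ca$dog, d$dX)
  dE <- gap_bwd(ca$gap, dx)
  for (i in rev(seq_len(cfg$n_blocks))) {
    pre <- paste0("blk", i, "_")
    bc <- ca$blocks[[i]]
    # feed-forward sub-block
    dff2 <- bt_mat(dE)
    d <- dense_bwd(bc$ff2, params[[paste0(pre, "ff2_W")]], dff2)
    g[[paste0(pre, "ff2_W")]] <- d$dW; g[[paste0(pre, "ff2_b")]] <- d$db
    dx <- gelu_bwd(bc$gelu, d$dX)
    d <- dense_bwd(bc$ff1, params[[paste0(pre, "ff1_W")]], dx)
    g[[paste0(pre, "ff1_W")]] <- d$dW; g[[paste0(pre, "ff1_b")]] <- d$db
    ln <- layernorm_bwd(bc$ln2, params[[paste0(pre, "ln2_gamma")]], d$dX)
    g[[paste0(pre, "ln2_gamma")]] <- ln$dgamma
    g[[paste0(pre, "ln2_beta")]] <- ln$dbeta
    dE1 <- dE + unbt_mat(ln$dX, B, T)     # residual
    # attention sub-block
    att <- mhsa_bwd(bc$att, params[[paste0(pre, "Wq")]],
                    params[[paste0(pre, "Wk")]], params[[paste0(pre, "Wv")]],
                    params[[paste0(pre, "Wo")]], cfg, dE1)
    g[[paste0(pre, "Wq")]] <- att$dWq; g[[paste0(pre, "Wk")]] <- att$dWk
    g[[paste0(pre, "Wv")]] <- att$dWv; g[[paste0(pre, "Wo")]] <- att$dWo
    g[[paste0(pre, "bo")]] <- att$dbo
    ln <- layernorm_bwd(bc$ln1, params[[paste0(pre, "ln1_gamma")]],
                        bt_mat(att$dX))
    g[[paste0(pre, "ln1_gamma")]] <- ln$dgamma
    g[[paste0(pre, "ln1_beta")]] <- ln$dbeta
    dE <- dE1 + unbt_mat(ln$dX, B, T)     # residual
  }
  g$pos <- apply(dE, c(2, 3), sum)
  dx3 <- relu_bwd(ca$remb, dE)
  cb <- conv1d_bwd(ca$emb, params$emb_W, params$emb_b, cfg$kernel, dx3)
  g$emb_W <- cb$dW; g$emb_b <- cb$db
  g
}

transformer_arch <- function() {
  list(forward = transformer_forward, backward = transformer_backward)
}
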