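# Minimal neural-network engine.
#
# The regressors in this package (convolutional imputer, CNN-LSTM,
# Transformer baseline) run on a compact internal engine: plain R arrays,
# hand-derived reverse-mode gradients for each layer, an RcppArmadillo
# kernel for the LSTM recurrence, and Adam. Every architecture's gradient
# is verified against finite differences in the test suite. Layout
# convention: sequence activations are (batch, time, channels) arrays;
# dense activations are (batch, features) matrices.

# ---- array helpers ---------------------------------------------------------

bt_mat <- function(X3) {
  d <- dim(X3)
  dim(X3) <- c(d[1] * d[2], d[3])
  X3
}

unbt_mat <- function(M, B, T) {
  dim(M) <- c(B, T, ncol(M))
  M
}

# out[, t, ] <- X3[, t + off, ] with zero padding outside [1, T]
shift_t <- function(X3, off) {
  d <- dim(X3)
  Y <- array(0, d)
  T <- d[2]
  src <- seq_len(T) + off
  ok <- src >= 1 & src <= T
  Y[, which(ok), ] <- X3[, src[ok], , drop = FALSE]
  Y
}

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# block-orthogonal recurrent initialisation (one orthogonal H x H block per
# gate), the standard default for LSTM recurrent kernels
orthogonal_lstm <- function(n_units) {
  blocks <- replicate(4, {
    qr.Q(qr(matrix(stats::rnorm(n_units^2), n_units)))
  }, simplify = FALSE)
  do.call(cbind, blocks)
}

# ---- primitive layers ------------------------------------------------------

dense_fwd <- function(X, W, b) {
  list(out = X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE),
       X = X)
}
dense_bwd <- function(cache, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

relu_fwd <- function(X) list(out = pmax(X, 0), mask = X > 0)
relu_bwd <- function(cache, dY) dY * cache$mask

gelu_fwd <- function(X) list(out = X * stats::pnorm(X), X = X)
gelu_bwd <- function(cache, dY) {
  x <- cache$X
  dY * (stats::pnorm(x) + x * stats::dnorm(x))
}

dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- array(stats::runif(length(X)) >= rate, dim(X) %||% length(X)) /
    (1 - rate)
  list(out = X * mask, mask = mask)
}
dropout_bwd <- function(cache, dY) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# conv1d, "same" padding; W is (K*Cin) x Cout with kernel-offset blocks
conv1d_fwd <- function(X3, W, b, K) {
  d <- dim(X3)
  cin <- d[3]
  offs <- seq_len(K) - (K + 1) / 2
  Xcol <- do.call(cbind, lapply(offs, function(o) bt_mat(shift_t(X3, o))))
  Y <- Xcol %*% W + matrix(b, nrow(Xcol), length(b), byrow = TRUE)
  list(out = unbt_mat(Y, d[1], d[2]), Xcol = Xcol, dims = d)
}
conv1d_bwd <- function(cache, W, b, K, dY3) {
  d <- cache$dims
  cin <- d[3]
  dY <- bt_mat(dY3)
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(W)
  offs <- seq_len(K) - (K + 1) / 2
  dX3 <- array(0, d)
  for (k in seq_len(K)) {
    blk <- dXcol[, ((k - 1) * cin + 1):(k * cin), drop = FALSE]
    dX3 <- dX3 + shift_t(unbt_mat(blk, d[1], d[2]), -offs[k])
  }
  list(dX = dX3, dW = dW, db = db)
}

gap_fwd <- function(X3) {
  d <- dim(X3)
  ib <- rep(seq_len(d[1]), times = d[2])
  list(out = rowsum(bt_mat(X3), ib, reorder = TRUE) / d[2], dims = d)
}
gap_bwd <- function(cache, dY) {
  d <- cache$dims
  ib <- rep(seq_len(d[1]), times = d[2])
  unbt_mat(dY[ib, , drop = FALSE] / d[2], d[1], d[2])
}

flatten_fwd <- function(X3) {
  d <- dim(X3)
  list(out = matrix(X3, d[1], d[2] * d[3]), dims = d)
}
flatten_bwd <- function(cache, dY) array(dY, cache$dims)

batchnorm_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                          momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    new_mean <- momentum * run_mean + (1 - momentum) * mu
    new_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  std <- sqrt(v + eps)
  xc <- sweep(X, 2L, mu)
  xhat <- sweep(xc, 2L, std, `/`)
  out <- sweep(xhat, 2L, gamma, `*`)
  out <- sweep(out, 2L, beta, `+`)
  list(out = out, xhat = xhat, xc = xc, std = std,
       new_mean = new_mean, new_var = new_var)
}
batchnorm_bwd <- function(cache, gamma, dY) {
  B <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, `*`)
  dvar <- colSums(dxhat * cache$xc) * (-0.5) / cache$std^3
  dmu <- -colSums(dxhat) / cache$std + dvar * colMeans(-2 * cache$xc)
  dX <- sweep(dxhat, 2L, cache$std, `/`) +
    sweep(cache$xc, 2L, 2 * dvar / B, `*`) +
    matrix(dmu / B, B, ncol(dY), byrow = TRUE)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans(X^2) - mu^2
  std <- sqrt(v + eps)
  xc <- X - mu
  xhat <- xc / std
  out <- sweep(xhat, 2L, gamma, `*`)
  out <- sweep(out, 2L, beta, `+`)
  list(out = out, xhat = xhat, xc = xc, std = std)
}
layernorm_bwd <- function(cache, gamma, dY) {
  D <- ncol(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, `*`)
  dvar <- rowSums(dxhat * cache$xc) * (-0.5) / cache$std^3
  dmu <- -rowSums(dxhat) / cache$std + dvar * rowMeans(-2 * cache$xc)
  dX <- dxhat / cache$std + cache$xc * (2 * dvar / D) + dmu / D
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(X) {
  e <- exp(X - apply(X, 1L, max))
  e / rowSums(e)
}
softmax_rows_bwd <- function(P, dP) {
  P * (dP - rowSums(P * dP))
}

# ---- LSTM layer (C++ recurrence) -------------------------------------------

lstm_init <- function(n_in, n_units) {
  b <- numeric(4 * n_units)
  b[(n_units + 1):(2 * n_units)] <- 1  # forget-gate bias
  list(Wx = glorot(n_in, 4 * n_units),
       Wh = orthogonal_lstm(n_units),
       b = b)
}

# X3 (B,T,C) -> H3 (B,T,H)
lstm_fwd <- function(X3, p) {
  Xc <- aperm(X3, c(1, 3, 2))
  res <- lstm_forward_cpp(Xc, p$Wx, p$Wh, p$b)
  list(out = aperm(res$H, c(1, 3, 2)), Xc = Xc, res = res)
}
lstm_bwd <- function(cache, p, dH3) {
  dHc <- aperm(dH3, c(1, 3, 2))
  g <- lstm_backward_cpp(cache$Xc, cache$res$H, cache$res$C, cache$res$gates,
                         cache$res$tanh_c, p$Wx, p$Wh, dHc)
  list(dX = aperm(g$dX, c(1, 3, 2)), dWx = g$dWx, dWh = g$dWh,
       db = drop(g$db))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L, lr = lr,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - opt$beta1^opt$t
  corr2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / corr1) / (sqrt(opt$v[[nm]] / corr2) + opt$eps)
  }
  list(opt = opt, params = params)
}

# ---- weighted MSE loss -----------------------------------------------------

wmse_fwd <- function(Yhat, Y, w) {
  r <- Yhat - Y
  list(loss = sum(w * rowMeans(r^2)) / length(w),
       dYhat = (2 / (length(w) * ncol(Y))) * r * w)
}

# ---- generic training loop -------------------------------------------------

# arch: list(forward = f(params, X, cfg, training),
#            backward = f(params, cache, dOut, cfg))
# forward returns list(out, cache); cache may carry $bn_updates, a named
# list of list(mean=, var=) entries applied to params while training.
fit_network <- function(arch, params, cfg, X, Y, weights = NULL,
                        val = NULL, epochs, batch_size, lr,
                        patience = 10, lr_factor = 0.5, lr_patience = 5,
                        min_lr = 1e-6, shuffle = TRUE, verbose = FALSE) {
  n <- if (is.matrix(X)) nrow(X) else dim(X)[1]
  if (is.null(weights)) weights <- rep(1, n)
  opt <- adam_init(params, lr)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L; lr_wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    idx <- if (shuffle) sample.int(n) else seq_len(n)
    batches <- split(idx, ceiling(seq_along(idx) / batch_size))
    ep_loss <- 0
    for (bi in batches) {
      Xb <- if (is.matrix(X)) X[bi, , drop = FALSE] else X[bi, , , drop = FALSE]
      fw <- arch$forward(params, Xb, cfg, training = TRUE)
      if (!is.null(fw$cache$bn_updates)) {
        for (nm in names(fw$cache$bn_updates)) {
          params[[paste0(nm, "_mean")]] <- fw$cache$bn_updates[[nm]]$mean
          params[[paste0(nm, "_var")]] <- fw$cache$bn_updates[[nm]]$var
        }
      }
      ls <- wmse_fwd(fw$out, Y[bi, , drop = FALSE], weights[bi])
      ep_loss <- ep_loss + ls$loss * length(bi)
      grads <- arch$backward(params, fw$cache, ls$dYhat, cfg)
      upd <- adam_step(opt, params, grads)
      opt <- upd$opt; params <- upd$params
    }
    val_loss <- if (is.null(val)) ep_loss / n else {
      pred <- predict_network(arch, params, cfg, val$X)
      mean((pred - val$Y)^2)
    }
    history <- c(history, val_loss)
    if (verbose) {
      message(sprintf("epoch %d: train %.5f val %.5f lr %.2e",
                      ep, ep_loss / n, val_loss, opt$lr))
    }
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = ep)
      wait <- 0L; lr_wait <- 0L
    } else {
      wait <- wait + 1L
      lr_wait <- lr_wait + 1L
      if (lr_wait >= lr_patience && opt$lr > min_lr) {
        opt$lr <- max(opt$lr * lr_factor, min_lr)
        lr_wait <- 0L
      }
      if (wait >= patience) break
    }
  }
  list(params = best$params, val_loss = best$loss, history = history,
       best_epoch = best$epoch)
}

predict_network <- function(arch, params, cfg, X, batch_size = 512) {
  n <- if (is.matrix(X)) nrow(X) else dim(X)[1]
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  out <- lapply(batches, function(bi) {
    Xb <- if (is.matrix(X)) X[bi, , drop = FALSE] else X[bi, , , drop = FALSE]
    arch$forward(params, Xb, cfg, training = FALSE)$out
  })
  do.call(rbind, out)
}

# parameter count (trainable entries only, by name filter)
count_params <- function(params, skip = "_(mean|var)$") {
  nm <- names(params)[!grepl(skip, names(params))]
  sum(vapply(params[nm], length, integer(1)))
}
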