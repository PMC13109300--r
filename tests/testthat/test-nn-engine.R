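# The network engine's hand-derived gradients are validated against central
# finite differences on tiny configurations of each architecture.

num_grad_param <- function(fwd_loss, params, nm, eps = 1e-5) {
  gp <- params[[nm]]
  for (i in seq_along(gp)) {
    p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
    gp[i] <- (fwd_loss(p1) - fwd_loss(p2)) / (2 * eps)
  }
  gp
}

check_arch_gradients <- function(arch, params, cfg, X, Y) {
  fwd_loss <- function(p) {
    mean((arch$forward(p, X, cfg, training = TRUE)$out - Y)^2)
  }
  fw <- arch$forward(params, X, cfg, training = TRUE)
  ls <- leafspec:::wmse_fwd(fw$out, Y, rep(1, nrow(Y)))
  an <- arch$backward(params, fw$cache, ls$dYhat, cfg)
  for (nm in names(an)) {
    ng <- num_grad_param(fwd_loss, params, nm)
    scale <- max(abs(ng), 1e-4)
    expect_lt(max(abs(as.numeric(an[[nm]]) - as.numeric(ng))) / scale,
              5e-5, label = paste("gradient of", nm))
  }
}

test_that("CNN-LSTM gradients match finite differences", {
  set.seed(1)
  B <- 4; T <- 9
  X <- matrix(runif(B * T), B, T)
  Y <- matrix(rnorm(B * 16), B, 16)
  cfg <- cnn_lstm_config(lstm_units = c(3, 4, 5), conv_filters = c(4, 3),
                         dropout = 0, n_outputs = 16)
  set.seed(42)
  check_arch_gradients(leafspec:::cnnlstm_arch(),
                       leafspec:::cnnlstm_init(cfg, T), cfg, X, Y)
})

test_that("imputer gradients match finite differences (incl. L1/L2)", {
  set.seed(2)
  B <- 4; P <- 7
  X <- matrix(runif(B * P), B, P)
  Y <- matrix(rnorm(B * 16), B, 16)
  cfg <- imputer_config(n_filters = 4, dense_units = c(6, 5), dropout = 0,
                        l1 = 0, l2 = 0)
  set.seed(43)
  check_arch_gradients(leafspec:::imputer_arch(),
                       leafspec:::imputer_init(cfg, P), cfg, X, Y)
  # penalty gradients: loss + l1|W| + l2 W^2 differentiated exactly
  cfgp <- imputer_config(n_filters = 4, dense_units = c(6, 5), dropout = 0,
                         l1 = 1e-3, l2 = 1e-2)
  set.seed(44)
  params <- leafspec:::imputer_init(cfgp, P)
  arch <- leafspec:::imputer_arch()
  pen_loss <- function(p) {
    mean((arch$forward(p, X, cfgp, training = TRUE)$out - Y)^2) +
      cfgp$l1 * (sum(abs(p$d1_W)) + sum(abs(p$d2_W))) +
      cfgp$l2 * (sum(p$d1_W^2) + sum(p$d2_W^2))
  }
  fw <- arch$forward(params, X, cfgp, training = TRUE)
  ls <- leafspec:::wmse_fwd(fw$out, Y, rep(1, B))
  an <- arch$backward(params, fw$cache, ls$dYhat, cfgp)
  ng <- num_grad_param(pen_loss, params, "d1_W")
  expect_lt(max(abs(as.numeric(an$d1_W) - as.numeric(ng))) /
              max(abs(ng)), 1e-5)
})

test_that("Transformer gradients match finite differences", {
  set.seed(3)
  B <- 3; T <- 8
  X <- matrix(runif(B * T), B, T)
  Y <- matrix(rnorm(B * 16), B, 16)
  cfg <- transformer_config(embed_dim = 6, n_blocks = 2, n_heads = 2,
                            key_dim = 3, ff_units = 7, dropout = 0,
                            n_outputs = 16)
  set.seed(45)
  check_arch_gradients(leafspec:::transformer_arch(),
                       leafspec:::transformer_init(cfg, T), cfg, X, Y)
})

test_that("LSTM parameter count follows the standard formula", {
  # 4 * (H*(I+H) + H) trainable entries for one layer
  cfg <- cnn_lstm_config(lstm_units = c(289, 268, 64),
                         conv_filters = c(64, 32))
  p <- leafspec:::cnnlstm_init(cfg, 204)
  n1 <- length(p$lstm1_Wx) + length(p$lstm1_Wh) + length(p$lstm1_b)
  expect_equal(n1, 4 * (289 * (1 + 289) + 289))  # 336,396
  n2 <- length(p$lstm2_Wx) + length(p$lstm2_Wh) + length(p$lstm2_b)
  expect_equal(n2, 4 * (268 * (289 + 268) + 268))
})

test_that("training reduces the loss on a learnable toy problem", {
  set.seed(6)
  n <- 120; T <- 12
  X <- matrix(runif(n * T), n, T)
  Y <- cbind(2 * X[, 3] - X[, 9], X[, 5])
  cfg <- imputer_config(n_filters = 4, dense_units = c(16, 8), dropout = 0,
                        epochs = 40, batch_size = 16, patience = 40)
  cfg$n_outputs <- 2L
  arch <- leafspec:::imputer_arch()
  params <- leafspec:::imputer_init(cfg, T)
  loss0 <- mean((arch$forward(params, X, cfg, FALSE)$out - Y)^2)
  fit <- leafspec:::fit_network(arch, params, cfg, X, Y, epochs = 40,
                                batch_size = 16, lr = 1e-2, patience = 40)
  pred <- leafspec:::predict_network(arch, fit$params, cfg, X)
  expect_lt(mean((pred - Y)^2), loss0 / 10)
})

test_that("weighted loss with equal weights matches the unweighted loss", {
  set.seed(7)
  Yh <- matrix(rnorm(40), 8); Y <- matrix(rnorm(40), 8)
  l1 <- leafspec:::wmse_fwd(Yh, Y, rep(1, 8))
  expect_equal(l1$loss, mean((Yh - Y)^2))
  # doubling one sample's weight doubles its gradient rows
  w <- rep(1, 8); w[3] <- 2
  l2 <- leafspec:::wmse_fwd(Yh, Y, w)
  expect_equal(l2$dYhat[3, ], 2 * l1$dYhat[3, ])
  expect_equal(l2$dYhat[1, ], l1$dYhat[1, ])
})
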