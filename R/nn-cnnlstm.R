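#' CNN-LSTM regressor configuration
#'
#' Hybrid architecture for trait regression from representative-band
#' spectra: an LSTM branch (three layers; dropout after the first two)
#' processes the bands as an ordered sequence in ascending wavelength and
#' emits its final hidden state, while a CNN branch (two 1-D convolutions
#' with kernel 3, dropout after the first, global average pooling, then a
#' dense layer) extracts local spectral features. The two branch vectors --
#' which must have equal width -- are combined by additive fusion, passed
#' through a 50-unit ReLU layer with batch normalisation and dropout, and a
#' linear output layer with one node per trait (1 for single-trait models,
#' 16 for the multi-trait model).
#'
#' The defaults are the selected full-scale protocol (LSTM 289/268/64 units,
#' conv filters 64/32, dropout 0.16, learning rate 5.5e-4, batch 32, up to
#' 300 epochs with early stopping). `test_mode = TRUE` switches to a reduced
#' preset (LSTM 32/32/32, conv 32/16, learning rate 5e-3, batch 16,
#' <= 30 epochs) sized for unit tests and desk-scale experiments on
#' synthetic data; the higher learning rate compensates for the short
#' epoch budget.
#'
#' @param lstm_units Integer vector of three LSTM layer widths; the third is
#'   also the fusion width.
#' @param conv_filters Two conv-branch filter counts.
#' @param kernel Convolution kernel size (default 3).
#' @param dropout Dropout rate after the first two LSTM layers, the first
#'   convolution and the fusion head.
#' @param head_units Width of the fused head layer (default 50).
#' @param n_outputs 1 (single-trait) or 16 (multi-trait).
#' @param learning_rate,batch_size,epochs,patience Training protocol; early
#'   stopping monitors validation loss and restores the best weights, with
#'   learning-rate decay on plateau.
#' @param test_mode Use the reduced preset.
#' @return A `cnn_lstm_config` list.
#' @export
cnn_lstm_config <- function(lstm_units = c(289, 268, 64),
                            conv_filters = c(64, 32), kernel = 3,
                            dropout = 0.16, head_units = 50, n_outputs = 16,
                            learning_rate = 5.5e-4, batch_size = 32,
                            epochs = 300, patience = 10,
                            test_mode = FALSE) {
  if (test_mode) {
    if (missing(lstm_units)) lstm_units <- c(32, 32, 32)
    if (missing(conv_filters)) conv_filters <- c(32, 16)
    if (missing(learning_rate)) learning_rate <- 5e-3
    if (missing(batch_size)) batch_size <- 16
    if (missing(epochs)) epochs <- 30
    if (missing(patience)) patience <- 8
  }
  if (length(lstm_units) != 3) abort("lstm_units must have length 3")
  if (!n_outputs %in% c(1L, 16L)) abort("n_outputs must be 1 or 16")
  structure(
    list(arch = "cnn_lstm", lstm_units = as.integer(lstm_units),
         conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
         dropout = dropout, head_units = as.integer(head_units),
         n_outputs = as.integer(n_outputs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         patience = as.integer(patience), test_mode = test_mode),
    class = "cnn_lstm_config"
  )
}

cnnlstm_init <- function(cfg, n_bands) {
  u <- cfg$lstm_units
  cf <- cfg$conv_filters
  K <- cfg$kernel
  p <- list()
  p[paste0("lstm1_", c("Wx", "Wh", "b"))] <- lstm_init(1L, u[1])
  p[paste0("lstm2_", c("Wx", "Wh", "b"))] <- lstm_init(u[1], u[2])
  p[paste0("lstm3_", c("Wx", "Wh", "b"))] <- lstm_init(u[2], u[3])
  p$conv1_W <- glorot(K * 1, cf[1], c(K * 1, cf[1]))
  p$conv1_b <- numeric(cf[1])
  p$conv2_W <- glorot(K * cf[1], cf[2], c(K * cf[1], cf[2]))
  p$conv2_b <- numeric(cf[2])
  p$convd_W <- glorot(cf[2], u[3])
  p$convd_b <- numeric(u[3])
  p$head_W <- glorot(u[3], cfg$head_units)
  p$head_b <- numeric(cfg$head_units)
  p$bnh_gamma <- rep(1, cfg$head_units)
  p$bnh_beta <- numeric(cfg$head_units)
  p$bnh_mean <- numeric(cfg$head_units)
  p$bnh_var <- rep(1, cfg$head_units)
  p$out_W <- glorot(cfg$head_units, cfg$n_outputs)
  p$out_b <- numeric(cfg$n_outputs)
  p
}

cnnlstm_forward <- function(params, X, cfg, training = FALSE) {
  B <- nrow(X); T <- ncol(X)
  X3 <- array(X, c(B, T, 1L))
  ca <- list()
  # LSTM branch
  ca$l1 <- lstm_fwd(X3, list(Wx = params$lstm1_Wx, Wh = params$lstm1_Wh,
                             b = params$lstm1_b))
  ca$do1 <- dropout_fwd(ca$l1$out, cfg$dropout, training)
  ca$l2 <- lstm_fwd(ca$do1$out, list(Wx = params$lstm2_Wx,
                                     Wh = params$lstm2_Wh, b = params$lstm2_b))
  ca$do2 <- dropout_fwd(ca$l2$out, cfg$dropout, training)
  ca$l3 <- lstm_fwd(ca$do2$out, list(Wx = params$lstm3_Wx,
                                     Wh = params$lstm3_Wh, b = params$lstm3_b))
  h_seq <- ca$l3$out
  h_last <- h_seq[, T, , drop = FALSE]
  dim(h_last) <- c(B, dim(h_seq)[3])
  # CNN branch
  ca$c1 <- conv1d_fwd(X3, params$conv1_W, params$conv1_b, cfg$kernel)
  ca$r1 <- relu_fwd(ca$c1$out)
  ca$doc <- dropout_fwd(ca$r1$out, cfg$dropout, training)
  ca$c2 <- conv1d_fwd(ca$doc$out, params$conv2_W, params$conv2_b, cfg$kernel)
  ca$r2 <- relu_fwd(ca$c2$out)
  ca$gap <- gap_fwd(ca$r2$out)
  ca$cd <- dense_fwd(ca$gap$out, params$convd_W, params$convd_b)
  ca$rcd <- relu_fwd(ca$cd$out)
  # additive fusion + head
  fused <- h_last + ca$rcd$out
  ca$hd <- dense_fwd(fused, params$head_W, params$head_b)
  ca$rh <- relu_fwd(ca$hd$out)
  ca$bn <- batchnorm_fwd(ca$rh$out, params$bnh_gamma, params$bnh_beta,
                         params$bnh_mean, params$bnh_var, training)
  ca$doh <- dropout_fwd(ca$bn$out, cfg$dropout, training)
  ca$out <- dense_fwd(ca$doh$out, params$out_W, params$out_b)
  ca$B <- B; ca$T <- T
  if (training) {
    ca$bn_updates <- list(bnh = list(mean = ca$bn$new_mean,
                                     var = ca$bn$new_var))
  }
  list(out = ca$out$out, cache = ca)
}

cnnlstm_backward <- function(params, ca, dOut, cfg) {
  g <- list()
  d <- dense_bwd(ca$out, params$out_W, dOut)
  g$out_W <- d$dW; g$out_b <- d$db
  dx <- dropout_bwd(ca$doh, d$dX)
  bn <- batchnorm_bwd(ca$bn, params$bnh_gamma, dx)
  g$bnh_gamma <- bn$dgamma; g$bnh_beta <- bn$dbeta
  dx <- relu_bwd(ca$rh, bn$dX)
  d <- dense_bwd(ca$hd, params$head_W, dx)
  g$head_W <- d$dW; g$head_b <- d$db
  dfused <- d$dX
  # CNN branch
  dx <- relu_bwd(ca$rcd, dfused)
  d <- dense_bwd(ca$cd, params$convd_W, dx)
  g$convd_W <- d$dW; g$convd_b <- d$db
  dx3 <- gap_bwd(ca$gap, d$dX)
  dx3 <- relu_bwd(ca$r2, dx3)
  cb <- conv1d_bwd(ca$c2, params$conv2_W, params$conv2_b, cfg$kernel, dx3)
  g$conv2_W <- cb$dW; g$conv2_b <- cb$db
  dx3 <- dropout_bwd(ca$doc, cb$dX)
  dx3 <- relu_bwd(ca$r1, dx3)
  cb <- conv1d_bwd(ca$c1, params$conv1_W, params$conv1_b, cfg$kernel, dx3)
  g$conv1_W <- cb$dW; g$conv1_b <- cb$db
  dX_cnn <- cb$dX
  # LSTM branch: gradient enters only at the last timestep
  u3 <- dim(ca$l3$out)[3]
  dH3 <- array(0, dim(ca$l3$out))
  dH3[, ca$T, ] <- dfused
  lb <- lstm_bwd(ca$l3, list(Wx = params$lstm3_Wx, Wh = params$lstm3_Wh,
                             b = params$lstm3_b), dH3)
  g$lstm3_Wx <- lb$dWx; g$lstm3_Wh <- lb$dWh; g$lstm3_b <- lb$db
  dx3 <- dropout_bwd(ca$do2, lb$dX)
  lb <- lstm_bwd(ca$l2, list(Wx = params$lstm2_Wx, Wh = params$lstm2_Wh,
                             b = params$lstm2_b), dx3)
  g$lstm2_Wx <- lb$dWx; g$lstm2_Wh <- lb$dWh; g$lstm2_b <- lb$db
  dx3 <- dropout_bwd(ca$do1, lb$dX)
  lb <- lstm_bwd(ca$l1, list(Wx = params$lstm1_Wx, Wh = params$lstm1_Wh,
                             b = params$lstm1_b), dx3)
  g$lstm1_Wx <- lb$dWx; g$lstm1_Wh <- lb$dWh; g$lstm1_b <- lb$db
  g
}

cnnlstm_arch <- function() {
  list(forward = cnnlstm_forward, backward = cnnlstm_backward)
}

#' Build an untrained trait-regression model
#'
#' Instantiates the configured architecture for a given number of input
#' bands. The returned object carries the initial parameters and a summary
#' of the layer graph; [fit_trait_model()] trains it.
#'
#' @param cfg A [cnn_lstm_config()] or [transformer_config()].
#' @param n_bands Number of representative-band input features (>= kernel).
#' @param seed Integer seed for weight initialisation.
#' @return A `trait_model` object with elements `cfg`, `params`,
#'   `n_bands`, `n_params`.
#' @export
build_model <- function(cfg, n_bands, seed = 1L) {
  if (n_bands < cfg$kernel %||% 3) abort("n_bands must be >= the kernel size")
  set.seed(seed)
  params <- switch(cfg$arch,
    cnn_lstm = cnnlstm_init(cfg, n_bands),
    transformer = transformer_init(cfg, n_bands),
    abort("unknown architecture")
  )
  structure(
    list(cfg = cfg, params = params, n_bands = as.integer(n_bands),
         n_params = count_params(params), trained = FALSE),
    class = "trait_model"
  )
}

#' @exportS3Method base::print
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> %s, %d input bands, %d output(s), %s params%s\n",
              x$cfg$arch, x$n_bands, x$cfg$n_outputs,
              format(x$n_params, big.mark = ","),
              if (x$trained) ", trained" else ""))
  invisible(x)
}

model_arch <- function(cfg) {
  switch(cfg$arch,
    cnn_lstm = cnnlstm_arch(),
    transformer = transformer_arch(),
    abort("unknown architecture"))
}

#' Train a trait model on band features
#'
#' Low-level fit on already-scaled features/targets: sample-weighted mean
#' squared error, Adam, early stopping on a validation set with best-weight
#' restoration and learning-rate decay on plateau. Most users should call
#' [train_cv()], which handles fold construction and target scaling.
#'
#' @param model A `trait_model` from [build_model()].
#' @param x Feature matrix (samples x bands).
#' @param y Target matrix (samples x n_outputs), already scaled.
#' @param weights Per-sample loss weights (default all 1).
#' @param validation Optional `list(x, y)` monitored for early stopping; if
#'   omitted, 10% of the rows are held out.
#' @param seed Integer seed (shuffling, dropout).
#' @return The model with trained `params`, `history` and `best_epoch`.
#' @export
fit_trait_model <- function(model, x, y, weights = NULL, validation = NULL,
                            seed = 1L) {
  cfg <- model$cfg
  y <- as.matrix(y)
  if (ncol(y) != cfg$n_outputs) abort("target width must equal n_outputs")
  if (ncol(x) != model$n_bands) abort("feature width differs from build_model()")
  set.seed(seed)
  if (is.null(validation)) {
    hold <- sample.int(nrow(x), max(1L, round(0.1 * nrow(x))))
    validation <- list(x = x[hold, , drop = FALSE], y = y[hold, , drop = FALSE])
    keep <- setdiff(seq_len(nrow(x)), hold)
    x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
    weights <- weights[keep]
  }
  fit <- fit_network(
    model_arch(cfg), model$params, cfg, x, y, weights = weights,
    val = list(X = validation$x, Y = validation$y),
    epochs = cfg$epochs, batch_size = cfg$batch_size,
    lr = cfg$learning_rate, patience = cfg$patience,
    lr_factor = cfg$lr_factor %||% 0.5,
    lr_patience = cfg$lr_patience %||% 5,
    min_lr = cfg$min_lr %||% 1e-6
  )
  model$params <- fit$params
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$val_loss <- fit$val_loss
  model$trained <- TRUE
  model
}

#' Predict traits from band features
#'
#' @param object A trained `trait_model`.
#' @param x Feature matrix with the width the model was built for.
#' @param ... Unused.
#' @return Matrix of predictions (samples x n_outputs) on the scale the
#'   model was trained on.
#' @export
predict.trait_model <- function(object, x, ...) {
  if (!object$trained) abort("model has not been trained")
  if (ncol(x) != object$n_bands) abort("feature width mismatch")
  predict_network(model_arch(object$cfg), object$params, object$cfg,
                  as.matrix(x))
}
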