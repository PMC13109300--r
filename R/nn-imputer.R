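#' Trait-imputer configuration
#'
#' A small convolutional network that predicts all 16 traits jointly from
#' the retained principal-component scores of the smoothed spectra: a 1-D
#' convolution (32 filters, kernel 3) over the PC sequence with batch
#' normalisation and dropout, flattened into two ReLU dense layers (128 and
#' 64 units, L1+L2 regularised), and a 16-node linear output. Targets are
#' log-transformed and per-trait standardised before training (scalers fit
#' on the training split only); predictions are inverse-transformed and
#' exponentiated, so imputed values are strictly positive.
#'
#' @param n_filters,kernel Convolution width and kernel.
#' @param dense_units Widths of the two dense layers.
#' @param dropout Dropout rate after batch normalisation (default 0.2).
#' @param l1,l2 Regularisation strengths on the dense weights.
#' @param learning_rate,epochs,batch_size,patience Adam/early-stopping
#'   protocol (MSE loss, learning rate 0.001).
#' @param cv_folds Folds for [cv_evaluate_imputer()] (stratified by
#'   dataset).
#' @param test_mode Reduced epochs for desk-scale runs.
#' @return An `imputer_config` list.
#' @export
imputer_config <- function(n_filters = 32, kernel = 3,
                           dense_units = c(128, 64), dropout = 0.2,
                           l1 = 1e-5, l2 = 1e-4, learning_rate = 1e-3,
                           epochs = 200, batch_size = 32, patience = 10,
                           cv_folds = 5, test_mode = FALSE) {
  if (test_mode && missing(epochs)) epochs <- 30
  if (cv_folds < 2) abort("cv_folds must be >= 2")
  structure(
    list(arch = "imputer", n_filters = as.integer(n_filters),
         kernel = as.integer(kernel), dense_units = as.integer(dense_units),
         dropout = dropout, l1 = l1, l2 = l2,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         cv_folds = as.integer(cv_folds), n_outputs = 16L),
    class = "imputer_config"
  )
}

imputer_init <- function(cfg, n_pc) {
  K <- cfg$kernel; F1 <- cfg$n_filters; du <- cfg$dense_units
  p <- list()
  p$conv_W <- glorot(K * 1, F1, c(K * 1, F1))
  p$conv_b <- numeric(F1)
  p$bnc_gamma <- rep(1, F1)
  p$bnc_beta <- numeric(F1)
  p$bnc_mean <- numeric(F1)
  p$bnc_var <- rep(1, F1)
  p$d1_W <- glorot(n_pc * F1, du[1])
  p$d1_b <- numeric(du[1])
  p$d2_W <- glorot(du[1], du[2])
  p$d2_b <- numeric(du[2])
  p$out_W <- glorot(du[2], cfg$n_outputs)
  p$out_b <- numeric(cfg$n_outputs)
  p
}

imputer_forward <- function(params, X, cfg, training = FALSE) {
  B <- nrow(X); P <- ncol(X)
  X3 <- array(X, c(B, P, 1L))
  ca <- list(B = B, P = P)
  ca$conv <- conv1d_fwd(X3, params$conv_W, params$conv_b, cfg$kernel)
  # batch norm per channel over all (sample, position) pairs
  ca$bn <- batchnorm_fwd(bt_mat(ca$conv$out), params$bnc_gamma,
                         params$bnc_beta, params$bnc_mean, params$bnc_var,
                         training)
  ca$r0 <- relu_fwd(ca$bn$out)
  ca$do <- dropout_fwd(ca$r0$out, cfg$dropout, training)
  ca$fl <- flatten_fwd(unbt_mat(ca$do$out, B, P))
  ca$d1 <- dense_fwd(ca$fl$out, params$d1_W, params$d1_b)
  ca$r1 <- relu_fwd(ca$d1$out)
  ca$d2 <- dense_fwd(ca$r1$out, params$d2_W, params$d2_b)
  ca$r2 <- relu_fwd(ca$d2$out)
  ca$out <- dense_fwd(ca$r2$out, params$out_W, params$out_b)
  if (training) {
    ca$bn_updates <- list(bnc = list(mean = ca$bn$new_mean,
                                     var = ca$bn$new_var))
  }
  list(out = ca$out$out, cache = ca)
}

imputer_backward <- function(params, ca, dOut, cfg) {
  g <- list()
  d <- dense_bwd(ca$out, params$out_W, dOut)
  g$out_W <- d$dW; g$out_b <- d$db
  dx <- relu_bwd(ca$r2, d$dX)
  d <- dense_bwd(ca$d2, params$d2_W, dx)
  g$d2_W <- d$dW + cfg$l1 * sign(params$d2_W) + 2 * cfg$l2 * params$d2_W
  g$d2_b <- d$db
  dx <- relu_bwd(ca$r1, d$dX)
  d <- dense_bwd(ca$d1, params$d1_W, dx)
  g$d1_W <- d$dW + cfg$l1 * sign(params$d1_W) + 2 * cfg$l2 * params$d1_W
  g$d1_b <- d$db
  dx3 <- flatten_bwd(ca$fl, d$dX)
  dx <- dropout_bwd(ca$do, bt_mat(dx3))
  dx <- relu_bwd(ca$r0, dx)
  bn <- batchnorm_bwd(ca$bn, params$bnc_gamma, dx)
  g$bnc_gamma <- bn$dgamma; g$bnc_beta <- bn$dbeta
  cb <- conv1d_bwd(ca$conv, params$conv_W, params$conv_b, cfg$kernel,
                   unbt_mat(bn$dX, ca$B, ca$P))
  g$conv_W <- cb$dW; g$conv_b <- cb$db
  g
}

imputer_arch <- function() {
  list(forward = imputer_forward, backward = imputer_backward)
}

# log/standardise target scalers; shifted log when a trait has zeros
make_log_scalers <- function(Y) {
  shifts <- vapply(seq_len(ncol(Y)), function(j) {
    if (any(Y[, j] <= 0, na.rm = TRUE)) {
      warn(sprintf("trait %s has non-positive values; using shifted log",
                   colnames(Y)[j]))
      1e-6 * stats::median(Y[, j], na.rm = TRUE) +
        max(0, -min(Y[, j], na.rm = TRUE))
    } else 0
  }, numeric(1))
  L <- log(sweep(Y, 2L, shifts, `+`))
  list(shift = shifts, mean = colMeans(L, na.rm = TRUE),
       sd = apply(L, 2L, stats::sd, na.rm = TRUE))
}
log_scale <- function(Y, sc) {
  L <- log(sweep(Y, 2L, sc$shift, `+`))
  sweep(sweep(L, 2L, sc$mean), 2L, pmax(sc$sd, 1e-12), `/`)
}
log_unscale <- function(Z, sc) {
  L <- sweep(sweep(Z, 2L, pmax(sc$sd, 1e-12), `*`), 2L, sc$mean, `+`)
  sweep(exp(L), 2L, sc$shift)
}

#' Cross-validated evaluation of the trait imputer
#'
#' Runs dataset-stratified k-fold cross-validation of the imputer on the
#' fully labeled samples and reports per-trait R-squared and NRMSE on the
#' original trait scale (averaged over folds). The per-trait R-squared,
#' clipped to \[0, 1\], becomes the `accuracy` used by
#' [compute_sample_weights()].
#'
#' @param pcs Matrix of retained PC scores with sample ids as rownames
#'   (from [pca_transform()]).
#' @param traits A long trait tibble, complete for the fully labeled set
#'   (run [rtm_fill_traits()] first).
#' @param cfg An [imputer_config()].
#' @param seed Integer seed.
#' @return An `imputation_report` tibble: `trait`, `r2`, `nrmse`,
#'   `accuracy`.
#' @export
cv_evaluate_imputer <- function(pcs, traits, cfg = imputer_config(),
                                seed = 1L) {
  traits <- as_leaf_traits(traits)
  ids <- fully_labeled_ids(traits)
  if (length(ids) < cfg$cv_folds) abort("too few fully labeled samples")
  Y <- trait_matrix(dplyr::filter(traits, .data$sample_id %in% ids))
  X <- pcs[rownames(Y), , drop = FALSE]
  ds <- sample_datasets(traits)[rownames(Y)]
  folds <- make_stratified_folds(ds, cfg$cv_folds, seed)
  per_fold <- vector("list", cfg$cv_folds)
  set.seed(seed)
  for (f in seq_len(cfg$cv_folds)) {
    tr <- folds != f
    sc <- make_log_scalers(Y[tr, , drop = FALSE])
    fx <- feature_scaler(X[tr, , drop = FALSE])
    Xtr <- apply_feature_scaler(X[tr, , drop = FALSE], fx)
    Xte <- apply_feature_scaler(X[!tr, , drop = FALSE], fx)
    Ytr <- log_scale(Y[tr, , drop = FALSE], sc)
    sp <- train_val_split(Xtr, Ytr, seed + f)
    fit <- fit_network(imputer_arch(), imputer_init(cfg, ncol(X)), cfg,
                       sp$X, sp$Y, epochs = cfg$epochs,
                       batch_size = cfg$batch_size, lr = cfg$learning_rate,
                       patience = cfg$patience, val = sp$val)
    pred <- log_unscale(
      predict_network(imputer_arch(), fit$params, cfg, Xte), sc)
    colnames(pred) <- colnames(Y)
    per_fold[[f]] <- evaluation_report(Y[!tr, , drop = FALSE], pred)
  }
  rep <- dplyr::bind_rows(per_fold) %>%
    dplyr::group_by(.data$trait) %>%
    dplyr::summarise(r2 = mean(.data$r2), nrmse = mean(.data$nrmse),
                     .groups = "drop") %>%
    dplyr::mutate(accuracy = pmin(pmax(.data$r2, 0), 1)) %>%
    dplyr::arrange(match(.data$trait, leaf_trait_order()))
  structure(rep, class = c("imputation_report", class(rep)))
}

#' Impute missing trait values from PC scores
#'
#' Trains the imputer on the entire fully labeled set and predicts the
#' partially labeled samples; only missing cells are replaced (provenance
#' `"imputed"`), measured and RTM-derived cells are untouched.
#'
#' @inheritParams cv_evaluate_imputer
#' @return The completed trait tibble.
#' @export
fit_and_impute <- function(pcs, traits, cfg = imputer_config(), seed = 1L) {
  traits <- as_leaf_traits(traits)
  ids <- fully_labeled_ids(traits)
  need <- traits %>%
    dplyr::filter(.data$provenance == "missing") %>%
    dplyr::pull("sample_id") %>% unique()
  if (length(need) == 0L) return(traits)
  Y <- trait_matrix(dplyr::filter(traits, .data$sample_id %in% ids))
  X <- pcs[rownames(Y), , drop = FALSE]
  sc <- make_log_scalers(Y)
  fx <- feature_scaler(X)
  set.seed(seed)
  sp <- train_val_split(apply_feature_scaler(X, fx), log_scale(Y, sc), seed)
  fit <- fit_network(imputer_arch(), imputer_init(cfg, ncol(X)), cfg,
                     sp$X, sp$Y, epochs = cfg$epochs,
                     batch_size = cfg$batch_size, lr = cfg$learning_rate,
                     patience = cfg$patience, val = sp$val)
  Xn <- apply_feature_scaler(pcs[need, , drop = FALSE], fx)
  pred <- log_unscale(predict_network(imputer_arch(), fit$params, cfg, Xn),
                      sc)
  rownames(pred) <- need
  colnames(pred) <- colnames(Y)
  miss <- which(traits$provenance == "missing" & traits$sample_id %in% need)
  traits$value[miss] <- pred[cbind(traits$sample_id[miss], traits$trait[miss])]
  traits$provenance[miss] <- "imputed"
  traits
}

#' Reliability-based sample weights
#'
#' Each sample's raw weight is the mean, over the 16 traits, of a per-cell
#' accuracy: 1 for measured or RTM-derived cells, and the imputer's
#' cross-validated R-squared (clipped to \[0, 1\]) for imputed cells.
#' Weights are normalised by the cohort mean, so they average exactly 1 and
#' fully measured samples never weigh less than imputed ones. The weights
#' multiply the per-sample loss during regressor training.
#'
#' @param traits A completed long trait tibble (no missing cells).
#' @param report An `imputation_report` from [cv_evaluate_imputer()].
#' @param rtm_accuracy Accuracy credited to RTM-derived cells (default 1:
#'   they exist uniformly for all samples).
#' @return A tibble: `sample_id`, `weight_raw`, `weight` (mean 1).
#' @export
compute_sample_weights <- function(traits, report, rtm_accuracy = 1) {
  traits <- as_leaf_traits(traits)
  if (any(traits$provenance == "missing")) {
    abort("trait table still has missing cells; impute first")
  }
  acc <- stats::setNames(report$accuracy, report$trait)
  cell_acc <- dplyr::case_when(
    traits$provenance == "imputed" ~ unname(acc[traits$trait]),
    traits$provenance == "rtm" ~ rtm_accuracy,
    TRUE ~ 1
  )
  w <- tibble::tibble(sample_id = traits$sample_id, a = cell_acc) %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(weight_raw = mean(.data$a), .groups = "drop")
  dplyr::mutate(w, weight = .data$weight_raw / mean(.data$weight_raw))
}

# ---- shared helpers --------------------------------------------------------

fully_labeled_ids <- function(traits) {
  traits %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(ok = !any(.data$provenance == "missing") &&
                       dplyr::n() == length(leaf_trait_order()),
                     .groups = "drop") %>%
    dplyr::filter(.data$ok) %>%
    dplyr::pull("sample_id")
}

sample_datasets <- function(traits) {
  if (!"dataset_id" %in% names(traits)) {
    abort("trait table needs a dataset_id column for stratification")
  }
  d <- dplyr::distinct(traits, .data$sample_id, .data$dataset_id)
  stats::setNames(d$dataset_id, d$sample_id)
}

feature_scaler <- function(X) {
  sds <- apply(X, 2L, stats::sd)
  list(mean = colMeans(X), sd = ifelse(sds == 0, 1, sds))
}
apply_feature_scaler <- function(X, fs) {
  sweep(sweep(X, 2L, fs$mean), 2L, fs$sd, `/`)
}

# carve a validation split out of a training set (no overlap)
train_val_split <- function(X, Y, seed, frac = 0.1) {
  set.seed(seed)
  hold <- sample.int(nrow(X), max(1L, round(frac * nrow(X))))
  keep <- setdiff(seq_len(nrow(X)), hold)
  list(X = X[keep, , drop = FALSE], Y = Y[keep, , drop = FALSE],
       val = list(X = X[hold, , drop = FALSE], Y = Y[hold, , drop = FALSE]))
}
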