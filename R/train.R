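#' Dataset-stratified cross-validation folds
#'
#' Assigns samples to `n_folds` folds so that every dataset (a collection
#' date x variety batch) contributes to every fold: within each dataset the
#' samples are shuffled and dealt round-robin. A dataset with fewer samples
#' than folds cannot satisfy this and raises an error naming it.
#'
#' @param dataset_id Character/factor vector of dataset labels, one per
#'   sample.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment, same length as `dataset_id`.
#' @export
make_stratified_folds <- function(dataset_id, n_folds = 5, seed = 1L) {
  set.seed(seed)
  folds <- integer(length(dataset_id))
  for (ds in unique(dataset_id)) {
    idx <- which(dataset_id == ds)
    if (length(idx) < n_folds) {
      abort(sprintf(
        "dataset '%s' has %d sample(s); stratification needs >= %d per dataset",
        ds, length(idx), n_folds))
    }
    folds[idx] <- rep(seq_len(n_folds),
                      length.out = length(idx))[sample.int(length(idx))]
  }
  folds
}

#' Cross-validated training of a trait regressor
#'
#' Runs dataset-stratified k-fold cross-validation of a CNN-LSTM or
#' Transformer model on representative-band features. Within each fold,
#' feature and per-trait target scalers are fit on the training split only
#' and inverted before metrics (leakage guard); sample weights multiply the
#' training loss; training uses early stopping on an inner validation split
#' with best-weight restoration and plateau learning-rate decay. Every
#' sample is predicted exactly once across folds.
#'
#' @param features Numeric matrix (samples x bands), rownames = sample ids.
#' @param targets Numeric matrix (samples x traits) on the original scale;
#'   column count must equal `cfg$n_outputs`.
#' @param dataset_id Dataset label per sample (stratification).
#' @param cfg A [cnn_lstm_config()] or [transformer_config()].
#' @param weights Optional per-sample loss weights (see
#'   [compute_sample_weights()]).
#' @param n_folds Folds (default 5).
#' @param seed Integer seed.
#' @return A `cv_result`: `predictions` (tibble of `sample_id`, `fold`,
#'   `trait`, `observed`, `predicted`), `metrics` (per fold x trait),
#'   `summary` (per trait, averaged over folds), `cfg`, `folds`.
#' @export
train_cv <- function(features, targets, dataset_id, cfg,
                     weights = NULL, n_folds = 5, seed = 1L) {
  features <- as.matrix(features); targets <- as.matrix(targets)
  if (nrow(features) != nrow(targets)) abort("features/targets misaligned")
  if (ncol(targets) != cfg$n_outputs) {
    abort("target width must equal cfg$n_outputs")
  }
  if (is.null(weights)) weights <- rep(1, nrow(features))
  if (length(weights) != nrow(features)) abort("weights misaligned")
  ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  folds <- make_stratified_folds(dataset_id, n_folds, seed)
  preds <- vector("list", n_folds)
  metrics <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fx <- feature_scaler(features[tr, , drop = FALSE])
    Xtr <- apply_feature_scaler(features[tr, , drop = FALSE], fx)
    Xte <- apply_feature_scaler(features[!tr, , drop = FALSE], fx)
    ty <- feature_scaler(targets[tr, , drop = FALSE])   # per-trait standardise
    Ytr <- apply_feature_scaler(targets[tr, , drop = FALSE], ty)
    model <- build_model(cfg, ncol(features), seed = seed + f)
    model <- fit_trait_model(model, Xtr, Ytr, weights = weights[tr],
                             seed = seed + f)
    Z <- predict(model, Xte)
    Yhat <- sweep(sweep(Z, 2L, ty$sd, `*`), 2L, ty$mean, `+`)
    colnames(Yhat) <- colnames(targets)
    metrics[[f]] <- dplyr::mutate(
      evaluation_report(targets[!tr, , drop = FALSE], Yhat), fold = f,
      .before = 1)
    preds[[f]] <- tibble::tibble(
      sample_id = rep(ids[!tr], times = ncol(targets)),
      fold = f,
      trait = rep(colnames(targets), each = sum(!tr)),
      observed = as.vector(targets[!tr, , drop = FALSE]),
      predicted = as.vector(Yhat)
    )
  }
  metrics <- dplyr::bind_rows(metrics)
  out <- list(
    predictions = dplyr::bind_rows(preds),
    metrics = metrics,
    summary = metrics %>%
      dplyr::group_by(.data$trait) %>%
      dplyr::summarise(dplyr::across(c("r2", "nrmse", "rpd"), mean),
                       .groups = "drop") %>%
      dplyr::arrange(match(.data$trait, leaf_trait_order())),
    cfg = cfg, folds = folds, seed = seed
  )
  class(out) <- "cv_result"
  out
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d folds, %d trait(s)\n", x$cfg$arch,
              max(x$metrics$fold), length(unique(x$metrics$trait))))
  cat(sprintf("mean R2 %.3f, mean NRMSE %.3f\n",
              mean(x$summary$r2), mean(x$summary$nrmse)))
  invisible(x)
}

#' @rdname train_cv
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return `tidy()` returns the per-trait summary; `glance()` a one-row
#'   overview.
#' @export
tidy.cv_result <- function(x, ...) x$summary

#' @rdname train_cv
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(arch = x$cfg$arch, n_folds = max(x$metrics$fold),
                 n_traits = length(unique(x$metrics$trait)),
                 mean_r2 = mean(x$summary$r2),
                 median_r2 = stats::median(x$summary$r2),
                 mean_nrmse = mean(x$summary$nrmse))
}

#' Train single-trait models for every trait
#'
#' Convenience wrapper running [train_cv()] with a one-output model per
#' trait (identical architecture apart from the output width).
#'
#' @inheritParams train_cv
#' @param targets Matrix of all traits (one single-output model per
#'   column).
#' @return A tibble of per-trait summaries with a `trait` column.
#' @export
train_single_trait_cv <- function(features, targets, dataset_id, cfg,
                                  weights = NULL, n_folds = 5, seed = 1L) {
  cfg1 <- cfg
  cfg1$n_outputs <- 1L
  purrr::map_dfr(colnames(targets), function(tr) {
    res <- train_cv(features, targets[, tr, drop = FALSE], dataset_id,
                    cfg1, weights = weights, n_folds = n_folds, seed = seed)
    res$summary
  })
}

#' Hyperparameter grid for the CNN-LSTM
#'
#' The targeted search space: each axis lists its candidate values with the
#' selected full-scale value first, so enumeration order starts from the
#' reference configuration.
#'
#' @return A named list of candidate vectors.
#' @export
grid_search_space <- function() {
  list(
    lstm1 = c(289, 128, 64),
    lstm2 = c(268, 128, 64),
    dropout = c(0.16, 0.20, 0.30),
    conv1 = c(64, 32, 128),
    conv2 = c(32, 16, 64),
    learning_rate = c(5.5e-4, 1e-4, 1e-3),
    batch_size = c(32, 16, 64),
    epochs = c(300, 200, 100)
  )
}

#' Grid search over CNN-LSTM hyperparameters
#'
#' Evaluates configurations (in deterministic enumeration order, first axis
#' varying fastest, starting at the all-first-values configuration) by the
#' mean cross-validated validation R-squared over all traits; ties broken
#' by lower mean NRMSE, then fewer parameters.
#'
#' @param space A named list as from [grid_search_space()].
#' @param features,targets,dataset_id,weights,n_folds,seed As in
#'   [train_cv()].
#' @param budget Number of configurations to evaluate (>= 1).
#' @param base_cfg Template config supplying the non-searched fields.
#' @return A list: `best_cfg`, `results` tibble (one row per configuration
#'   evaluated, with `mean_r2`, `mean_nrmse`, `n_params`).
#' @export
grid_search <- function(space, features, targets, dataset_id,
                        weights = NULL, budget = 1L, n_folds = 5, seed = 1L,
                        base_cfg = cnn_lstm_config()) {
  if (length(space) == 0) abort("empty search space")
  if (budget < 1) abort("budget must be >= 1")
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE)
  grid <- utils::head(grid, budget)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    gg <- grid[i, ]
    cfg <- base_cfg
    cfg$lstm_units <- as.integer(c(gg$lstm1, gg$lstm2, base_cfg$lstm_units[3]))
    cfg$dropout <- gg$dropout
    cfg$conv_filters <- as.integer(c(gg$conv1, gg$conv2))
    cfg$learning_rate <- gg$learning_rate
    cfg$batch_size <- as.integer(gg$batch_size)
    cfg$epochs <- min(as.integer(gg$epochs), base_cfg$epochs)
    cv <- train_cv(features, targets, dataset_id, cfg, weights = weights,
                   n_folds = n_folds, seed = seed)
    tibble::tibble(
      config = i, mean_r2 = mean(cv$summary$r2),
      mean_nrmse = mean(cv$summary$nrmse),
      n_params = build_model(cfg, ncol(features), seed)$n_params
    )
  })
  best <- res[order(-res$mean_r2, res$mean_nrmse, res$n_params), ][1, ]
  gg <- grid[best$config, ]
  cfg <- base_cfg
  cfg$lstm_units <- as.integer(c(gg$lstm1, gg$lstm2, base_cfg$lstm_units[3]))
  cfg$dropout <- gg$dropout
  cfg$conv_filters <- as.integer(c(gg$conv1, gg$conv2))
  cfg$learning_rate <- gg$learning_rate
  cfg$batch_size <- as.integer(gg$batch_size)
  cfg$epochs <- min(as.integer(gg$epochs), base_cfg$epochs)
  list(best_cfg = cfg, results = res)
}

#' Sensitivity of the multi-trait model to imputation quality
#'
#' Trains and cross-validates the multi-trait model on three nested
#' training sets: (i) measured samples only, (ii) measured plus all imputed
#' samples, (iii) measured plus only the high-confidence imputed samples
#' (spectral dissimilarity below the retention percentile of the imputed
#' group), with identical hyperparameters and the same stratified-fold
#' protocol.
#'
#' @param features,targets,dataset_id,cfg,weights,n_folds,seed As in
#'   [train_cv()].
#' @param measured_ids,imputed_ids Sample ids of the fully measured and
#'   imputed groups.
#' @param percentile Retention percentile for scenario (iii) (default 90).
#' @return A `scenario_result` tibble: per-scenario training-set size and
#'   per-trait metrics.
#' @export
run_scenarios <- function(features, targets, dataset_id, cfg,
                          measured_ids, imputed_ids, weights = NULL,
                          percentile = 90, n_folds = 5, seed = 1L) {
  ids <- rownames(features)
  if (is.null(ids)) abort("features needs sample ids as rownames")
  if (length(imputed_ids) == 0L) {
    sets <- list(measured = measured_ids, measured_imputed = measured_ids,
                 measured_high_confidence = measured_ids)
  } else {
    diss <- dissimilarity_scores(features[imputed_ids, , drop = FALSE],
                                 features[measured_ids, , drop = FALSE])
    keep <- high_confidence_filter(diss, percentile)
    hc <- imputed_ids[keep$retained]
    sets <- list(measured = measured_ids,
                 measured_imputed = c(measured_ids, imputed_ids),
                 measured_high_confidence = c(measured_ids, hc))
  }
  if (is.null(weights)) weights <- rep(1, nrow(features))
  names(weights) <- names(weights) %||% ids
  res <- purrr::imap(sets, function(set_ids, scen) {
    sel <- ids %in% set_ids
    cv <- train_cv(features[sel, , drop = FALSE],
                   targets[sel, , drop = FALSE], dataset_id[sel], cfg,
                   weights = weights[ids[sel]], n_folds = n_folds,
                   seed = seed)
    dplyr::mutate(cv$summary, scenario = scen, n_train = sum(sel),
                  .before = 1)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("scenario_result", class(out))
  out
}

#' Plot cross-validated performance per trait
#' @param x A `cv_result` (or a list of them, named by model, to compare).
#' @param ... Unused.
#' @return A ggplot of per-trait R-squared.
#' @export
plot_cv_metrics <- function(x, ...) {
  df <- if (inherits(x, "cv_result")) {
    dplyr::mutate(x$summary, model = x$cfg$arch)
  } else {
    purrr::imap_dfr(x, function(r, nm) dplyr::mutate(r$summary, model = nm))
  }
  df$trait <- factor(df$trait, levels = leaf_trait_order())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$r2,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
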