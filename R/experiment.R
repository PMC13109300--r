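#' Desk-scale parameter-recovery experiment
#'
#' Runs the whole pipeline end to end on a synthetic study and measures how
#' well the models recover the traits that generated the spectra: simulate
#' (default: the high signal-to-noise regime), preprocess, merge bands,
#' calibrate and apply the RTM fill, cross-validate the imputer, impute,
#' weight samples, then train the multi-trait CNN-LSTM and the 16
#' single-trait models on a dataset-stratified 80/20 split and score them
#' on the held-out samples. Finally it scores spectral dissimilarity and
#' residual-vs-dissimilarity slopes on the held-out set augmented with
#' out-of-distribution spectra (same trait model, inflated structural
#' variability and noise).
#'
#' Problem sizes follow the package's desk-scale protocol: the 70-band
#' regime representation, the reduced `test_mode` architecture, at most 30
#' epochs, and a single stratified split instead of the full five-fold
#' protocol; the imputer keeps its full protocol (its PC-score input makes
#' it cheap). The full-scale protocol is available by passing full-size
#' configs to the individual functions.
#'
#' @param seed Integer seed for every stochastic step.
#' @param cfg A [synthetic_config()]; defaults to `signature_scale = 2`,
#'   the high-SNR recovery regime.
#' @param model_cfg A [cnn_lstm_config()]; defaults to the test-mode
#'   preset.
#' @param merge_threshold Band-merge threshold for the model features
#'   (default 0.99, the 70-band regime).
#' @param n_ood Number of out-of-distribution samples appended to the
#'   held-out set for the uncertainty analysis.
#' @param run_single Also train the 16 single-trait models (set `FALSE` to
#'   skip the most expensive stage).
#' @return A list with elements `multi_r2`, `single_r2` (per-trait
#'   tibbles), `imputer_report`, `slopes`, `weights`, `partition`,
#'   `calibration`, `n_bands`, and `sizes`.
#' @export
run_recovery_experiment <- function(seed = 1L,
                                    cfg = synthetic_config(signature_scale = 2),
                                    model_cfg = cnn_lstm_config(test_mode = TRUE),
                                    merge_threshold = 0.99,
                                    n_ood = 120, run_single = TRUE) {
  sim <- simulate_leaf_dataset(cfg, seed)
  sp <- preprocess_spectra(sim$spectra)
  map <- merge_bands(sp, merge_threshold)
  X <- band_values(apply_band_map(sp, map))
  part <- assemble_partition(sim$traits)

  # RTM bias calibration on the fully labeled set, then fill
  full_ids <- part$sample_id[part$labeled == "fully"]
  chl <- trait_matrix(dplyr::filter(sim$traits, .data$sample_id %in% full_ids),
                      "Chl")
  cal <- fit_scale_factor(chl[, 1],
                          sim$rtm$chl[match(rownames(chl), sim$rtm$sample_id)])
  traits <- rtm_fill_traits(sim$traits, sim$rtm, cal)

  # imputer: cross-validated accuracies, then imputation + weights
  basis <- pca_fit_retain(sp)
  pcs <- pca_transform(basis, sp)
  # the imputer is cheap (PC-score input), so it keeps its full protocol
  icfg <- imputer_config()
  report <- cv_evaluate_imputer(pcs, traits, icfg, seed = seed)
  completed <- fit_and_impute(pcs, traits, icfg, seed = seed)
  weights <- compute_sample_weights(completed, report)

  # stratified 80/20 split
  Y <- trait_matrix(completed)
  X <- X[rownames(Y), , drop = FALSE]
  ds <- sample_datasets(completed)[rownames(Y)]
  folds <- make_stratified_folds(ds, 5, seed)
  te <- folds == 5
  w <- weights$weight[match(rownames(Y), weights$sample_id)]
  fx <- feature_scaler(X[!te, , drop = FALSE])
  Xtr <- apply_feature_scaler(X[!te, , drop = FALSE], fx)
  Xte <- apply_feature_scaler(X[te, , drop = FALSE], fx)
  ty <- feature_scaler(Y[!te, , drop = FALSE])
  Ytr <- apply_feature_scaler(Y[!te, , drop = FALSE], ty)

  fit_and_score <- function(out_cols) {
    cfg1 <- model_cfg
    cfg1$n_outputs <- length(out_cols)
    m <- build_model(cfg1, ncol(X), seed = seed)
    m <- fit_trait_model(m, Xtr, Ytr[, out_cols, drop = FALSE],
                         weights = w[!te], seed = seed)
    Z <- predict(m, Xte)
    Yhat <- sweep(sweep(Z, 2L, ty$sd[out_cols], `*`), 2L,
                  ty$mean[out_cols], `+`)
    colnames(Yhat) <- colnames(Y)[out_cols]
    list(model = m, pred = Yhat,
         r2 = vapply(colnames(Yhat), function(tr) {
           evaluate_predictions(Y[te, tr], Yhat[, tr])$r2
         }, numeric(1)))
  }

  multi <- fit_and_score(seq_len(ncol(Y)))
  single_r2 <- NULL
  if (run_single) {
    single_r2 <- vapply(seq_len(ncol(Y)), function(j) {
      fit_and_score(j)$r2
    }, numeric(1))
    names(single_r2) <- colnames(Y)
  }

  # out-of-distribution spectra: same trait model, inflated structural
  # variability and smooth noise
  cfg_ood <- cfg
  cfg_ood$n_per_dataset <- rep(ceiling(n_ood / 12), 12)
  cfg_ood$structure_mode_sd <- cfg$structure_mode_sd * 2.5
  cfg_ood$noise_sd <- cfg$noise_sd * 4
  sim_ood <- simulate_leaf_dataset(cfg_ood, seed + 1000L)
  sp_ood <- preprocess_spectra(sim_ood$spectra)
  X_ood <- band_values(apply_band_map(sp_ood, map))
  Y_ood <- trait_matrix(sim_ood$traits_complete)[rownames(X_ood), ]
  Xo <- apply_feature_scaler(X_ood, fx)
  Zo <- predict(multi$model, Xo)
  Yhat_ood <- sweep(sweep(Zo, 2L, ty$sd, `*`), 2L, ty$mean, `+`)

  val_X <- rbind(Xte, Xo)
  val_Y <- rbind(Y[te, , drop = FALSE], Y_ood)
  val_P <- rbind(multi$pred, Yhat_ood)
  diss <- dissimilarity_scores(val_X, Xtr, k = 5, standardize = FALSE)
  records <- purrr::map_dfr(seq_len(ncol(Y)), function(j) {
    tibble::tibble(sample_id = diss$sample_id,
                   dissimilarity = diss$dissimilarity,
                   trait = colnames(Y)[j],
                   residual = abs(val_Y[, j] - val_P[, j]))
  })
  slopes <- residual_dissimilarity_slope(records)

  list(
    multi_r2 = tibble::tibble(trait = colnames(Y), r2 = unname(multi$r2)),
    single_r2 = if (run_single) {
      tibble::tibble(trait = colnames(Y), r2 = unname(single_r2))
    },
    imputer_report = report,
    slopes = slopes,
    weights = weights,
    partition = part,
    calibration = cal,
    n_bands = nrow(map),
    sizes = c(n = nrow(Y), n_train = sum(!te), n_test = sum(te),
              n_ood = nrow(X_ood))
  )
}
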