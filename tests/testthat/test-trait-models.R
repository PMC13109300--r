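# Model construction, stratification, and the CV protocol, at toy scale.

test_that("single- and multi-trait models differ only in the output layer", {
  cfg1 <- cnn_lstm_config(test_mode = TRUE, n_outputs = 1)
  cfg16 <- cnn_lstm_config(test_mode = TRUE, n_outputs = 16)
  m1 <- build_model(cfg1, 40, seed = 1)
  m16 <- build_model(cfg16, 40, seed = 1)
  expect_equal(ncol(m1$params$out_W), 1)
  expect_equal(ncol(m16$params$out_W), 16)
  shared <- setdiff(names(m1$params), c("out_W", "out_b"))
  for (nm in shared) {
    expect_equal(dim(m1$params[[nm]]) %||% length(m1$params[[nm]]),
                 dim(m16$params[[nm]]) %||% length(m16$params[[nm]]),
                 label = nm)
  }
  expect_error(build_model(cfg1, 2), "kernel")
  expect_error(cnn_lstm_config(n_outputs = 3), "n_outputs")
})

test_that("prediction is deterministic and matches a manual forward pass", {
  set.seed(10)
  X <- matrix(runif(6 * 12), 6, 12)
  cfg <- cnn_lstm_config(lstm_units = c(3, 3, 4), conv_filters = c(3, 2),
                         dropout = 0, n_outputs = 16)
  m <- build_model(cfg, 12, seed = 2)
  m$trained <- TRUE
  p1 <- predict(m, X)
  p2 <- predict(m, X)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(6, 16))
  expect_error(predict(m, X[, 1:5]), "width")

  # manual forward oracle for a 1-sample, tiny dense-only path: zeroing the
  # conv branch and LSTM weights isolates the head, which we can hand-roll
  mz <- m
  for (nm in grep("^(lstm|conv)", names(mz$params), value = TRUE)) {
    mz$params[[nm]][] <- 0
  }
  h_last <- rep(0, 4)                      # all-zero LSTM output
  conv_out <- pmax(mz$params$convd_b, 0)   # GAP of zeros -> dense bias
  fused <- h_last + conv_out
  hd <- pmax(drop(fused %*% mz$params$head_W) + mz$params$head_b, 0)
  # batch norm at inference with running stats (mean 0, var 1)
  bn <- mz$params$bnh_gamma * hd / sqrt(1 + 1e-5) + mz$params$bnh_beta
  manual <- drop(bn %*% mz$params$out_W) + mz$params$out_b
  got <- predict(mz, X[1, , drop = FALSE])
  expect_equal(drop(got), manual, tolerance = 1e-10)
})

test_that("stratified folds cover every dataset in every fold", {
  ds <- rep(sprintf("D%02d", 1:12), times = rep(c(6, 9), 6))
  folds <- make_stratified_folds(ds, 5, seed = 3)
  for (f in 1:5) {
    expect_setequal(unique(ds[folds == f]), unique(ds))
  }
  expect_equal(length(folds), length(ds))
  # infeasible stratification raises a named error
  expect_error(make_stratified_folds(c(rep("D01", 10), "D12"), 5),
               "D12")
})

test_that("cross-validation predicts every sample exactly once", {
  set.seed(20)
  n <- 60
  ds <- rep(sprintf("D%d", 1:6), each = 10)
  X <- matrix(runif(n * 10), n, 10,
              dimnames = list(sprintf("s%02d", 1:n), NULL))
  Y <- cbind(t1 = 2 * X[, 3] + rnorm(n, 0, 0.05))
  cfg <- cnn_lstm_config(lstm_units = c(4, 4, 4), conv_filters = c(4, 3),
                         epochs = 4, n_outputs = 1, test_mode = TRUE)
  cv <- train_cv(X, Y, ds, cfg, n_folds = 3, seed = 4)
  per_sample <- dplyr::count(cv$predictions, .data$sample_id)
  expect_equal(nrow(per_sample), n)
  expect_true(all(per_sample$n == 1))
  expect_equal(sort(unique(cv$predictions$fold)), 1:3)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(glance(cv)$n_folds, 3)
})

test_that("label shuffling collapses cross-validated R2 (leakage guard)", {
  set.seed(21)
  n <- 150
  ds <- rep(sprintf("D%d", 1:6), each = 25)
  # a global-intensity target, the kind of signal the pooled conv branch
  # picks up quickly, so the real/shuffled contrast is sharp
  X <- matrix(runif(n * 12), n, 12,
              dimnames = list(sprintf("s%03d", 1:n), NULL))
  y <- rowMeans(X) + rnorm(n, 0, 0.01)
  cfg <- cnn_lstm_config(lstm_units = c(8, 8, 8), conv_filters = c(8, 4),
                         epochs = 30, batch_size = 8, n_outputs = 1,
                         test_mode = TRUE)
  cv_real <- train_cv(X, cbind(y = y), ds, cfg, n_folds = 3, seed = 5)
  cv_null <- train_cv(X, cbind(y = sample(y)), ds, cfg, n_folds = 3,
                      seed = 5)
  expect_gt(mean(cv_real$summary$r2), 0.5)
  expect_lt(mean(cv_null$summary$r2), 0.15)
})

test_that("grid search enumerates from the reference configuration", {
  space <- grid_search_space()
  expect_equal(space$lstm1[1], 289)
  expect_equal(space$learning_rate[1], 5.5e-4)
  # budget-1 search returns the first-listed configuration
  set.seed(22)
  n <- 48
  ds <- rep(sprintf("D%d", 1:4), each = 12)
  X <- matrix(runif(n * 8), n, 8,
              dimnames = list(sprintf("s%02d", 1:n), NULL))
  Y <- cbind(t1 = X[, 2] + rnorm(n, 0, 0.1))
  tiny_space <- list(lstm1 = 4, lstm2 = 4, dropout = 0.16, conv1 = 4,
                     conv2 = 3, learning_rate = 5.5e-4, batch_size = 16,
                     epochs = 3)
  base <- cnn_lstm_config(lstm_units = c(4, 4, 4), conv_filters = c(4, 3),
                          epochs = 3, n_outputs = 1, test_mode = TRUE)
  gs <- grid_search(tiny_space, X, Y, ds, budget = 1, n_folds = 2,
                    seed = 6, base_cfg = base)
  expect_equal(nrow(gs$results), 1)
  expect_equal(gs$best_cfg$lstm_units[1:2], c(4L, 4L))
  expect_equal(gs$best_cfg$learning_rate, 5.5e-4)
  expect_error(grid_search(list(), X, Y, ds), "empty")
})

test_that("weighted training loss responds to sample weights", {
  # equal weights must reproduce the unweighted fit exactly
  set.seed(23)
  X <- matrix(runif(40 * 8), 40, 8)
  Y <- cbind(X[, 1])
  cfg <- cnn_lstm_config(lstm_units = c(3, 3, 3), conv_filters = c(3, 2),
                         epochs = 3, n_outputs = 1, test_mode = TRUE)
  m0 <- build_model(cfg, 8, seed = 7)
  f1 <- fit_trait_model(m0, X, Y, weights = rep(1, 40), seed = 7)
  f2 <- fit_trait_model(m0, X, Y, weights = NULL, seed = 7)
  expect_equal(f1$params, f2$params)
})

test_that("the Transformer baseline trains under the same protocol", {
  set.seed(30)
  n <- 90
  ds <- rep(sprintf("D%d", 1:6), each = 15)
  X <- matrix(runif(n * 10), n, 10,
              dimnames = list(sprintf("s%03d", 1:n), NULL))
  y <- rowMeans(X) + rnorm(n, 0, 0.01)
  cfg <- transformer_config(test_mode = TRUE, epochs = 15, n_outputs = 16)
  # output width 16 and constant embedding width through the blocks
  m <- build_model(cfg, 10, seed = 8)
  expect_equal(ncol(m$params$out_W), 16)
  expect_equal(dim(m$params$blk1_Wo)[2], cfg$embed_dim)
  expect_equal(dim(m$params$blk2_ff2_W)[2], cfg$embed_dim)
  cfg1 <- transformer_config(test_mode = TRUE, epochs = 30, batch_size = 8,
                             n_outputs = 1)
  cv <- train_cv(X, cbind(y = y), ds, cfg1, n_folds = 2, seed = 8)
  expect_equal(nrow(cv$summary), 1)
  expect_true(is.finite(cv$summary$r2))
  # learns the global-intensity toy clearly above chance
  expect_gt(cv$summary$r2, 0.3)
})

test_that("data-inclusion scenarios nest and report per-trait metrics", {
  set.seed(31)
  n <- 80
  ds <- rep(sprintf("D%d", 1:4), each = 20)
  X <- matrix(runif(n * 8), n, 8,
              dimnames = list(sprintf("s%03d", 1:n), NULL))
  y <- cbind(t1 = rowMeans(X) + rnorm(n, 0, 0.02))
  cfg <- cnn_lstm_config(lstm_units = c(4, 4, 4), conv_filters = c(4, 3),
                         epochs = 3, n_outputs = 1, test_mode = TRUE)
  measured <- rownames(X)[1:56]
  imputed <- rownames(X)[57:80]
  res <- run_scenarios(X, y, ds, cfg, measured_ids = measured,
                       imputed_ids = imputed, percentile = 75,
                       n_folds = 2, seed = 9)
  sizes <- unique(res[, c("scenario", "n_train")])
  expect_equal(sizes$n_train[sizes$scenario == "measured"], 56)
  expect_equal(sizes$n_train[sizes$scenario == "measured_imputed"], 80)
  # floor rule: 75% of 24 imputed -> 18 retained
  expect_equal(sizes$n_train[sizes$scenario == "measured_high_confidence"],
               56 + 18)
  expect_equal(nrow(res), 3)  # one trait x three scenarios
  # zero imputed samples collapse the scenarios onto one training set
  res0 <- run_scenarios(X[1:56, ], y[1:56, , drop = FALSE], ds[1:56], cfg,
                        measured_ids = measured, imputed_ids = character(0),
                        n_folds = 2, seed = 9)
  expect_equal(unique(res0$n_train), 56)
  expect_equal(res0$r2[res0$scenario == "measured"],
               res0$r2[res0$scenario == "measured_imputed"])
})
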