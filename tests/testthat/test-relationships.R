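test_that("averaged Spearman matches the rank formula and averages datasets", {
  # single dataset, hand-computed: ranks differ by (−2,1,1), sum d^2 = 6
  m <- cbind(N = c(1, 2, 3), P = c(3, 1, 2))
  tr <- toy_traits(m, dataset_id = rep("D1", 3))
  out <- averaged_spearman(tr)
  expect_equal(out$rho[out$trait_a == "N" & out$trait_b == "P"], -0.5)

  # monotone transform within every dataset -> 1
  m2 <- cbind(N = c(1, 2, 3, 5, 6, 9), P = exp(c(1, 2, 3, 5, 6, 9)))
  tr2 <- toy_traits(m2, dataset_id = rep(c("D1", "D2"), each = 3))
  out2 <- averaged_spearman(tr2)
  expect_equal(out2$rho[out2$trait_a == "N" & out2$trait_b == "P"], 1)
  expect_equal(out2$n_datasets[out2$trait_a == "N" & out2$trait_b == "P"], 2)

  # two datasets with rho +1 and -1 average to 0
  m3 <- cbind(N = c(1, 2, 3, 1, 2, 3), P = c(1, 2, 3, 3, 2, 1))
  tr3 <- toy_traits(m3, dataset_id = rep(c("D1", "D2"), each = 3))
  out3 <- averaged_spearman(tr3)
  expect_equal(out3$rho[out3$trait_a == "N" & out3$trait_b == "P"], 0)

  # correlation matrix view is symmetric with unit diagonal
  cm <- correlation_matrix(out3)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
})

test_that("ensemble importance concentrates on the causal band", {
  set.seed(5)
  n <- 120
  X <- matrix(runif(n * 10, 0.1, 0.9), n)
  colnames(X) <- sprintf("band_%d", seq(500, 950, 50))
  red <- dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%03d", 1:n)),
                          tibble::as_tibble(X))
  y <- 3 * X[, 7] + 0.5
  prof <- ensemble_importance(red, y, seed = 3)
  expect_equal(sum(prof$importance), 1)
  expect_true(all(prof$importance >= 0))
  expect_equal(which.max(prof$importance), 7L)
  # affine rescaling of the trait leaves the profile essentially unchanged
  # (tree learners are not exactly scale-equivariant, so compare loosely)
  prof2 <- ensemble_importance(red, 10 * y - 4, seed = 3)
  expect_equal(which.max(prof2$importance), 7L)
  expect_gt(cor(prof$importance, prof2$importance), 0.99)
  expect_error(ensemble_importance(red, rep(1, n)), "constant")
})

test_that("per-model importance favours the causal band", {
  set.seed(6)
  n <- 100
  X <- matrix(runif(n * 6), n)
  colnames(X) <- sprintf("band_%d", seq(600, 1100, 100))
  red <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(1:n)),
                          tibble::as_tibble(X))
  y <- 2 * X[, 3]
  for (m in c("rf", "xgb", "svr", "ridge")) {
    prof <- ensemble_importance(red, y, models = m, seed = 4)
    expect_equal(which.max(prof$importance), 3L, label = m)
  }
})

test_that("importance overlap implements the top-fraction set rule", {
  mk <- function(v) tibble::tibble(band = sprintf("band_%d", seq_along(v)),
                                   centre_nm = seq_along(v),
                                   importance = v / sum(v))
  a <- mk(c(10, 9, 8, rep(1, 7)))
  b <- mk(c(1, 1, 8, 9, 10, rep(1, 5)))
  expect_equal(importance_overlap(a, a), 100)
  expect_equal(importance_overlap(a, b, 0.3), 100 * 1 / 3) # share {3}
  disj <- mk(c(rep(1, 7), 10, 9, 8))
  expect_equal(importance_overlap(a, disj, 0.3), 0)
  # symmetry and range
  expect_equal(importance_overlap(a, b), importance_overlap(b, a))
})

test_that("display smoothing is a renormalised Gaussian convolution", {
  v <- c(rep(0, 9), 1, rep(0, 10))
  prof <- tibble::tibble(band = sprintf("band_%d", 1:20),
                         centre_nm = 1:20, importance = v)
  sm <- smooth_importance(prof, sigma_bands = 1.5)
  expect_equal(which.max(sm$importance), 10L)
  expect_equal(sum(sm$importance), 1)
  # uniform profile is a fixed point
  unif <- tibble::tibble(band = prof$band, centre_nm = 1:20,
                         importance = rep(1 / 20, 20))
  expect_equal(smooth_importance(unif, 2)$importance, unif$importance)
  # interior values match a plain discrete convolution oracle
  set.seed(8)
  w <- runif(20); w <- w / sum(w)
  profw <- tibble::tibble(band = prof$band, centre_nm = 1:20, importance = w)
  smw <- smooth_importance(profw, 1)$importance
  half <- 3
  kern <- dnorm(-half:half, sd = 1)
  oracle <- vapply((half + 1):(20 - half), function(i) {
    sum(w[(i - half):(i + half)] * kern) / sum(kern)
  }, numeric(1))
  ratio <- smw[(half + 1):(20 - half)] / oracle
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-8)
})
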