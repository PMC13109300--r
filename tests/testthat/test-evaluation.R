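test_that("metrics match closed-form values and the RPD identity", {
  # hand-computed toy pair
  r <- evaluate_predictions(c(0, 2), c(1, 1))
  expect_equal(r$mse, 1)
  expect_equal(r$r2, 0)
  expect_equal(r$nrmse, 0.5)
  expect_equal(r$rpd, sqrt(2))
  # perfect prediction
  y <- runif(10)
  rp <- evaluate_predictions(y, y)
  expect_equal(rp$r2, 1)
  expect_equal(rp$nrmse, 0)
  # RPD = sqrt(n/(n-1)) / sqrt(1 - R2) for any non-degenerate pair
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    yy <- rnorm(n); yh <- yy + rnorm(n, 0, runif(1, 0.1, 2))
    m <- evaluate_predictions(yy, yh)
    expect_equal(m$rpd, sqrt(n / (n - 1)) / sqrt(1 - m$r2), tolerance = 1e-10)
  }
  expect_error(evaluate_predictions(rep(1, 5), rnorm(5)), "constant")
})

test_that("kNN dissimilarity matches brute force and scales linearly", {
  # 1-D toy: mean of the 5 nearest of {0,1,2,3,4,10} from 0 is 2
  train <- matrix(c(0, 1, 2, 3, 4, 10), ncol = 1)
  d <- dissimilarity_scores(matrix(0), train, k = 5, standardize = FALSE)
  expect_equal(d$dissimilarity, 2)
  # validation equal to 5 identical training rows -> 0
  tr5 <- matrix(0.3, 5, 4)
  expect_equal(dissimilarity_scores(matrix(0.3, 1, 4), tr5, k = 5,
                                    standardize = FALSE)$dissimilarity, 0)
  # exhaustive oracle on random data
  set.seed(31)
  tr <- matrix(rnorm(50 * 20), 50)
  va <- matrix(rnorm(8 * 20), 8)
  got <- dissimilarity_scores(va, tr, k = 5, standardize = FALSE)
  oracle <- apply(va, 1, function(v) {
    mean(sort(sqrt(colSums((t(tr) - v)^2)))[1:5])
  })
  expect_equal(got$dissimilarity, oracle, tolerance = 1e-10)
  # permutation invariance in the training set, linear scaling
  got_perm <- dissimilarity_scores(va, tr[sample(50), ], k = 5,
                                   standardize = FALSE)
  expect_equal(got_perm$dissimilarity, got$dissimilarity)
  got_scaled <- dissimilarity_scores(3 * va, 3 * tr, k = 5,
                                     standardize = FALSE)
  expect_equal(got_scaled$dissimilarity, 3 * got$dissimilarity)
  expect_error(dissimilarity_scores(va, tr, k = 51), "exceeds")
})

test_that("residual-dissimilarity slopes match the closed form", {
  rec <- tibble::tibble(trait = "N",
                        dissimilarity = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                        residual = c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20))
  out <- residual_dissimilarity_slope(rec)
  expect_equal(out$slope, 2)
  expect_equal(out$intercept, 0)
  # constant residual -> slope 0
  rec0 <- dplyr::mutate(rec, residual = 3)
  expect_equal(residual_dissimilarity_slope(rec0)$slope, 0)
  # closed form on hand points
  set.seed(4)
  x <- rnorm(10); y <- rnorm(10)
  rec2 <- tibble::tibble(trait = "P", dissimilarity = x, residual = y)
  expect_equal(residual_dissimilarity_slope(rec2)$slope,
               sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
  expect_error(residual_dissimilarity_slope(
    dplyr::mutate(rec, dissimilarity = 1)), "zero variance")
})

test_that("high-confidence filter retains the floor-count prefix", {
  sc <- tibble::tibble(sample_id = sprintf("s%02d", 1:10),
                       dissimilarity = c(5, 1, 9, 2, 7, 3, 8, 4, 6, 10))
  out <- high_confidence_filter(sc, 90)
  expect_equal(sum(out$retained), 9)
  expect_false(out$retained[out$dissimilarity == 10])
  # retained max below removed min
  expect_lt(max(out$dissimilarity[out$retained]),
            min(out$dissimilarity[!out$retained]))
  # the study's bookkeeping: 665 -> 598 retained, 67 removed
  sc665 <- tibble::tibble(sample_id = as.character(1:665),
                          dissimilarity = runif(665))
  out665 <- high_confidence_filter(sc665, 90)
  expect_equal(sum(out665$retained), 598)
  expect_equal(sum(!out665$retained), 67)
  # p = 100 keeps everything
  expect_true(all(high_confidence_filter(sc, 100)$retained))
  expect_error(high_confidence_filter(sc, 0), "percentile")
})
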