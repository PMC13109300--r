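#' Regression metrics for trait predictions
#'
#' Computes the chemometric metric set on the original trait scale:
#' \deqn{MSE = \frac{1}{n}\sum_i (y_i - \hat y_i)^2}
#' \deqn{R^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2}}
#' \deqn{NRMSE = \frac{\sqrt{MSE}}{\max(y) - \min(y)}}
#' \deqn{RPD = \frac{SD(y)}{RMSE}}
#' with SD the n-1 sample standard deviation of the reference values.
#' An RPD above 2 is conventionally considered good.
#'
#' @param y Reference values (non-constant, n >= 3).
#' @param y_hat Predictions, same length.
#' @return A one-row tibble: `n`, `mse`, `rmse`, `r2`, `nrmse`, `rpd`.
#' @export
#' @examples
#' evaluate_predictions(c(0, 2), c(1, 1)) # R2 0, NRMSE 0.5, RPD sqrt(2)
evaluate_predictions <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("y and y_hat must be paired")
  ok <- is.finite(y) & is.finite(y_hat)
  y <- y[ok]; y_hat <- y_hat[ok]
  if (length(y) < 2) abort("need at least 2 finite pairs")
  if (stats::sd(y) == 0) abort("metrics undefined for constant reference values")
  mse <- mean((y - y_hat)^2)
  rmse <- sqrt(mse)
  tibble::tibble(
    n = length(y),
    mse = mse,
    rmse = rmse,
    r2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2),
    nrmse = rmse / (max(y) - min(y)),
    rpd = stats::sd(y) / rmse
  )
}

#' Per-trait evaluation report
#'
#' @param y_mat,yhat_mat Matrices (samples x traits) of reference values and
#'   predictions with matching column names.
#' @return A tibble with one row per trait and the metric columns of
#'   [evaluate_predictions()].
#' @export
evaluation_report <- function(y_mat, yhat_mat) {
  stopifnot(identical(dim(y_mat), dim(yhat_mat)))
  purrr::map_dfr(seq_len(ncol(y_mat)), function(j) {
    dplyr::bind_cols(tibble::tibble(trait = colnames(y_mat)[j]),
                     evaluate_predictions(y_mat[, j], yhat_mat[, j]))
  })
}

#' k-nearest-neighbour spectral dissimilarity
#'
#' Applicability-domain proxy: for each validation sample, the mean
#' Euclidean distance to its `k` nearest neighbours in the training set,
#' computed in the standardised representative-band feature space (the same
#' representation the regressors see; standardisation statistics come from
#' the training set). Large values flag spectra unlike anything the model
#' was trained on. Ties are broken by training-sample index.
#'
#' @param validation,training Numeric feature matrices with identical
#'   columns.
#' @param k Number of neighbours (default 5; must not exceed training size).
#' @param standardize Standardise columns with training means/sds first
#'   (default `TRUE`).
#' @return A tibble: `sample_id` (from rownames, else row index) and
#'   `dissimilarity`.
#' @export
dissimilarity_scores <- function(validation, training, k = 5,
                                 standardize = TRUE) {
  validation <- as.matrix(validation); training <- as.matrix(training)
  if (ncol(validation) != ncol(training)) abort("feature spaces differ")
  if (k > nrow(training)) abort("k exceeds the training-set size")
  if (standardize) {
    mu <- colMeans(training)
    sds <- apply(training, 2L, stats::sd)
    sds[sds == 0] <- 1
    training <- scale(training, mu, sds)
    validation <- scale(validation, mu, sds)
  }
  # squared distances via the expansion |v - t|^2 = |v|^2 + |t|^2 - 2 v.t
  d2 <- outer(rowSums(validation^2), rowSums(training^2), `+`) -
    2 * tcrossprod(validation, training)
  d2[d2 < 0] <- 0
  diss <- apply(d2, 1L, function(r) {
    nn <- order(r)[seq_len(k)]     # order() breaks ties by index
    mean(sqrt(r[nn]))
  })
  ids <- rownames(validation) %||% as.character(seq_len(nrow(validation)))
  tibble::tibble(sample_id = ids, dissimilarity = unname(diss))
}

#' Slope of prediction residuals on spectral dissimilarity
#'
#' For each trait, ordinary least squares of the absolute residual on the
#' dissimilarity score (with intercept). Positive slopes indicate that
#' predictions degrade as spectra leave the training domain -- the expected
#' applicability-domain behaviour.
#'
#' @param records A tibble with columns `dissimilarity`, `trait`,
#'   `residual` (absolute residuals).
#' @return A tibble: `trait`, `slope`, `intercept`, `n`.
#' @export
residual_dissimilarity_slope <- function(records) {
  records %>%
    dplyr::group_by(.data$trait) %>%
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) abort("need at least 3 records per trait")
      if (stats::sd(d$dissimilarity) == 0) {
        abort("slope undefined: dissimilarity has zero variance")
      }
      fit <- stats::lm(residual ~ dissimilarity, data = d)
      tibble::tibble(slope = unname(stats::coef(fit)[2]),
                     intercept = unname(stats::coef(fit)[1]),
                     n = nrow(d))
    }) %>%
    dplyr::ungroup()
}

#' Retain high-confidence samples by dissimilarity percentile
#'
#' Keeps the `floor(percentile/100 * n)` samples with the lowest
#' dissimilarity (ties broken by sample order); the rest are treated as
#' low-confidence and dropped. With the default 90th percentile, 665
#' imputed samples yield 598 retained and 67 removed.
#'
#' @param scores A tibble from [dissimilarity_scores()].
#' @param percentile Retention percentile in (0, 100\].
#' @return `scores` with a logical `retained` column.
#' @export
high_confidence_filter <- function(scores, percentile = 90) {
  if (percentile <= 0 || percentile > 100) {
    abort("percentile must be in (0, 100]")
  }
  n <- nrow(scores)
  if (n == 0) abort("empty dissimilarity table")
  n_keep <- floor(percentile / 100 * n)
  ord <- order(scores$dissimilarity, seq_len(n))
  retained <- logical(n)
  retained[ord[seq_len(n_keep)]] <- TRUE
  dplyr::mutate(scores, retained = retained)
}

#' Plot residual vs dissimilarity with per-trait OLS fits
#' @param records As in [residual_dissimilarity_slope()].
#' @return A ggplot faceted by trait.
#' @export
plot_uncertainty <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$dissimilarity, y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = "Spectral dissimilarity (kNN distance)",
                  y = "|residual|") +
    ggplot2::theme_minimal()
}
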