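#' Dataset-averaged Spearman correlations between traits
#'
#' Trait ranges differ between collection dates and varieties, so rank
#' correlations pooled over all samples can be dominated by between-dataset
#' shifts. Instead the Spearman correlation (midranks for ties) is computed
#' separately within every dataset that has enough complete pairs, and the
#' unweighted mean over those datasets is reported.
#'
#' @param traits A long trait tibble with a `dataset_id` column.
#' @param min_n Minimum complete pairs within a dataset for it to count
#'   towards a trait pair (default 3).
#' @return A tibble in long form: `trait_a`, `trait_b`, `rho` (averaged),
#'   `n_datasets`. Pairs with no valid dataset get `rho = NA` and a message.
#' @export
averaged_spearman <- function(traits, min_n = 3) {
  if (!"dataset_id" %in% names(traits)) {
    abort("averaged_spearman needs a dataset_id column")
  }
  traits <- dplyr::filter(as_leaf_traits(traits),
                          .data$provenance != "missing")
  tr_names <- intersect(leaf_trait_order(), unique(traits$trait))
  per_ds <- traits %>%
    dplyr::group_by(.data$dataset_id) %>%
    dplyr::group_map(function(d, key) {
      m <- trait_matrix(d, tr_names)
      suppressWarnings(
        stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
      ) -> rho
      nn <- crossprod(!is.na(m))      # complete pairs per trait pair
      rho[nn < min_n] <- NA
      rho
    })
  pairs <- expand.grid(trait_a = tr_names, trait_b = tr_names,
                       stringsAsFactors = FALSE)
  pairs <- tibble::as_tibble(pairs[match(pairs$trait_a, tr_names) <=
                                     match(pairs$trait_b, tr_names), ])
  res <- purrr::pmap(pairs, function(trait_a, trait_b) {
    vals <- map_dbl(per_ds, function(r) r[trait_a, trait_b])
    vals <- vals[is.finite(vals)]
    tibble::tibble(rho = if (length(vals)) mean(vals) else NA_real_,
                   n_datasets = length(vals))
  })
  out <- dplyr::bind_cols(pairs, dplyr::bind_rows(res))
  if (any(is.na(out$rho))) {
    inform(sprintf("%d trait pair(s) had no dataset with >= %d complete pairs",
                   sum(is.na(out$rho)), min_n))
  }
  out
}

#' Square matrix view of averaged trait correlations
#' @param corr Output of [averaged_spearman()].
#' @return A symmetric matrix with unit diagonal.
#' @export
correlation_matrix <- function(corr) {
  tr <- unique(c(corr$trait_a, corr$trait_b))
  m <- matrix(NA_real_, length(tr), length(tr), dimnames = list(tr, tr))
  m[cbind(corr$trait_a, corr$trait_b)] <- corr$rho
  m[cbind(corr$trait_b, corr$trait_a)] <- corr$rho
  diag(m) <- 1
  m
}

#' Ensemble band importance for one trait
#'
#' Fits four regressors -- random forest, gradient-boosted trees, a linear
#' support-vector regressor and ridge regression -- of one trait on the
#' representative band features, under 5-fold cross-validation. Importance is
#' the impurity-based importance for the tree models and the absolute
#' coefficient on standardised features for the linear models. Each
#' model-fold importance vector is normalised to sum to one; the profile is
#' their mean, renormalised.
#'
#' @param reduced A reduced spectra tibble from [apply_band_map()] (or any
#'   tibble with `band_*` columns).
#' @param trait_values Numeric response, one value per row of `reduced`.
#' @param n_folds Cross-validation folds (default 5).
#' @param models Subset of `c("rf", "xgb", "svr", "ridge")`.
#' @param seed Integer seed controlling fold assignment and the stochastic
#'   learners.
#' @return An importance tibble: `band`, `centre_nm`, `importance`
#'   (non-negative, sums to 1), with attributes `models` and `n_folds`.
#' @export
ensemble_importance <- function(reduced, trait_values, n_folds = 5,
                                models = c("rf", "xgb", "svr", "ridge"),
                                seed = 1L) {
  x <- band_values(reduced)
  y <- trait_values
  if (length(y) != nrow(x)) abort("trait_values length must match rows")
  if (nrow(x) < 30) abort("need at least 30 samples for ensemble importance")
  if (stats::sd(y) == 0) abort("importance undefined for a constant trait")
  set.seed(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = nrow(x)))
  xs <- scale(x)
  profiles <- list()
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    xt <- x[tr, , drop = FALSE]
    xts <- xs[tr, , drop = FALSE]
    yt <- y[tr]
    for (m in models) {
      imp <- switch(
        m,
        rf = {
          fit <- ranger::ranger(x = xt, y = yt, num.trees = 200,
                                importance = "impurity", seed = seed + f)
          fit$variable.importance
        },
        xgb = {
          fit <- xgboost::xgboost(
            xt, yt, nrounds = 50, max_depth = 4,
            learning_rate = 0.1, verbosity = 0, nthreads = 1
          )
          gain <- xgboost::xgb.importance(model = fit)
          v <- stats::setNames(rep(0, ncol(xt)), colnames(xt))
          v[gain$Feature] <- gain$Gain
          v
        },
        svr = {
          fit <- e1071::svm(x = xts, y = yt, kernel = "linear",
                            type = "eps-regression", scale = FALSE)
          w <- crossprod(fit$coefs, fit$SV)
          abs(drop(w))
        },
        ridge = {
          fit <- glmnet::glmnet(xts, yt, alpha = 0, lambda = 0.1,
                                standardize = FALSE)
          abs(drop(stats::coef(fit))[-1])
        },
        abort(paste0("unknown model: ", m))
      )
      imp <- pmax(imp, 0)
      if (sum(imp) > 0) imp <- imp / sum(imp)
      profiles[[length(profiles) + 1L]] <- imp
    }
  }
  prof <- Reduce(`+`, profiles) / length(profiles)
  prof <- prof / sum(prof)
  centres <- as.integer(sub("^band_", "", colnames(x)))
  structure(
    tibble::tibble(band = colnames(x), centre_nm = centres,
                   importance = unname(prof)),
    models = models, n_folds = n_folds,
    class = c("band_importance", "tbl_df", "tbl", "data.frame")
  )
}

#' Percentage of shared important bands between two traits
#'
#' The important set of a profile is its top `ceiling(top_fraction * n)`
#' bands by importance (ties broken towards the lower wavelength); the
#' overlap is `100 * |A intersect B| / |A|` with equal-size sets, so it is
#' symmetric and lies in \[0, 100\].
#'
#' @param profile_a,profile_b Importance tibbles from
#'   [ensemble_importance()] over the same bands.
#' @param top_fraction Fraction of bands deemed important (default 0.3).
#' @return Overlap percentage (scalar).
#' @export
importance_overlap <- function(profile_a, profile_b, top_fraction = 0.3) {
  if (nrow(profile_a) != nrow(profile_b)) {
    abort("profiles must cover the same bands")
  }
  k <- ceiling(top_fraction * nrow(profile_a))
  top_set <- function(p) {
    ord <- order(-p$importance, p$centre_nm)
    p$band[ord[seq_len(k)]]
  }
  a <- top_set(profile_a)
  b <- top_set(profile_b)
  100 * length(intersect(a, b)) / k
}

#' Gaussian display smoothing of an importance profile
#'
#' Convolves the profile with a discrete Gaussian kernel (renormalised at
#' the edges) and rescales to sum 1. Display only -- never feed the smoothed
#' profile back into band selection.
#'
#' @param profile An importance tibble.
#' @param sigma_bands Gaussian standard deviation in band units (> 0).
#' @return The profile with `importance` replaced by its smoothed version.
#' @export
smooth_importance <- function(profile, sigma_bands = 1) {
  if (sigma_bands <= 0) abort("sigma_bands must be > 0")
  v <- profile$importance
  n <- length(v)
  half <- max(1L, ceiling(3 * sigma_bands))
  kern <- exp(-0.5 * ((-half:half) / sigma_bands)^2)
  out <- vapply(seq_len(n), function(i) {
    idx <- (i - half):(i + half)
    ok <- idx >= 1 & idx <= n
    sum(v[idx[ok]] * kern[ok]) / sum(kern[ok])
  }, numeric(1))
  profile$importance <- out / sum(out)
  profile
}

#' Plot a band importance profile
#' @param profile An importance tibble (optionally smoothed).
#' @param trait Optional trait label for the title.
#' @return A ggplot.
#' @export
plot_band_importance <- function(profile, trait = NULL) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$centre_nm, y = .data$importance)) +
    ggplot2::geom_col(width = 5, fill = "steelblue") +
    ggplot2::labs(x = "Band centre (nm)", y = "Relative importance",
                  title = paste(c("Band importance", trait), collapse = " - ")) +
    ggplot2::theme_minimal()
}
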