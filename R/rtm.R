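#' Read externally produced radiative-transfer trait estimates
#'
#' The package does not invert the PROSPECT-PRO leaf optical model itself;
#' it consumes its per-sample outputs from a CSV adapter with columns
#' `sample_id` and any of `chl`, `car`, `ant`, `nstruct`, `protein`, `cbc`
#' (pigments in ug/cm^2, protein/CBC as mass per area).
#'
#' @param path CSV path.
#' @return A tibble of RTM estimates.
#' @export
read_rtm_estimates <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!"sample_id" %in% names(x)) abort("RTM file needs a sample_id column")
  num <- setdiff(names(x), "sample_id")
  if (any(vapply(x[num], function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    abort("RTM estimates must be non-negative")
  }
  x
}

#' Fit a multiplicative bias calibration for RTM estimates
#'
#' Physical inversion of leaf optical models tends to over- or under-shoot a
#' trait by a roughly constant factor. Regressing the estimates on the
#' reference measurements (through the origin by default, since the
#' correction is a pure scale) gives a slope; the calibration factor is its
#' reciprocal, and multiplying the estimates by it aligns them with the
#' reference scale.
#'
#' @param actual Reference measurements.
#' @param estimated Paired RTM estimates (same length, n >= 10).
#' @param with_intercept If `TRUE`, fit `estimated ~ actual` with an
#'   intercept; the slope still defines the factor.
#' @return A `scale_calibration` object: `slope`, `scale_factor` (=1/slope),
#'   `n_pairs`, `nrmse_before`, `nrmse_after`.
#' @export
#' @examples
#' set.seed(1)
#' y <- runif(50, 20, 60)
#' cal <- fit_scale_factor(y, 1.33 * y + rnorm(50, 0, 0.5))
#' cal$scale_factor  # ~0.75
fit_scale_factor <- function(actual, estimated, with_intercept = FALSE) {
  ok <- is.finite(actual) & is.finite(estimated)
  actual <- actual[ok]; estimated <- estimated[ok]
  if (length(actual) < 10) abort("need at least 10 calibration pairs")
  fit <- if (with_intercept) stats::lm(estimated ~ actual)
         else stats::lm(estimated ~ actual + 0)
  slope <- unname(stats::coef(fit)[["actual"]])
  if (slope <= 0) abort("calibration slope must be positive")
  rng <- diff(range(actual))
  nrmse <- function(err) sqrt(mean(err^2)) / rng
  structure(
    list(slope = slope, scale_factor = 1 / slope, n_pairs = length(actual),
         with_intercept = with_intercept,
         nrmse_before = nrmse(estimated - actual),
         nrmse_after = nrmse(estimated / slope - actual)),
    class = "scale_calibration"
  )
}

#' @exportS3Method base::print
print.scale_calibration <- function(x, ...) {
  cat(sprintf(
    "RTM bias calibration: slope %.3f -> scale factor %.3f (n = %d)\nNRMSE before %.3f, after %.3f\n",
    x$slope, x$scale_factor, x$n_pairs, x$nrmse_before, x$nrmse_after))
  invisible(x)
}

#' @rdname fit_scale_factor
#' @param x A `scale_calibration`.
#' @param ... Unused.
#' @export
glance.scale_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, scale_factor = x$scale_factor,
                 n_pairs = x$n_pairs, nrmse_before = x$nrmse_before,
                 nrmse_after = x$nrmse_after)
}

#' Apply a bias calibration to RTM estimates
#' @param estimates Numeric vector of raw estimates.
#' @param calibration A `scale_calibration`.
#' @return The rescaled estimates.
#' @export
apply_scale <- function(estimates, calibration) {
  estimates * calibration$scale_factor
}

#' Convert leaf protein content to total nitrogen
#'
#' Uses the canonical protein-to-nitrogen conversion factor k_p = 4.43:
#' N = protein / 4.43, in the same areal units.
#'
#' @param protein Non-negative protein content (mass per area).
#' @param k_p Conversion factor (default 4.43).
#' @return Nitrogen content.
#' @export
protein_to_nitrogen <- function(protein, k_p = 4.43) {
  if (any(protein < 0)) abort("protein must be non-negative")
  protein / k_p
}

#' Leaf mass per area from protein and carbon-based constituents
#'
#' In the PROSPECT-PRO decomposition, dry matter is the sum of protein and
#' carbon-based constituents, so LMA = protein + CBC.
#'
#' @param protein,cbc Non-negative mass-per-area values.
#' @return LMA in the same units.
#' @export
lma_from_protein_cbc <- function(protein, cbc) {
  if (any(protein < 0) || any(cbc < 0)) abort("inputs must be non-negative")
  protein + cbc
}

#' Normal-approximation confidence interval of a mean
#'
#' @param mean,sd Sample mean and standard deviation (sd >= 0).
#' @param n Sample size (>= 2).
#' @param z Critical value (default 1.96 for 95%).
#' @return A tibble with `lower` and `upper`.
#' @export
#' @examples
#' ci_of_mean(35.9, 8.6, 327)
ci_of_mean <- function(mean, sd, n, z = 1.96) {
  if (any(sd < 0)) abort("sd must be >= 0")
  if (any(n < 2)) abort("n must be >= 2")
  half <- z * sd / sqrt(n)
  tibble::tibble(lower = mean - half, upper = mean + half)
}

#' Fill a trait table with calibrated RTM-derived traits
#'
#' Completes a trait table using RTM outputs: carotenoids, anthocyanins and
#' the structural parameter are taken from the RTM for every sample (they
#' are never assayed), and chlorophyll gaps are filled with the
#' bias-calibrated RTM chlorophyll. Measured cells are never touched; filled
#' cells get provenance `"rtm"`.
#'
#' @param traits A long trait tibble.
#' @param rtm RTM estimates tibble from [read_rtm_estimates()] /
#'   [generate_rtm_estimates()].
#' @param chl_calibration A `scale_calibration` for chlorophyll, or `NULL`
#'   to use the raw estimates.
#' @return The completed trait tibble.
#' @export
rtm_fill_traits <- function(traits, rtm, chl_calibration = NULL) {
  traits <- as_leaf_traits(traits)
  chl_est <- stats::setNames(rtm$chl, rtm$sample_id)
  if (!is.null(chl_calibration)) chl_est <- apply_scale(chl_est, chl_calibration)
  fill_map <- list(Chl = chl_est,
                   Car = stats::setNames(rtm$car, rtm$sample_id),
                   Ant = stats::setNames(rtm$ant, rtm$sample_id),
                   Nstruct = stats::setNames(rtm$nstruct, rtm$sample_id))
  for (tr in names(fill_map)) {
    idx <- traits$trait == tr & traits$provenance == "missing" &
      traits$sample_id %in% names(fill_map[[tr]])
    traits$value[idx] <- unname(fill_map[[tr]][traits$sample_id[idx]])
    traits$provenance[idx] <- "rtm"
  }
  traits
}
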