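#' Preprocessing configuration
#'
#' Spectral standardisation settings: the common wavelength grid (default an
#' inclusive 1-nm grid over 400--2500 nm, i.e. 2101 points) and the
#' Savitzky-Golay smoother (default a 75-nm window -- 75 points on the 1-nm
#' grid -- with a cubic polynomial).
#'
#' @param grid_start_nm,grid_end_nm,grid_step_nm Common grid in nm.
#' @param sg_window_nm Smoother window in nm; must map to an odd number of
#'   grid points.
#' @param sg_polyorder Polynomial order, less than the window point count.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(grid_start_nm = 400, grid_end_nm = 2500,
                              grid_step_nm = 1, sg_window_nm = 75,
                              sg_polyorder = 3) {
  if (grid_end_nm <= grid_start_nm) abort("grid_end_nm must exceed grid_start_nm")
  window_pts <- round(sg_window_nm / grid_step_nm)
  if (window_pts %% 2 == 0) abort("Savitzky-Golay window must be odd in grid points")
  if (sg_polyorder >= window_pts) abort("sg_polyorder must be < window points")
  structure(
    list(grid_start_nm = grid_start_nm, grid_end_nm = grid_end_nm,
         grid_step_nm = grid_step_nm, sg_window_nm = sg_window_nm,
         sg_window_pts = window_pts, sg_polyorder = sg_polyorder),
    class = "preprocess_config"
  )
}

#' Common grid implied by a preprocessing configuration
#' @param cfg A [preprocess_config()].
#' @return Numeric vector of wavelengths (nm).
#' @export
preprocess_grid <- function(cfg = preprocess_config()) {
  seq(cfg$grid_start_nm, cfg$grid_end_nm, by = cfg$grid_step_nm)
}

#' Interpolate spectra onto the common wavelength grid
#'
#' Piecewise-linear interpolation of each sample's native-grid reflectance at
#' every grid wavelength. No extrapolation: every sample's native range must
#' cover the grid, otherwise an error names the offending samples.
#'
#' @param spectra A spectra tibble on any strictly increasing native grid.
#' @param cfg A [preprocess_config()].
#' @return A spectra tibble on the common grid.
#' @export
interpolate_spectra <- function(spectra, cfg = preprocess_config()) {
  wl <- spectra_wavelengths(spectra)
  grid <- preprocess_grid(cfg)
  if (min(wl) > grid[1] || max(wl) < grid[length(grid)]) {
    abort(sprintf(
      "native range [%.1f, %.1f] nm does not cover the grid [%g, %g] nm; refusing to extrapolate",
      min(wl), max(wl), grid[1], grid[length(grid)]))
  }
  vals <- spectra_values(spectra)
  out <- t(apply(vals, 1L, function(r) stats::approx(wl, r, xout = grid)$y))
  spectra_from_matrix(spectra, grid, out)
}

#' Savitzky-Golay smoothing of gridded spectra
#'
#' Per-sample local least-squares polynomial smoothing on the uniform grid.
#' At the spectrum edges the polynomial is fitted to the nearest full-length
#' window (no zero padding), so the pigment features near 400 nm and the
#' water features near 2500 nm are not distorted by artificial boundary
#' values.
#'
#' @param spectra A spectra tibble on a uniform grid.
#' @param cfg A [preprocess_config()].
#' @return The smoothed spectra tibble (same grid).
#' @export
smooth_spectra <- function(spectra, cfg = preprocess_config()) {
  wl <- spectra_wavelengths(spectra)
  steps <- diff(wl)
  if (max(steps) - min(steps) > 1e-8) {
    abort("smoothing requires a uniform wavelength grid; interpolate first")
  }
  n <- cfg$sg_window_pts
  if (n >= length(wl)) abort("smoother window must be shorter than the spectrum")
  vals <- spectra_values(spectra)
  sm <- t(apply(vals, 1L, signal::sgolayfilt, p = cfg$sg_polyorder, n = n))
  spectra_from_matrix(spectra, wl, sm)
}

#' Standardise and smooth spectra in one call
#'
#' Runs the fixed pipeline order: linear interpolation to the common grid,
#' then Savitzky-Golay smoothing.
#'
#' @inheritParams interpolate_spectra
#' @return A smoothed spectra tibble on the common grid.
#' @export
preprocess_spectra <- function(spectra, cfg = preprocess_config()) {
  smooth_spectra(interpolate_spectra(spectra, cfg), cfg)
}

#' Per-band mean and quantile envelope
#'
#' Summarises a spectra set by the per-wavelength mean and lower/upper
#' quantiles (default the 1%--99% envelope).
#'
#' @param spectra A spectra tibble.
#' @param q_low,q_high Envelope quantiles.
#' @return A tibble with columns `wavelength_nm`, `mean`, `q_low`, `q_high`.
#' @export
quantile_envelope <- function(spectra, q_low = 0.01, q_high = 0.99) {
  vals <- spectra_values(spectra)
  if (nrow(vals) < 2) abort("need at least 2 samples for an envelope")
  tibble::tibble(
    wavelength_nm = spectra_wavelengths(spectra),
    mean = unname(colMeans(vals)),
    q_low = unname(apply(vals, 2L, stats::quantile, probs = q_low,
                         names = FALSE)),
    q_high = unname(apply(vals, 2L, stats::quantile, probs = q_high,
                          names = FALSE))
  )
}

#' Plot the spectral envelope
#'
#' @param envelope The tibble from [quantile_envelope()].
#' @return A ggplot: mean reflectance with the quantile ribbon.
#' @export
plot_spectral_envelope <- function(envelope) {
  ggplot2::ggplot(envelope, ggplot2::aes(x = .data$wavelength_nm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q_low, ymax = .data$q_high),
                         fill = "darkgreen", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "darkgreen") +
    ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance",
                  title = "Mean reflectance and quantile envelope") +
    ggplot2::theme_minimal()
}
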