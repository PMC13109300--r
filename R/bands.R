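#' Merge adjacent, highly correlated wavelengths into representative bands
#'
#' Hyperspectral neighbours are strongly collinear; runs of adjacent
#' wavelengths whose reflectance is (almost) perfectly correlated across
#' samples carry one effective degree of freedom. This scans the grid left to
#' right: a window opens at some band, and each following band joins the
#' window while its Pearson correlation (across samples) with the window's
#' *first* band exceeds `threshold`; otherwise it opens a new window.
#' Anchoring on the first band prevents correlation drift across wide
#' windows and makes the result deterministic.
#'
#' A zero-variance band has no defined correlation; it is merged with its
#' neighbour (treated as correlation 1) and a message is logged.
#'
#' @param spectra A spectra tibble (>= 3 samples).
#' @param threshold Correlation cutoff in (0, 1). 0.99 is a sensible default
#'   for exploratory importance work; 0.999 retains more variance for
#'   predictive models.
#' @return A `band_map`: tibble with one row per window -- `window`,
#'   `start_nm`, `end_nm`, `n_bands`, plus attributes `threshold`,
#'   `wavelengths` and `index` (list of member column indices).
#' @export
merge_bands <- function(spectra, threshold = 0.99) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  vals <- spectra_values(spectra)
  if (nrow(vals) < 3) abort("need at least 3 samples to estimate correlations")
  wl <- spectra_wavelengths(spectra)
  sds <- apply(vals, 2L, stats::sd)
  n_flat <- sum(sds == 0)
  if (n_flat > 0) {
    inform(sprintf("%d zero-variance band(s) merged with their neighbours", n_flat))
  }
  windows <- list()
  anchor <- 1L
  members <- 1L
  for (j in seq_len(ncol(vals))[-1]) {
    r <- if (sds[j] == 0 || sds[anchor] == 0) 1
         else stats::cor(vals[, anchor], vals[, j])
    if (r > threshold) {
      members <- c(members, j)
    } else {
      windows[[length(windows) + 1L]] <- members
      anchor <- j
      members <- j
    }
  }
  windows[[length(windows) + 1L]] <- members
  out <- tibble::tibble(
    window = seq_along(windows),
    start_nm = wl[map_int(windows, 1L)],
    end_nm = wl[map_int(windows, function(w) w[length(w)])],
    n_bands = lengths(windows)
  )
  structure(out, class = c("band_map", class(out)),
            threshold = threshold, wavelengths = wl, index = windows,
            representative_rule = "window-mean")
}

#' Reduce spectra to representative band values
#'
#' The representative value of each window is the unweighted mean reflectance
#' over the window's member wavelengths (noise-averaging; the usual choice).
#'
#' @param spectra A spectra tibble on the same grid the map was built on.
#' @param map A `band_map` from [merge_bands()].
#' @return A tibble: metadata columns plus one `band_<centre nm>` column per
#'   window, ordered by wavelength.
#' @export
apply_band_map <- function(spectra, map) {
  wl <- spectra_wavelengths(spectra)
  if (!isTRUE(all.equal(wl, attr(map, "wavelengths")))) {
    abort("spectra grid does not match the grid the band map was built on")
  }
  vals <- spectra_values(spectra)
  idx <- attr(map, "index")
  red <- vapply(idx, function(w) rowMeans(vals[, w, drop = FALSE]),
                numeric(nrow(vals)))
  if (nrow(vals) == 1L) red <- matrix(red, nrow = 1L)
  centres <- round((map$start_nm + map$end_nm) / 2)
  colnames(red) <- sprintf("band_%d", centres)
  meta <- spectra[, intersect(names(spectra), spectra_meta_cols()), drop = FALSE]
  dplyr::bind_cols(meta, tibble::as_tibble(red))
}

#' Band-feature matrix of a reduced spectra tibble
#' @param reduced Output of [apply_band_map()].
#' @return Numeric matrix (samples x windows).
#' @export
band_values <- function(reduced) {
  cols <- grep("^band_", names(reduced), value = TRUE)
  m <- as.matrix(reduced[, cols])
  rownames(m) <- reduced$sample_id
  m
}

#' Fit a PCA basis retaining a cumulative explained-variance fraction
#'
#' Centred (unscaled) principal component analysis of the full-resolution
#' smoothed spectra; keeps the smallest number of components whose cumulative
#' explained variance reaches `variance_threshold`. The retained scores are
#' the input features of the trait imputer.
#'
#' @param spectra A spectra tibble (or any tibble with wavelength columns).
#' @param variance_threshold Cumulative explained-variance target in (0, 1];
#'   default 0.9999.
#' @return A `pca_basis` object with elements `rotation`, `center`,
#'   `explained_ratio`, `n_retained`, `variance_threshold`.
#' @export
pca_fit_retain <- function(spectra, variance_threshold = 0.9999) {
  if (variance_threshold <= 0 || variance_threshold > 1) {
    abort("variance_threshold must be in (0, 1]")
  }
  vals <- spectra_values(spectra)
  if (nrow(vals) < 2) abort("need at least 2 samples for PCA")
  fit <- stats::prcomp(vals, center = TRUE, scale. = FALSE)
  ratio <- fit$sdev^2 / sum(fit$sdev^2)
  n_keep <- which(cumsum(ratio) >= variance_threshold - 1e-12)[1]
  structure(
    list(rotation = fit$rotation[, seq_len(n_keep), drop = FALSE],
         center = fit$center,
         explained_ratio = ratio,
         n_retained = n_keep,
         variance_threshold = variance_threshold),
    class = "pca_basis"
  )
}

#' Project spectra onto a retained PCA basis
#' @param basis A `pca_basis` from [pca_fit_retain()].
#' @param spectra A spectra tibble on the same grid.
#' @return Numeric matrix of scores (samples x retained components).
#' @export
pca_transform <- function(basis, spectra) {
  vals <- spectra_values(spectra)
  scale(vals, center = basis$center, scale = FALSE) %*% basis$rotation
}

#' Reconstruct spectra from retained PCA scores
#' @param basis A `pca_basis`.
#' @param scores Matrix of scores as returned by [pca_transform()].
#' @return Reconstructed reflectance matrix.
#' @export
pca_inverse <- function(basis, scores) {
  sweep(scores %*% t(basis$rotation), 2L, basis$center, `+`)
}

#' @exportS3Method base::print
print.pca_basis <- function(x, ...) {
  cat(sprintf("PCA basis: %d component(s) retained (>= %.4f%% variance)\n",
              x$n_retained, 100 * x$variance_threshold))
  invisible(x)
}

#' Tidy a PCA basis
#' @param x A `pca_basis`.
#' @param ... Unused.
#' @return A tibble with `component`, `explained_ratio`,
#'   `cumulative_ratio`, `retained`.
#' @export
tidy.pca_basis <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained_ratio),
    explained_ratio = x$explained_ratio,
    cumulative_ratio = cumsum(x$explained_ratio),
    retained = seq_along(x$explained_ratio) <= x$n_retained
  )
}
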