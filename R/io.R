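#' Read leaf reflectance spectra from a wide CSV
#'
#' Reads a table with one row per leaf sample and one numeric-named column per
#' wavelength (nm), e.g. `400, 401, ..., 2500` or an irregular native grid
#' such as `410.3, 411.9, ...`. Metadata columns `sample_id` (required),
#' `dataset_id`, `variety` and `stage` are carried through; every other
#' column name must parse as a wavelength in nanometres.
#'
#' Reflectance is a unitless fraction in `[0, 1]`. Values outside that range
#' are clipped with a warning (calibration overshoot near strong absorption
#' features is common and clipping preserves the sample); rows containing
#' non-numeric or missing reflectance cells are dropped with a warning.
#'
#' @param path Path to a CSV file.
#' @return A spectra tibble: metadata columns followed by wavelength columns
#'   in strictly increasing order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(sample_id = c("a", "b"),
#'                      `400` = c(0.1, 0.2), `401` = c(0.11, 0.21),
#'                      check.names = FALSE), f, row.names = FALSE)
#' read_spectra(f)
read_spectra <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(raw)) {
    abort("spectra file must contain a `sample_id` column")
  }
  as_leaf_spectra(tibble::as_tibble(raw))
}

#' Validate a data frame as a spectra table
#'
#' @param x A data frame with `sample_id`, optional metadata columns
#'   (`dataset_id`, `variety`, `stage`) and numeric-named wavelength columns.
#' @return The validated spectra tibble (wavelength columns sorted).
#' @export
as_leaf_spectra <- function(x) {
  x <- tibble::as_tibble(x)
  meta_cols <- intersect(names(x), spectra_meta_cols())
  wl_cols <- setdiff(names(x), meta_cols)
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (length(wl_cols) == 0L) abort("no wavelength columns found")
  if (anyNA(wl)) {
    abort(paste0("column headers that are not wavelengths: ",
                 paste(utils::head(wl_cols[is.na(wl)], 5), collapse = ", ")))
  }
  ord <- order(wl)
  if (any(diff(wl[ord]) <= 0)) {
    abort("wavelength headers must be distinct (strictly increasing grid)")
  }
  x <- x[, c(meta_cols, wl_cols[ord])]
  vals <- as.matrix(x[, wl_cols[ord]])
  if (!is.numeric(vals)) {
    keep <- apply(vals, 1L, function(r) all(!is.na(suppressWarnings(as.numeric(r)))))
    warn(sprintf("dropping %d sample(s) with non-numeric reflectance cells",
                 sum(!keep)))
    x <- x[keep, ]
    vals <- matrix(as.numeric(as.matrix(x[, wl_cols[ord]])), nrow = nrow(x))
  }
  bad <- !is.finite(vals)
  if (any(bad)) {
    keep <- rowSums(bad) == 0L
    warn(sprintf("dropping %d sample(s) with missing reflectance cells",
                 sum(!keep)))
    x <- x[keep, ]
    vals <- vals[keep, , drop = FALSE]
  }
  n_clip <- sum(vals < 0 | vals > 1)
  if (n_clip > 0) {
    warn(sprintf("clipped %d reflectance value(s) to [0, 1]", n_clip))
    vals <- pmin(pmax(vals, 0), 1)
    x[, wl_cols[ord]] <- vals
  }
  x
}

spectra_meta_cols <- function() c("sample_id", "dataset_id", "variety", "stage")

#' Wavelength grid of a spectra tibble
#' @param spectra A spectra tibble (see [read_spectra()]).
#' @return Numeric vector of wavelengths in nm, increasing.
#' @export
spectra_wavelengths <- function(spectra) {
  wl_cols <- setdiff(names(spectra), spectra_meta_cols())
  as.numeric(wl_cols)
}

#' Reflectance values of a spectra tibble as a matrix
#' @inheritParams spectra_wavelengths
#' @return A numeric matrix, samples in rows (named by `sample_id`),
#'   wavelengths in columns.
#' @export
spectra_values <- function(spectra) {
  wl_cols <- setdiff(names(spectra), spectra_meta_cols())
  m <- as.matrix(spectra[, wl_cols])
  rownames(m) <- spectra$sample_id
  m
}

# Rebuild a spectra tibble from metadata of `template` and a values matrix.
spectra_from_matrix <- function(template, wavelengths, values) {
  meta <- template[, intersect(names(template), spectra_meta_cols()), drop = FALSE]
  vals <- tibble::as_tibble(as.data.frame(values, check.names = FALSE),
                            .name_repair = "minimal")
  names(vals) <- as.character(wavelengths)
  dplyr::bind_cols(meta, vals)
}

#' Read a trait table
#'
#' Accepts either a long table with columns `sample_id`, `trait`, `value`
#' and optionally `provenance`, or a wide table with one column per trait.
#' Missing values get provenance `"missing"`; present values default to
#' `"measured"` unless a provenance column says otherwise.
#'
#' @param path Path to a CSV file.
#' @return A long trait tibble with columns `sample_id`, `dataset_id` (if
#'   present), `trait`, `value`, `provenance`, ordered by the canonical
#'   trait order ([leaf_trait_order()]).
#' @export
read_traits <- function(path) {
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (all(c("trait", "value") %in% names(raw))) {
    as_leaf_traits(raw)
  } else {
    meta <- intersect(names(raw), spectra_meta_cols())
    long <- tidyr::pivot_longer(raw, -dplyr::all_of(meta),
                                names_to = "trait", values_to = "value")
    as_leaf_traits(long)
  }
}

#' Validate a long trait table
#'
#' @param x A data frame with at least `sample_id`, `trait`, `value`;
#'   optional `provenance` in `measured | rtm | imputed | missing` and
#'   optional metadata columns.
#' @return A validated long trait tibble.
#' @export
as_leaf_traits <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("sample_id", "trait", "value")
  if (!all(req %in% names(x))) {
    abort("trait table needs columns sample_id, trait, value")
  }
  if (nrow(x) == 0L) abort("trait table is empty")
  unknown <- setdiff(unique(x$trait), leaf_trait_order())
  if (length(unknown) > 0) {
    abort(paste0("unknown trait(s): ", paste(unknown, collapse = ", ")))
  }
  if (!"provenance" %in% names(x)) {
    x$provenance <- ifelse(is.na(x$value), "missing", "measured")
  }
  bad_prov <- setdiff(unique(x$provenance),
                      c("measured", "rtm", "imputed", "missing"))
  if (length(bad_prov) > 0) {
    abort(paste0("invalid provenance value(s): ", paste(bad_prov, collapse = ", ")))
  }
  filled <- x$provenance != "missing"
  if (any(filled & (!is.finite(x$value) | x$value < 0))) {
    abort("non-missing trait values must be finite and >= 0")
  }
  x$trait <- factor(x$trait, levels = leaf_trait_order())
  x <- dplyr::arrange(x, .data$sample_id, .data$trait)
  x$trait <- as.character(x$trait)
  x
}

#' Pivot a long trait table to the samples-by-traits value matrix
#'
#' @param traits A long trait tibble.
#' @param traits_subset Optional character vector restricting/ordering
#'   columns; defaults to all 16 canonical traits.
#' @return A numeric matrix with one row per sample (rownames `sample_id`)
#'   and one column per trait in canonical order; missing cells are `NA`.
#' @export
trait_matrix <- function(traits, traits_subset = leaf_trait_order()) {
  wide <- tidyr::pivot_wider(
    dplyr::select(traits, "sample_id", "trait", "value"),
    names_from = "trait", values_from = "value"
  )
  keep <- intersect(traits_subset, names(wide))
  m <- as.matrix(wide[, keep, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}
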