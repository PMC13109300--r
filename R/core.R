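#' Derive leaf mass per area and equivalent water thickness
#'
#' LMA (leaf mass per area) is leaf dry weight divided by leaf area; EWT
#' (equivalent water thickness) is the water mass -- fresh minus dry weight --
#' per unit leaf area. Weights are expected in grams and areas in cm^2;
#' results are returned in the package's canonical units, LMA in g/m^2 and
#' EWT in mg/cm^2.
#'
#' @param data A data frame with one row per sample.
#' @param fresh_weight,dry_weight,leaf_area_cm2 Column names (tidy-select,
#'   unquoted or strings) holding fresh weight (g), dry weight (g) and leaf
#'   area (cm^2).
#' @return `data` with columns `LMA` (g/m^2) and `EWT` (mg/cm^2) appended.
#' @export
#' @examples
#' d <- tibble::tibble(sample_id = "s1", fresh = 1.5, dry = 0.5, area = 100)
#' compute_lma_ewt(d, fresh, dry, area)  # LMA 50 g/m2, EWT 10 mg/cm2
compute_lma_ewt <- function(data, fresh_weight, dry_weight, leaf_area_cm2) {
  fresh <- dplyr::pull(data, {{ fresh_weight }})
  dry <- dplyr::pull(data, {{ dry_weight }})
  area <- dplyr::pull(data, {{ leaf_area_cm2 }})
  if (any(area <= 0)) abort("leaf area must be > 0")
  if (any(dry < 0) || any(dry > fresh)) {
    abort("need 0 <= dry_weight <= fresh_weight")
  }
  dplyr::mutate(
    data,
    LMA = dry / area * 1e4,          # g/cm2 -> g/m2
    EWT = (fresh - dry) / area * 1e3 # g/cm2 -> mg/cm2
  )
}

#' Convert a per-dry-mass trait value to a leaf-area basis (and back)
#'
#' Area-based content = mass fraction x LMA. With the mass fraction as g per
#' g dry matter and LMA in g/m^2 the result is in g/m^2; scale the inputs for
#' other unit pairs.
#'
#' @param mass_value Trait content per unit dry mass (e.g. g/g).
#' @param lma Leaf mass per area, same mass unit as `mass_value`'s
#'   denominator over the desired area unit. Must be > 0.
#' @return The area-based value (or mass fraction for the inverse).
#' @export
#' @examples
#' convert_mass_to_area(0.02, 50) # 2% N at LMA 50 g/m2 -> 1 g/m2
convert_mass_to_area <- function(mass_value, lma) {
  if (any(lma <= 0)) abort("lma must be > 0")
  mass_value * lma
}

#' @rdname convert_mass_to_area
#' @param area_value Trait content per unit leaf area.
#' @export
convert_area_to_mass <- function(area_value, lma) {
  if (any(lma <= 0)) abort("lma must be > 0")
  area_value / lma
}

#' Split samples into fully and partially labeled sets
#'
#' A sample is fully labeled when none of the 13 laboratory-measured traits
#' is missing; any sample with at least one missing measured trait is
#' partially labeled (its gaps are later imputed). The two sets are disjoint
#' and together cover every sample.
#'
#' @param traits A long trait tibble (see [as_leaf_traits()]).
#' @return A tibble with columns `sample_id` and `labeled`
#'   (`"fully"`/`"partially"`).
#' @export
assemble_partition <- function(traits) {
  traits <- as_leaf_traits(traits)
  measured <- measured_trait_names()
  part <- traits %>%
    dplyr::filter(.data$trait %in% measured) %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      n_missing = sum(.data$provenance == "missing" |
                        !(.data$trait %in% measured)) +
        (length(measured) - dplyr::n()),
      .groups = "drop"
    ) %>%
    dplyr::mutate(labeled = ifelse(.data$n_missing == 0L, "fully", "partially")) %>%
    dplyr::select("sample_id", "labeled")
  # samples present in the table but with no measured-trait rows at all
  missing_ids <- setdiff(unique(traits$sample_id), part$sample_id)
  if (length(missing_ids) > 0) {
    part <- dplyr::bind_rows(
      part, tibble::tibble(sample_id = missing_ids, labeled = "partially")
    )
  }
  inform(sprintf("partition: %d fully labeled, %d partially labeled",
                 sum(part$labeled == "fully"), sum(part$labeled == "partially")))
  dplyr::arrange(part, .data$sample_id)
}

#' Flag implausibly large trait values
#'
#' Cells whose value exceeds `factor` times the per-trait median of measured
#' cells are flagged as likely contamination (e.g. soil iron/zinc on the leaf
#' surface). Use [apply_anomaly_filter()] to blank the flagged cells, which
#' moves the affected samples into the partially labeled set so the values
#' can be re-imputed.
#'
#' @param traits A long trait tibble.
#' @param factor Multiple of the per-trait median above which a measured
#'   value is anomalous (default 10).
#' @return A tibble of flags: `sample_id`, `trait`, `value`, `trait_median`.
#' @export
flag_trait_anomalies <- function(traits, factor = 10) {
  traits <- as_leaf_traits(traits)
  meas <- dplyr::filter(traits, .data$provenance == "measured")
  n_per_trait <- dplyr::count(meas, .data$trait)
  if (any(n_per_trait$n < 5)) {
    warn("fewer than 5 measured samples for some traits; medians may be unstable")
  }
  meas %>%
    dplyr::group_by(.data$trait) %>%
    dplyr::mutate(trait_median = stats::median(.data$value)) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$value > factor * .data$trait_median) %>%
    dplyr::select("sample_id", "trait", "value", "trait_median")
}

#' @rdname flag_trait_anomalies
#' @param flags The tibble returned by [flag_trait_anomalies()].
#' @return `apply_anomaly_filter()` returns the trait tibble with flagged
#'   cells set to missing.
#' @export
apply_anomaly_filter <- function(traits, flags) {
  traits <- as_leaf_traits(traits)
  if (nrow(flags) == 0L) return(traits)
  hit <- paste(traits$sample_id, traits$trait) %in%
    paste(flags$sample_id, flags$trait)
  traits$value[hit] <- NA_real_
  traits$provenance[hit] <- "missing"
  inform(sprintf("blanked %d anomalous cell(s) in %d sample(s)",
                 sum(hit), length(unique(flags$sample_id))))
  traits
}
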