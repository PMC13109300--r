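#' Synthetic grapevine leaf dataset configuration
#'
#' Defines the conditions of the emulated study: 12 date-by-variety
#' sub-datasets totalling 992 leaf samples collected over three seasons,
#' of which the three pre-2023 datasets (183 + 287 + 195 = 665 samples)
#' assayed only N, EWT and LMA while the nine 2023 datasets (327 samples)
#' assayed all 13 laboratory traits; pigment and structural traits come
#' from radiative-transfer inversion for every sample. Trait marginals
#' default to the aggregate summary statistics of the emulated study
#' (area-basis means, SDs and ranges); the three RTM-derived traits use
#' typical grapevine values. Inter-trait dependence is a Gaussian copula
#' whose rank-correlation targets reproduce the reported trait
#' relationships (e.g. Mg-Ca 0.69, LMA-Ca 0.68, K-Chl -0.31), with a mild
#' positive background correlation elsewhere and a nearest-PSD eigenvalue
#' repair.
#'
#' Spectra are built as a smooth vegetation-like baseline minus
#' trait-driven Gaussian absorption features (pigments in the visible,
#' water at 1200/1450/1940 nm, dry matter and protein in the shortwave
#' infrared, a broad 1000-1300 nm structural plateau), plus smooth
#' correlated noise and a little white noise, clipped to \[0.01, 0.99\] on
#' the 1-nm 400-2500 nm grid.
#'
#' @param n_per_dataset Integer vector of per-dataset sample counts.
#' @param trait_marginals Tibble `trait, mean, sd, min, max` (area basis).
#' @param correlation_targets Tibble `trait_a, trait_b, rho` of Spearman
#'   targets; unspecified pairs fall back to `background_rho`.
#' @param background_rho Default inter-trait rank correlation (0.2).
#' @param dataset_offset_sd SD of per-dataset mean offsets on the latent
#'   (z) scale, creating between-dataset heterogeneity (default 0.3).
#' @param measurement_cv Relative measurement noise on observed trait
#'   values.
#' @param signature_scale Global multiplier on the trait absorption depths
#'   (default 1). Parameter-recovery experiments use 2 -- the high
#'   signal-to-noise regime in which trait information dominates the
#'   structural variability.
#' @param structure_mode_sd Amplitude (reflectance units at the NIR
#'   plateau) of the broad leaf-structure mode that dominates sample-to-
#'   sample spectral variance, partially driven by the structural
#'   parameter. Real leaf sets concentrate most spectral variance in this
#'   first mode.
#' @param noise_sd Amplitude of the smooth spectral noise (reflectance
#'   units).
#' @param white_noise_sd Amplitude of per-band white noise.
#' @param rtm_bias_slope Multiplicative bias of the synthetic RTM
#'   chlorophyll estimates (default 1.33).
#' @param rtm_noise_cv Relative noise of the RTM estimates.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_dataset = c(183, 287, 195, 40, 40, 32,
                                               40, 32, 40, 32, 39, 32),
                             trait_marginals = default_trait_marginals(),
                             correlation_targets = default_correlation_targets(),
                             background_rho = 0.2,
                             dataset_offset_sd = 0.3,
                             measurement_cv = 0.05,
                             signature_scale = 1,
                             structure_mode_sd = 0.08,
                             noise_sd = 0.004,
                             white_noise_sd = 2e-4,
                             rtm_bias_slope = 1.33,
                             rtm_noise_cv = 0.08) {
  stopifnot(length(n_per_dataset) >= 1, all(n_per_dataset > 0))
  structure(
    list(n_per_dataset = as.integer(n_per_dataset),
         trait_marginals = trait_marginals,
         correlation_targets = correlation_targets,
         background_rho = background_rho,
         dataset_offset_sd = dataset_offset_sd,
         measurement_cv = measurement_cv,
         signature_scale = signature_scale,
         structure_mode_sd = structure_mode_sd,
         noise_sd = noise_sd, white_noise_sd = white_noise_sd,
         rtm_bias_slope = rtm_bias_slope, rtm_noise_cv = rtm_noise_cv),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_trait_marginals <- function() {
  tibble::tribble(
    ~trait,    ~mean,  ~sd,   ~min,   ~max,
    "N",        0.15,  0.03,  0.08,   0.32,
    "P",       13.50,  4.34,  2.35,  35.37,
    "K",       48.64, 12.76, 15.54,  92.00,
    "Ca",     115.12, 52.15, 21.46, 285.67,
    "Mg",      24.38,  9.02,  5.88,  47.30,
    "Zn",       0.11,  0.04,  0.02,   0.54,
    "Mn",       0.58,  0.28,  0.16,   1.46,
    "Fe",       0.62,  0.72,  0.13,   9.62,
    "Cu",       0.38,  0.44,  0.02,   1.96,
    "B",        0.24,  0.06,  0.07,   0.52,
    "Chl",     35.88,  8.59, 22.07,  73.23,
    "Car",      8.00,  2.00,  3.00,  16.00,
    "Ant",      1.50,  0.80,  0.20,   5.00,
    "EWT",     16.05,  1.58,  8.86,  27.74,
    "LMA",     61.47, 12.77, 35.09, 118.30,
    "Nstruct",  1.80,  0.35,  1.00,   3.00
  )
}

#' @rdname synthetic_config
#' @export
default_correlation_targets <- function() {
  tibble::tribble(
    ~trait_a, ~trait_b, ~rho,
    "Mg",  "Ca",   0.69,
    "LMA", "Ca",   0.68,
    "LMA", "Mg",   0.63,
    "LMA", "N",    0.59,
    "LMA", "P",    0.45,
    "N",   "K",   -0.19,
    "K",   "Chl", -0.31,
    "K",   "Car", -0.27,
    "K",   "Ant", -0.25,
    "K",   "Ca",   0.00,
    "P",   "Chl", -0.32,
    "P",   "Car", -0.30,
    "P",   "Ant", -0.42,
    "Chl", "Car",  0.70,
    "Chl", "Ant",  0.40,
    "Chl", "N",    0.45
  )
}

# target rank-correlation matrix -> PSD Pearson matrix for the copula
copula_correlation <- function(cfg) {
  tr <- leaf_trait_order()
  R <- matrix(cfg$background_rho, 16, 16, dimnames = list(tr, tr))
  # the structural parameter is largely independent of leaf chemistry
  R["Nstruct", ] <- 0.1
  R[, "Nstruct"] <- 0.1
  for (i in seq_len(nrow(cfg$correlation_targets))) {
    a <- cfg$correlation_targets$trait_a[i]
    b <- cfg$correlation_targets$trait_b[i]
    R[a, b] <- R[b, a] <- cfg$correlation_targets$rho[i]
  }
  diag(R) <- 1
  # Spearman target -> Pearson correlation of the latent normals
  P <- 2 * sin(pi * R / 6)
  diag(P) <- 1
  # nearest-PSD repair by eigenvalue clipping, then unit-diagonal rescale
  e <- eigen(P, symmetric = TRUE)
  if (any(e$values < 1e-8)) {
    P <- e$vectors %*% diag(pmax(e$values, 1e-8)) %*% t(e$vectors)
    d <- sqrt(diag(P))
    P <- P / tcrossprod(d)
  }
  if (any(eigen(P, symmetric = TRUE, only.values = TRUE)$values < 0)) {
    abort("correlation target matrix could not be repaired to PSD")
  }
  P
}

#' Generate a synthetic trait table
#'
#' Draws latent trait scores from a Gaussian copula with the configured
#' rank-correlation structure, adds per-dataset mean offsets (so that
#' within-dataset and pooled correlations differ, as in multi-season field
#' data), maps them through log-normal marginals matched to the configured
#' mean/SD, adds relative measurement noise, and truncates to the
#' configured min/max. All cells get provenance `"measured"`; use
#' [apply_missingness()] to impose the study's missing-label pattern.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return A long trait tibble with metadata columns `dataset_id`,
#'   `variety`, `stage`, plus attributes `latent` (n x 16 matrix of latent
#'   z-scores, used by [generate_spectra()]) and `samples` (sample
#'   metadata tibble).
#' @export
generate_traits <- function(cfg = synthetic_config(), seed = 1L) {
  set.seed(seed)
  n <- sum(cfg$n_per_dataset)
  tr <- leaf_trait_order()
  meta <- dataset_metadata(cfg)
  ds <- rep(meta$dataset_id, cfg$n_per_dataset)
  samples <- tibble::tibble(
    sample_id = sprintf("s%04d", seq_len(n)),
    dataset_id = ds,
    variety = rep(meta$variety, cfg$n_per_dataset),
    stage = rep(meta$stage, cfg$n_per_dataset)
  )
  P <- copula_correlation(cfg)
  Z <- MASS::mvrnorm(n, mu = rep(0, 16), Sigma = P)
  colnames(Z) <- tr
  # per-dataset offsets on the latent (z) scale; rescale so the pooled
  # marginal variance stays 1
  offs <- matrix(stats::rnorm(length(meta$dataset_id) * 16, 0,
                              cfg$dataset_offset_sd),
                 nrow = length(meta$dataset_id),
                 dimnames = list(meta$dataset_id, tr))
  # standardized post-offset latent: this is the latent that generates the
  # realized trait values, so the spectra are driven by it too (absorption
  # must track what is actually in the leaf, dataset shifts included)
  Zoff <- (Z + offs[ds, ]) / sqrt(1 + cfg$dataset_offset_sd^2)
  # log-normal marginals matched to (mean, sd)
  m <- cfg$trait_marginals[match(tr, cfg$trait_marginals$trait), ]
  sdlog <- sqrt(log(1 + (m$sd / m$mean)^2))
  meanlog <- log(m$mean) - sdlog^2 / 2
  V <- exp(sweep(sweep(Zoff, 2L, sdlog, `*`), 2L, meanlog, `+`))
  V <- V * (1 + matrix(stats::rnorm(n * 16, 0, cfg$measurement_cv), n, 16))
  V <- pmin(pmax(V, rep(m$min, each = n)), rep(m$max, each = n))
  traits <- samples %>%
    dplyr::cross_join(tibble::tibble(trait = tr)) %>%
    dplyr::mutate(value = as.vector(t(V)), provenance = "measured")
  traits <- as_leaf_traits(traits)
  attr(traits, "latent") <- structure(Zoff,
                                      dimnames = list(samples$sample_id, tr))
  attr(traits, "samples") <- samples
  traits
}

dataset_metadata <- function(cfg) {
  k <- length(cfg$n_per_dataset)
  full <- tibble::tibble(
    dataset_id = sprintf("D%02d", seq_len(k)),
    variety = rep(c("FlameSeedless", "FlameSeedless", "Solbrio", "Solbrio",
                    "Solbrio", "Sunpreme", "Solbrio", "Sunpreme", "Solbrio",
                    "Sunpreme", "Solbrio", "Sunpreme"), length.out = k),
    stage = rep(c("veraison", "unknown", "veraison", "prebloom", "bloom",
                  "bloom", "berry_set", "berry_set", "veraison", "veraison",
                  "harvest", "harvest"), length.out = k)
  )
  full
}

# smooth vegetation-like reflectance baseline on an arbitrary grid
vegetation_baseline <- function(grid) {
  knots <- c(400, 450, 500, 550, 600, 650, 680, 710, 740, 780, 900, 1100,
             1300, 1400, 1450, 1550, 1650, 1800, 1900, 1940, 2050, 2150,
             2250, 2350, 2450, 2500)
  refl <- c(0.05, 0.045, 0.06, 0.12, 0.09, 0.06, 0.05, 0.12, 0.30, 0.44,
            0.47, 0.46, 0.44, 0.36, 0.28, 0.35, 0.37, 0.33, 0.25, 0.17,
            0.24, 0.26, 0.23, 0.18, 0.13, 0.11)
  stats::spline(knots, refl, xout = grid, method = "natural")$y
}

# trait -> Gaussian absorption features (centre nm, width nm, depth per SD)
trait_signatures <- function() {
  tibble::tribble(
    ~trait,    ~centre, ~width, ~depth,
    "Chl",      450,  30, 0.015,
    "Chl",      550,  40, 0.030,
    "Chl",      680,  25, 0.018,
    "Car",      450,  25, 0.012,
    "Car",      500,  30, 0.012,
    "Ant",      570,  30, 0.014,
    "EWT",     1200,  60, 0.015,
    "EWT",     1450,  80, 0.030,
    "EWT",     1940,  90, 0.030,
    "LMA",     1700,  60, 0.015,
    "LMA",     2200,  80, 0.018,
    "LMA",     2300,  60, 0.012,
    "N",       1510,  40, 0.012,
    "N",       2180,  50, 0.012,
    "Nstruct", 1150, 150, 0.025,
    "P",       2150,  40, 0.010,
    "K",       1730,  40, 0.010,
    "Ca",      2210,  50, 0.009,
    "Ca",      1700,  40, 0.006,
    "Mg",      2100,  40, 0.009,
    "Mg",      1690,  40, 0.005,
    "Zn",      2060,  40, 0.009,
    "Mn",      1870,  40, 0.009,
    "Fe",       870,  50, 0.009,
    "Cu",      2350,  40, 0.009,
    "B",       1380,  40, 0.008
  )
}

#' Generate synthetic leaf spectra from a trait table
#'
#' Builds one reflectance spectrum per sample: the vegetation baseline
#' minus each trait's Gaussian absorption features scaled by the sample's
#' latent trait z-score, plus smooth correlated noise (a random natural
#' spline) and white noise, clipped to \[0.01, 0.99\]. Doubling a pigment
#' thus deepens its absorption feature in expectation, mirroring how real
#' absorption features respond to concentration.
#'
#' @param traits The tibble from [generate_traits()] (its `latent`
#'   attribute drives the spectra).
#' @param cfg The same [synthetic_config()].
#' @param seed Integer seed.
#' @param grid Wavelength grid in nm (default the 1-nm 400-2500 grid).
#' @return A spectra tibble (2101 wavelength columns by default).
#' @export
generate_spectra <- function(traits, cfg = synthetic_config(), seed = 1L,
                             grid = seq(400, 2500, by = 1)) {
  Z <- attr(traits, "latent")
  samples <- attr(traits, "samples")
  if (is.null(Z) || is.null(samples)) {
    abort("traits must come from generate_traits() (latent attribute missing)")
  }
  set.seed(seed + 1L)
  n <- nrow(Z)
  base <- vegetation_baseline(grid)
  sig <- trait_signatures()
  # feature matrix: one Gaussian per signature row, columns = wavelengths
  G <- t(vapply(seq_len(nrow(sig)), function(i) {
    cfg$signature_scale * sig$depth[i] *
      exp(-0.5 * ((grid - sig$centre[i]) / sig$width[i])^2)
  }, numeric(length(grid))))
  effects <- Z[, sig$trait, drop = FALSE] %*% G
  # broad structural/albedo mode: the dominant axis of leaf-to-leaf
  # spectral variability, shaped like the baseline (strongest in the NIR)
  # and partly driven by the structural parameter
  mode_shape <- base / max(base)
  s <- 0.5 * Z[, "Nstruct"] + sqrt(1 - 0.5^2) * stats::rnorm(n)
  structure_mode <- (cfg$structure_mode_sd * s) %o% mode_shape
  # smooth correlated noise: natural spline through random knot values
  knots <- seq(min(grid), max(grid), length.out = 18)
  noise <- t(vapply(seq_len(n), function(i) {
    stats::spline(knots, stats::rnorm(length(knots), 0, cfg$noise_sd),
                  xout = grid, method = "natural")$y
  }, numeric(length(grid))))
  refl <- matrix(base, n, length(grid), byrow = TRUE) + structure_mode -
    effects + noise +
    matrix(stats::rnorm(n * length(grid), 0, cfg$white_noise_sd), n)
  refl <- pmin(pmax(refl, 0.01), 0.99)
  spectra_from_matrix(samples, grid, refl)
}

#' Impose the study's missing-label pattern
#'
#' The three pre-2023 datasets retain only N, EWT and LMA (the other ten
#' laboratory traits, including chlorophyll, become missing); the nine 2023
#' datasets retain all 13 laboratory traits. The three RTM-derived traits
#' (Car, Ant, Nstruct) are set to missing for every sample until
#' [rtm_fill_traits()] supplies them. With the default dataset sizes this
#' yields 327 fully labeled and 665 partially labeled samples.
#'
#' @param traits The tibble from [generate_traits()].
#' @param partial_datasets Dataset ids forming the partially labeled
#'   group; defaults to the first three.
#' @return The trait tibble with the pattern applied (attributes kept).
#' @export
apply_missingness <- function(traits, partial_datasets = c("D01", "D02", "D03")) {
  keep_latent <- attr(traits, "latent")
  keep_samples <- attr(traits, "samples")
  partial_gone <- setdiff(measured_trait_names(), c("N", "EWT", "LMA"))
  drop <- (traits$dataset_id %in% partial_datasets &
             traits$trait %in% partial_gone) |
    traits$trait %in% rtm_trait_names()
  traits$value[drop] <- NA_real_
  traits$provenance[drop] <- "missing"
  attr(traits, "latent") <- keep_latent
  attr(traits, "samples") <- keep_samples
  traits
}

#' Generate synthetic radiative-transfer trait estimates
#'
#' Emulates inversion outputs: chlorophyll estimates carry a multiplicative
#' bias (`rtm_bias_slope`, default 1.33, so bias calibration should recover
#' a scale factor near 0.75) plus relative noise; carotenoids, anthocyanins
#' and the structural parameter are unbiased noisy copies of the latent
#' truth; protein is 4.43 x latent N (the protein-to-nitrogen factor) and
#' CBC is latent LMA minus protein (floored at zero), both in mg/cm^2.
#'
#' @param traits The tibble from [generate_traits()] (pre-missingness
#'   truth values are used).
#' @param cfg The same [synthetic_config()].
#' @param seed Integer seed.
#' @return A tibble: `sample_id`, `chl`, `car`, `ant`, `nstruct`,
#'   `protein`, `cbc`.
#' @export
generate_rtm_estimates <- function(traits, cfg = synthetic_config(),
                                   seed = 1L) {
  truth <- trait_matrix(traits, c("Chl", "Car", "Ant", "Nstruct", "N", "LMA"))
  if (anyNA(truth)) {
    abort("generate_rtm_estimates needs the complete (pre-missingness) table")
  }
  set.seed(seed + 2L)
  n <- nrow(truth)
  noisy <- function(x, slope = 1) {
    unname(pmax(slope * x * (1 + stats::rnorm(n, 0, cfg$rtm_noise_cv)), 0))
  }
  protein <- noisy(4.43 * truth[, "N"])          # mg/cm2
  lma_mg_cm2 <- truth[, "LMA"] * 0.1             # g/m2 -> mg/cm2
  tibble::tibble(
    sample_id = rownames(truth),
    chl = noisy(truth[, "Chl"], cfg$rtm_bias_slope),
    car = noisy(truth[, "Car"]),
    ant = noisy(truth[, "Ant"]),
    nstruct = noisy(truth[, "Nstruct"]),
    protein = protein,
    cbc = pmax(lma_mg_cm2 - protein, 0)
  )
}

#' Simulate a complete synthetic study
#'
#' One-call generator running [generate_traits()], [apply_missingness()],
#' [generate_spectra()] and [generate_rtm_estimates()] with a shared seed.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list: `spectra`, `traits` (with missingness),
#'   `traits_complete` (pre-missingness truth), `rtm`, `samples`.
#' @export
simulate_leaf_dataset <- function(cfg = synthetic_config(), seed = 1L) {
  traits_full <- generate_traits(cfg, seed)
  spectra <- generate_spectra(traits_full, cfg, seed)
  rtm <- generate_rtm_estimates(traits_full, cfg, seed)
  traits <- apply_missingness(traits_full)
  list(spectra = spectra, traits = traits, traits_complete = traits_full,
       rtm = rtm, samples = attr(traits_full, "samples"))
}
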