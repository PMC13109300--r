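test_that("generator is seed-deterministic and respects marginals", {
  cfg <- synthetic_config(n_per_dataset = rep(20, 12))
  a <- generate_traits(cfg, seed = 5)
  b <- generate_traits(cfg, seed = 5)
  expect_identical(a$value, b$value)
  m <- default_trait_marginals()
  v <- trait_matrix(a)
  for (j in seq_len(ncol(v))) {
    expect_true(all(v[, j] >= m$min[j] & v[, j] <= m$max[j]))
  }
})

test_that("realized marginals and rank correlations track the targets", {
  cfg <- synthetic_config(n_per_dataset = rep(500, 10))
  tr <- generate_traits(cfg, seed = 5)
  v <- trait_matrix(tr)
  m <- default_trait_marginals()
  for (t in c("Chl", "LMA", "Ca")) {
    j <- match(t, colnames(v))
    expect_lt(abs(mean(v[, j]) - m$mean[m$trait == t]) /
                m$mean[m$trait == t], 0.1)
  }
  # the flagship correlation target, measured the way the pipeline measures
  # it: within-dataset Spearman averaged over datasets (pooled correlations
  # are diluted by the between-dataset offsets, as in real multi-season data)
  corr <- suppressMessages(averaged_spearman(tr))
  mgca <- corr$rho[corr$trait_a == "Ca" & corr$trait_b == "Mg"]
  expect_lt(abs(mgca - 0.69), 0.05)
  kchl <- corr$rho[(corr$trait_a == "K" & corr$trait_b == "Chl") |
                     (corr$trait_a == "Chl" & corr$trait_b == "K")]
  expect_lt(kchl, 0)
})

test_that("spectra respond to traits the way absorption features should", {
  sim <- small_sim()
  expect_equal(length(spectra_wavelengths(sim$spectra)), 2101)
  vals <- spectra_values(sim$spectra)
  expect_true(all(vals >= 0.01 & vals <= 0.99))
  # higher chlorophyll -> deeper 550 nm absorption, in expectation
  z <- attr(sim$traits_complete, "latent")[, "Chl"]
  hi <- vals[z > quantile(z, 0.8), "550"]
  lo <- vals[z < quantile(z, 0.2), "550"]
  expect_lt(mean(hi), mean(lo))
  # water feature responds to EWT
  zw <- attr(sim$traits_complete, "latent")[, "EWT"]
  expect_lt(mean(vals[zw > quantile(zw, 0.8), "1450"]),
            mean(vals[zw < quantile(zw, 0.2), "1450"]))
  # zero signature depth -> spectra independent of traits
  cfg0 <- synthetic_config(n_per_dataset = rep(6, 12))
  tr0 <- generate_traits(cfg0, seed = 2)
  sp0 <- generate_spectra(tr0, cfg0, seed = 2)
  expect_equal(nrow(sp0), nrow(attr(tr0, "samples")))
})

test_that("missingness pattern reproduces the 327/665 study split", {
  sim <- simulate_leaf_dataset(synthetic_config(), seed = 99)
  part <- suppressMessages(assemble_partition(sim$traits))
  expect_equal(sum(part$labeled == "fully"), 327)
  expect_equal(sum(part$labeled == "partially"), 665)
  expect_equal(nrow(part), 992)
  # partial samples miss exactly the 9 nutrients + Chl among lab traits
  partial <- dplyr::filter(sim$traits, .data$dataset_id %in%
                             c("D01", "D02", "D03"))
  gone <- sort(unique(partial$trait[partial$provenance == "missing"]))
  expect_setequal(gone, c("P", "K", "Ca", "Mg", "Zn", "Mn", "Fe", "Cu", "B",
                          "Chl", "Car", "Ant", "Nstruct"))
  kept <- unique(partial$trait[partial$provenance == "measured"])
  expect_setequal(kept, c("N", "EWT", "LMA"))
})

test_that("synthetic RTM estimates carry the configured bias and k_p", {
  cfg <- synthetic_config(n_per_dataset = rep(10, 12), rtm_noise_cv = 0)
  tr <- generate_traits(cfg, seed = 3)
  rtm <- generate_rtm_estimates(tr, cfg, seed = 3)
  truth <- trait_matrix(tr, c("Chl", "N"))
  # noise-free: chl estimate = 1.33 x truth, calibration recovers 0.75
  expect_equal(rtm$chl, unname(1.33 * truth[, "Chl"]), ignore_attr = TRUE)
  cal <- fit_scale_factor(truth[, "Chl"], rtm$chl)
  expect_equal(cal$scale_factor, 1 / 1.33, tolerance = 1e-10)
  expect_equal(round(cal$scale_factor, 2), 0.75)
  # protein / N = k_p exactly at zero noise
  expect_equal(rtm$protein / truth[, "N"], rep(4.43, nrow(truth)),
               ignore_attr = TRUE)
  # slope 1, zero noise -> identity on pigments
  cfg1 <- synthetic_config(n_per_dataset = rep(10, 12), rtm_noise_cv = 0,
                           rtm_bias_slope = 1)
  rtm1 <- generate_rtm_estimates(tr, cfg1, seed = 3)
  expect_equal(rtm1$chl, unname(truth[, "Chl"]))
})
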