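test_that("read_spectra ingests wide CSVs, keeps native grids, clips", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  df <- data.frame(sample_id = c("a", "b"),
                   `410.3` = c(0.1, 0.2), `411.9` = c(0.3, 1.07),
                   check.names = FALSE)
  write.csv(df, f, row.names = FALSE)
  expect_warning(sp <- read_spectra(f), "clipped 1")
  expect_equal(spectra_wavelengths(sp), c(410.3, 411.9))
  expect_equal(unname(spectra_values(sp)["b", "411.9"]), 1.0)

  # regular grid identity ingestion
  grid <- 400:2500
  df2 <- cbind(data.frame(sample_id = c("a", "b")),
               matrix(0.5, 2, length(grid), dimnames = list(NULL, grid)))
  write.csv(df2, f, row.names = FALSE)
  sp2 <- read_spectra(f)
  expect_equal(length(spectra_wavelengths(sp2)), 2101)
  expect_equal(nrow(sp2), 2)

  # bad headers are a format error
  df3 <- data.frame(sample_id = "a", notawavelength = 0.5)
  write.csv(df3, f, row.names = FALSE)
  expect_error(read_spectra(f), "not wavelengths")
})

test_that("LMA/EWT derivation matches hand arithmetic and conserves mass", {
  d <- tibble::tibble(sample_id = c("a", "b", "c"),
                      fresh = c(1, 1.5, 2.0),
                      dry = c(1, 0.5, 0.8),
                      area = c(1, 100, 150))
  out <- compute_lma_ewt(d, fresh, dry, area)
  expect_equal(out$EWT[1], 0)                 # no water
  expect_equal(out$LMA[2], 50)                # 0.5 g / 100 cm2 = 50 g/m2
  expect_equal(out$EWT[2], 10)                # 1 g water / 100 cm2 = 10 mg/cm2
  # conservation: fresh = dry + EWT * area (units: g, mg/cm2 * cm2 / 1000)
  expect_equal(out$dry + out$EWT * out$area / 1e3, out$fresh)
  expect_error(compute_lma_ewt(tibble::tibble(f = 1, d = 2, a = 1), f, d, a),
               "dry_weight")
  expect_error(compute_lma_ewt(tibble::tibble(f = 1, d = 1, a = 0), f, d, a),
               "area")
})

test_that("mass/area conversion is the LMA product and inverts", {
  expect_equal(convert_mass_to_area(0, 50), 0)
  expect_equal(convert_mass_to_area(0.02, 50), 1)  # 2% N at 50 g/m2
  x <- runif(20, 0.001, 0.05)
  lma <- runif(20, 30, 120)
  expect_equal(convert_area_to_mass(convert_mass_to_area(x, lma), lma), x)
  expect_error(convert_mass_to_area(1, 0), "lma")
})

test_that("partition is exhaustive, disjoint, and driven by measured traits", {
  lab_traits <- c("N", "P", "K", "Ca", "Mg", "Zn", "Mn", "Fe", "Cu", "B",
                  "Chl", "EWT", "LMA")
  m <- matrix(runif(4 * 13, 1, 2), 4, dimnames = list(NULL, lab_traits))
  tr <- toy_traits(m)
  part <- suppressMessages(assemble_partition(tr))
  expect_setequal(part$labeled, "fully")

  tr2 <- tr
  tr2$value[tr2$sample_id == "t02" & tr2$trait == "Zn"] <- NA
  tr2$provenance[tr2$sample_id == "t02" & tr2$trait == "Zn"] <- "missing"
  part2 <- suppressMessages(assemble_partition(tr2))
  expect_equal(part2$labeled[part2$sample_id == "t02"], "partially")
  expect_equal(sum(part2$labeled == "fully"), 3)
  # exhaustive and disjoint by construction
  expect_setequal(part2$sample_id, unique(tr2$sample_id))
  expect_equal(anyDuplicated(part2$sample_id), 0L)
  expect_error(suppressMessages(assemble_partition(tr[0, ])), "empty")
})

test_that("anomaly flagging finds >10x cells, moves samples, is idempotent", {
  set.seed(1)
  m <- cbind(Fe = c(rep(0.6, 9), 6.3), Zn = rep(0.1, 10))
  tr <- toy_traits(m)
  flags <- flag_trait_anomalies(tr, factor = 10)
  expect_equal(nrow(flags), 1)
  expect_equal(flags$trait, "Fe")
  expect_equal(flags$sample_id, "t10")

  cleaned <- suppressMessages(apply_anomaly_filter(tr, flags))
  hit <- cleaned$sample_id == "t10" & cleaned$trait == "Fe"
  expect_true(is.na(cleaned$value[hit]))
  expect_equal(cleaned$provenance[hit], "missing")
  # second pass on the cleaned table finds nothing (idempotence)
  expect_equal(nrow(flag_trait_anomalies(cleaned, factor = 10)), 0)

  # two anomalous traits in one sample -> 2 flags, 1 sample
  m2 <- cbind(Fe = c(rep(0.6, 9), 6.3), Zn = c(rep(0.1, 9), 1.2))
  fl2 <- flag_trait_anomalies(toy_traits(m2), factor = 10)
  expect_equal(nrow(fl2), 2)
  expect_equal(length(unique(fl2$sample_id)), 1)
  # homogeneous table -> no flags
  expect_equal(nrow(flag_trait_anomalies(toy_traits(
    cbind(Fe = rep(0.6, 10))), 10)), 0)
})
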