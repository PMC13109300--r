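# Shared fixtures, built in code.

# tiny spectra tibble on an arbitrary grid
toy_spectra <- function(values, wavelengths, ids = NULL) {
  values <- as.matrix(values)
  ids <- ids %||% sprintf("t%02d", seq_len(nrow(values)))
  out <- tibble::tibble(sample_id = ids)
  vals <- tibble::as_tibble(as.data.frame(values), .name_repair = "minimal")
  names(vals) <- as.character(wavelengths)
  dplyr::bind_cols(out, vals)
}

# long trait table from a named matrix (rows = samples)
toy_traits <- function(m, dataset_id = NULL) {
  df <- tibble::as_tibble(m)
  df$sample_id <- rownames(m) %||% sprintf("t%02d", seq_len(nrow(m)))
  if (!is.null(dataset_id)) df$dataset_id <- dataset_id
  meta <- intersect(names(df), c("sample_id", "dataset_id"))
  long <- tidyr::pivot_longer(df, -dplyr::all_of(meta),
                              names_to = "trait", values_to = "value")
  as_leaf_traits(long)
}

# small synthetic study reused across tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        n_per_dataset = c(30, 30, 30, 12, 12, 12, 12, 12, 12, 12, 12, 12),
        signature_scale = 2
      )
      cache <<- simulate_leaf_dataset(cfg, seed = 421)
    }
    cache
  }
})

# coarse-grid variant of the generator for fast model tests
small_grid <- function() seq(400, 2500, by = 10)

`%||%` <- function(a, b) if (is.null(a)) b else a
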