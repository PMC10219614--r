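# Shared fixtures: small, fast generator configurations.

config_with <- function(defaults, overrides) {
  do.call(generator_config, utils::modifyList(defaults, overrides))
}

# Deterministic band-model-only config: no noise, baseline, spikes, gain
# or biological variation.
clean_config <- function(...) {
  config_with(
    list(
      noise_sd = 0, spike_probability = 0, gain_sd = 0,
      baseline_amplitude = 0, between_sample_sd = 0,
      replicates_per_sample = 1, n_cancer = 2, n_control = 2, seed = 1
    ),
    list(...)
  )
}

# Small default-structure cohort config (paper-direction effects).
small_config <- function(...) {
  config_with(list(replicates_per_sample = 3, seed = 1), list(...))
}

# Exchangeable-groups config: identical band amplitudes in both groups.
null_config <- function(...) {
  config_with(
    list(
      peaks = dplyr::mutate(default_peak_table(), cancer_multiplier = 1),
      replicates_per_sample = 3, seed = 1
    ),
    list(...)
  )
}

# Closed-form noiseless band model on a wavenumber grid: the sum of
# Lorentzians the generator is built from, written independently here.
band_model <- function(wavenumbers, peaks, group = "control") {
  mult <- if (group == "cancer") peaks$cancer_multiplier else rep(1, nrow(peaks))
  y <- numeric(length(wavenumbers))
  for (b in seq_len(nrow(peaks))) {
    gam <- peaks$fwhm[b] / 2
    y <- y + peaks$base_amplitude[b] * mult[b] *
      gam^2 / ((wavenumbers - peaks$center[b])^2 + gam^2)
  }
  y
}

# Wide spectral-matrix tibble from a bare matrix + labels, for tests that
# construct data directly.
as_spectral_matrix <- function(X, labels, wavenumbers = seq(350, by = 2, length.out = ncol(X))) {
  colnames(X) <- as.character(wavenumbers)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%02d", seq_len(nrow(X))), group = labels),
    tibble::as_tibble(X)
  )
}
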