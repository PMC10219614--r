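#' Default vibrational-band table for the synthetic generator
#'
#' Twenty bands typical of saliva-derived exosome SERS spectra on silver
#' substrates, spanning thiocyanate, saccharide, protein, lipid and
#' nucleic-acid modes. Every band is elevated in the cancer group
#' (`cancer_multiplier > 1`) except the two thiocyanate bands at 443 and
#' 2110 cm^-1, which are elevated in controls; the dominant 2110 cm^-1
#' -C≡N stretch has `cancer_multiplier = 0.5`, i.e. a control-group mean
#' intensity about twice the cancer-group mean. `base_amplitude` is the
#' control-group peak height; the cancer-group height is
#' `base_amplitude * cancer_multiplier`.
#'
#' @return A tibble with columns `center` (cm^-1), `fwhm` (cm^-1),
#'   `base_amplitude` (a.u.), `cancer_multiplier`, `assignment`.
#' @examples
#' default_peak_table()
#' @export
default_peak_table <- function() {
  tibble::tribble(
    ~center, ~base_amplitude, ~cancer_multiplier, ~assignment,
    443,  2.0, 0.7,  "Thiocyanate",
    460,  1.0, 1.25, "Saccharides",
    498,  1.0, 1.25, "Polysaccharide, Glycogen",
    533,  1.0, 1.25, "Lysozyme",
    593,  1.0, 1.25, "Saccharides",
    638,  1.5, 1.3,  "C-C twisting of Tyrosine",
    729,  1.2, 1.3,  "Tryptophan, coenzyme A, nucleic acids",
    890,  1.5, 1.4,  "Proteins",
    930,  1.5, 1.4,  "Proteins, C-C stretch amino acids (proline, hydroxyproline, and valine)",
    968,  1.2, 1.3,  "Proteins, Monoester Phosphate group",
    1002, 2.5, 1.3,  "C-C symmetric stretch of Phenylalanine, symmetric ring breathing mode (tryptophan)",
    1049, 1.2, 1.3,  "C–N, C-C stretching of Protein and Lipids",
    1100, 1.5, 1.4,  "Nucleic acids",
    1323, 1.3, 1.4,  "CH2-CH2 of Nucleic Acids",
    1449, 1.8, 1.3,  "CH2 symmetric bending of collagen, CH2 bending mode of lipids and proteins, CH2, CH3 deformation",
    1577, 1.3, 1.4,  "Nucleic acids (guanine), Amide II",
    1598, 1.5, 1.3,  "Phenylalanine",
    1655, 1.6, 1.3,  "Nucleic acids, Amide I",
    1686, 1.4, 1.4,  "Amide I",
    2110, 10.0, 0.5, "-C≡N Thiocyanate"
  ) |>
    dplyr::mutate(fwhm = 12, .after = "center")
}

#' Synthetic SERS cohort generator configuration
#'
#' Bundles every knob of the two-group cohort simulator. The defaults
#' emulate the acquisition design the pipeline targets: 29 cancer and 22
#' control subjects, 100 replicate acquisitions per sample on a 350-2350
#' cm^-1 window, Lorentzian band profiles from [default_peak_table()], a
#' broad fluorescence background, additive detector noise, occasional
#' cosmic-ray spikes and a log-normal per-replicate gain.
#'
#' @param grid [uniform_grid()] on which replicates are simulated.
#' @param peaks Band table (see [default_peak_table()]).
#' @param n_cancer,n_control Group sizes.
#' @param replicates_per_sample Acquisitions per subject; reduce for fast
#'   simulation studies.
#' @param baseline_amplitude Scale of the fluorescence background (a.u.);
#'   0 disables it.
#' @param noise_sd Additive Gaussian detector noise sd (a.u.).
#' @param spike_probability Per-replicate probability of one cosmic-ray
#'   spike.
#' @param spike_amplitude Spike height (a.u.); spikes are 1-3 grid points
#'   wide.
#' @param gain_sd sdlog of the log-normal per-replicate multiplicative
#'   gain (0 disables gain variation).
#' @param between_sample_sd sdlog of the log-normal per-sample, per-band
#'   random effect (biological variability).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A `generator_config` list.
#' @export
generator_config <- function(grid = uniform_grid(),
                             peaks = default_peak_table(),
                             n_cancer = 29,
                             n_control = 22,
                             replicates_per_sample = 100,
                             baseline_amplitude = 5,
                             noise_sd = 0.1,
                             spike_probability = 0.05,
                             spike_amplitude = 30,
                             gain_sd = 0.2,
                             between_sample_sd = 0.15,
                             seed = 1L) {
  stopifnot(
    inherits(grid, "uniform_grid"),
    is.data.frame(peaks),
    all(c("center", "fwhm", "base_amplitude", "cancer_multiplier") %in% names(peaks)),
    all(peaks$fwhm > 0), all(peaks$base_amplitude >= 0),
    all(peaks$cancer_multiplier > 0),
    n_cancer >= 1, n_control >= 1, replicates_per_sample >= 1,
    spike_probability >= 0, spike_probability <= 1,
    noise_sd >= 0, baseline_amplitude >= 0, gain_sd >= 0, between_sample_sd >= 0
  )
  structure(
    list(
      grid = grid, peaks = peaks,
      n_cancer = as.integer(n_cancer), n_control = as.integer(n_control),
      replicates_per_sample = as.integer(replicates_per_sample),
      baseline_amplitude = baseline_amplitude, noise_sd = noise_sd,
      spike_probability = spike_probability, spike_amplitude = spike_amplitude,
      gain_sd = gain_sd, between_sample_sd = between_sample_sd,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Lorentzian profile matrix: grid points x bands, unit peak height.
lorentzian_profiles <- function(wavenumbers, peaks) {
  gam <- peaks$fwhm / 2
  vapply(
    seq_len(nrow(peaks)),
    function(b) gam[b]^2 / ((wavenumbers - peaks$center[b])^2 + gam[b]^2),
    numeric(length(wavenumbers))
  )
}

# Broad fluorescence background: decaying exponential + gentle quadratic,
# unit-scale; multiplied by baseline_amplitude.
baseline_profile <- function(wavenumbers) {
  t <- (wavenumbers - wavenumbers[1]) / diff(range(wavenumbers))
  1.2 * exp(-3 * t) + 0.8 - 0.4 * t + 0.15 * t^2
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate one replicate acquisition
#'
#' One synthetic SERS acquisition: the band model times a per-sample
#' effect, plus fluorescence background, all scaled by a log-normal
#' replicate gain, plus Gaussian detector noise and (with probability
#' `spike_probability`) one 1-3-point cosmic-ray spike. Consumes the
#' current R random number stream; seed it (or use [simulate_cohort()])
#' for reproducibility.
#'
#' @param config [generator_config()].
#' @param group `"cancer"` or `"control"`.
#' @param sample_effect Per-band multipliers (length `nrow(config$peaks)`);
#'   defaults to 1s.
#' @return A spectrum tibble (`wavenumber`, `intensity`).
#' @export
simulate_replicate <- function(config, group = c("control", "cancer"),
                               sample_effect = rep(1, nrow(config$peaks))) {
  group <- match.arg(group)
  stopifnot(length(sample_effect) == nrow(config$peaks))
  w <- config$grid$wavenumbers
  L <- lorentzian_profiles(w, config$peaks)
  amps <- config$peaks$base_amplitude *
    (if (group == "cancer") config$peaks$cancer_multiplier else 1) *
    sample_effect
  clean <- drop(L %*% amps) + config$baseline_amplitude * baseline_profile(w)
  gain <- if (config$gain_sd > 0) rlnorm(1, 0, config$gain_sd) else 1
  y <- gain * clean + if (config$noise_sd > 0) rnorm(length(w), 0, config$noise_sd) else 0
  if (config$spike_probability > 0 && runif(1) < config$spike_probability) {
    width <- sample(1:3, 1)
    pos <- sample(length(w) - width + 1L, 1)
    y[pos:(pos + width - 1L)] <- y[pos:(pos + width - 1L)] + config$spike_amplitude
  }
  tibble::tibble(wavenumber = w, intensity = y)
}

#' Simulate a labelled two-group cohort
#'
#' Draws `n_cancer + n_control` subjects, each with a log-normal
#' per-band random effect (sdlog `between_sample_sd`) and
#' `replicates_per_sample` replicate acquisitions from
#' [simulate_replicate()]. Deterministic given `config$seed`: identical
#' configs produce bit-identical cohorts, and the caller's RNG state is
#' left untouched.
#'
#' @param config [generator_config()].
#' @return A long tibble with columns `sample_id`, `group`, `replicate`,
#'   `wavenumber`, `intensity`.
#' @examples
#' cohort <- simulate_cohort(generator_config(
#'   n_cancer = 2, n_control = 2, replicates_per_sample = 2,
#'   seed = 7
#' ))
#' dplyr::count(cohort, sample_id, group)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    groups <- rep(c("cancer", "control"), c(config$n_cancer, config$n_control))
    ids <- sprintf(
      "%s_%02d", ifelse(groups == "cancer", "ca", "ct"),
      c(seq_len(config$n_cancer), seq_len(config$n_control))
    )
    n_bands <- nrow(config$peaks)
    purrr::map2(ids, groups, function(sid, grp) {
      eff <- if (config$between_sample_sd > 0) {
        rlnorm(n_bands, 0, config$between_sample_sd)
      } else rep(1, n_bands)
      purrr::map(seq_len(config$replicates_per_sample), function(r) {
        sp <- simulate_replicate(config, grp, eff)
        sp$sample_id <- sid
        sp$group <- grp
        sp$replicate <- r
        sp
      }) |> purrr::list_rbind()
    }) |>
      purrr::list_rbind() |>
      dplyr::select("sample_id", "group", "replicate", "wavenumber", "intensity")
  })
}
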