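#' Preprocessing configuration
#'
#' Parameters of the per-replicate preprocessing chain: cosmic-ray
#' despiking (modified z-score of first differences), asymmetric least
#' squares (AsLS) fluorescence-background removal, and the uniform
#' resampling grid.
#'
#' @param despike_z_threshold Modified z-score threshold above which a
#'   point is treated as a cosmic-ray spike. Default 8; `Inf` disables
#'   despiking (useful for noise-free simulated input, where any
#'   self-scaled spike detector degenerates).
#' @param baseline_lambda AsLS smoothness penalty (lambda). Default 1e5.
#' @param baseline_asymmetry AsLS asymmetry (p), in (0, 1). Default 0.01.
#' @param baseline_iterations Fixed AsLS reweighting iteration count.
#' @param baseline Apply the baseline stage at all? `FALSE` skips it
#'   (for data known to carry no background, where the small positive
#'   baseline AsLS infers under real bands is pure distortion).
#' @param grid Target [uniform_grid()] for resampling.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(despike_z_threshold = 8,
                              baseline_lambda = 1e5,
                              baseline_asymmetry = 0.01,
                              baseline_iterations = 10,
                              baseline = TRUE,
                              grid = uniform_grid()) {
  stopifnot(
    despike_z_threshold > 0,
    baseline_lambda > 0,
    baseline_asymmetry > 0, baseline_asymmetry < 1,
    baseline_iterations >= 1,
    is.logical(baseline),
    inherits(grid, "uniform_grid")
  )
  structure(
    list(
      despike_z_threshold = despike_z_threshold,
      baseline_lambda = baseline_lambda,
      baseline_asymmetry = baseline_asymmetry,
      baseline_iterations = as.integer(baseline_iterations),
      baseline = baseline,
      grid = grid
    ),
    class = "preprocess_config"
  )
}

# Modified z-score despiking on a bare intensity vector.
despike_vector <- function(y, z_threshold) {
  d <- diff(y)
  scale <- mad(d, constant = 1)
  if (scale == 0) return(y) # constant/linear trace: nothing to flag
  z <- 0.6745 * (d - median(d)) / scale
  flagged <- c(FALSE, abs(z) > z_threshold)
  if (!any(flagged)) return(y)
  idx <- which(flagged)
  n <- length(y)
  for (i in idx) {
    half <- 2L
    repeat {
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      nb <- setdiff(lo:hi, which(flagged))
      if (length(nb) > 0) {
        y[i] <- median(y[nb])
        break
      }
      half <- half + 1L
      if (half > n) break # all points flagged; leave as is
    }
  }
  y
}

#' Remove cosmic-ray spikes
#'
#' Whitaker-Hayes-style despiking: points whose modified z-score of
#' first-differenced intensities exceeds `z_threshold` are replaced by the
#' median of the nearest unflagged neighbours within a 5-point window
#' (widened only if the whole window is flagged). Spike-free spectra are
#' returned unchanged; a constant spectrum is a no-op.
#'
#' @param spectrum Spectrum tibble (`wavenumber`, `intensity`), length >= 5.
#' @param z_threshold Flagging threshold (default 8).
#' @return The despiked spectrum tibble.
#' @export
despike <- function(spectrum, z_threshold = 8) {
  validate_spectrum(spectrum)
  if (nrow(spectrum) < 5) abort("despike() needs at least 5 points.")
  spectrum$intensity <- despike_vector(spectrum$intensity, z_threshold)
  spectrum
}

#' Subtract an asymmetric least squares baseline
#'
#' Estimates the broad fluorescence background with Eilers-type
#' asymmetric least squares (second-difference penalty `lambda`,
#' asymmetry `p`, fixed iteration count) and subtracts it. The grid is
#' unchanged. If the asymmetric weights have not stabilised after the
#' final iteration the last iterate is used and a warning is raised.
#'
#' @param spectrum Spectrum tibble, length >= 10.
#' @param lambda,p,iterations AsLS parameters (see [preprocess_config()]).
#' @return The baseline-corrected spectrum tibble.
#' @export
subtract_baseline <- function(spectrum, lambda = 1e5, p = 0.01, iterations = 10) {
  validate_spectrum(spectrum)
  if (nrow(spectrum) < 10) abort("subtract_baseline() needs at least 10 points.")
  fit <- asls_baseline_cpp(spectrum$intensity, lambda, p, as.integer(iterations))
  if (!fit$converged) {
    warn("AsLS weights did not stabilise within the iteration budget; using last iterate.")
  }
  spectrum$intensity <- spectrum$intensity - fit$baseline
  spectrum
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean over replicates that share an identical
#' wavenumber sequence. Heterogeneous grids are an error: resample first
#' (see [resample_uniform()]).
#'
#' @param replicates Long tibble with `replicate`, `wavenumber`,
#'   `intensity` columns, or a list of spectrum tibbles.
#' @return One averaged spectrum tibble.
#' @export
average_replicates <- function(replicates) {
  specs <- if (is.data.frame(replicates)) {
    if (!"replicate" %in% names(replicates)) list(replicates)
    else unname(split(replicates, replicates$replicate))
  } else replicates
  if (length(specs) == 0) abort("No replicates to average.")
  w0 <- specs[[1]]$wavenumber
  same <- vapply(specs, function(s) {
    length(s$wavenumber) == length(w0) && all(s$wavenumber == w0)
  }, logical(1))
  if (!all(same)) {
    abort("Replicates are on different wavenumber grids; resample to a common grid first.")
  }
  y <- rowMeans(vapply(specs, function(s) s$intensity, numeric(length(w0))))
  tibble::tibble(wavenumber = w0, intensity = y)
}

#' Resample onto a uniform grid by linear interpolation
#'
#' Each output intensity is interpolated linearly between the two input
#' points bracketing the grid wavenumber; input points that fall exactly
#' on the grid are reproduced. The grid must lie inside the input's
#' support — no extrapolation, ever.
#'
#' @param spectrum Spectrum tibble (any strictly increasing grid).
#' @param grid Target [uniform_grid()].
#' @return Spectrum tibble on `grid$wavenumbers`.
#' @export
resample_uniform <- function(spectrum, grid = uniform_grid()) {
  validate_spectrum(spectrum)
  w <- spectrum$wavenumber
  if (grid$start < w[1] || grid$stop > w[length(w)]) {
    abort(sprintf(
      "Grid %g-%g lies outside the spectrum support %g-%g; extrapolation is not supported.",
      grid$start, grid$stop, w[1], w[length(w)]
    ))
  }
  out <- approx(w, spectrum$intensity, xout = grid$wavenumbers, method = "linear")
  tibble::tibble(wavenumber = out$x, intensity = out$y)
}

#' Standard normal variate normalisation
#'
#' Centers and scales one spectrum to mean 0, sd 1 (n-1 denominator),
#' removing additive offsets and multiplicative gain:
#' `snv(a*x + b) == snv(x)` for any `a > 0`.
#'
#' @param spectrum Spectrum tibble.
#' @return The normalised spectrum tibble.
#' @export
snv <- function(spectrum) {
  validate_spectrum(spectrum)
  s <- sd(spectrum$intensity)
  if (s == 0) {
    id <- if ("sample_id" %in% names(spectrum)) spectrum$sample_id[1] else "<unknown>"
    abort(sprintf("SNV undefined: zero intensity variance (sample %s).", id))
  }
  spectrum$intensity <- (spectrum$intensity - mean(spectrum$intensity)) / s
  spectrum
}

#' Preprocess one sample's replicates into a final spectrum
#'
#' The full per-sample chain, in fixed order: despike and
#' baseline-correct each replicate, resample each to the uniform grid,
#' average the replicates, then SNV-normalise the average. Replicates on
#' heterogeneous acquisition grids are supported via the per-replicate
#' resampling step.
#'
#' @param sample Long tibble for one sample (`replicate`, `wavenumber`,
#'   `intensity`, optional `sample_id`/`group`).
#' @param config [preprocess_config()].
#' @return One processed spectrum tibble (with `sample_id`/`group`
#'   carried over when present).
#' @export
preprocess_sample <- function(sample, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  sid <- if ("sample_id" %in% names(sample)) as.character(sample$sample_id[1]) else NULL
  specs <- if ("replicate" %in% names(sample)) {
    unname(split(sample, sample$replicate))
  } else list(sample)
  processed <- tryCatch(
    lapply(specs, function(sp) {
      sp <- despike(sp, config$despike_z_threshold)
      if (config$baseline) {
        sp <- subtract_baseline(
          sp, config$baseline_lambda, config$baseline_asymmetry,
          config$baseline_iterations
        )
      }
      resample_uniform(sp, config$grid)
    }),
    error = function(e) {
      abort(sprintf(
        "Preprocessing failed for sample %s: %s",
        sid %||% "<unknown>", conditionMessage(e)
      ))
    }
  )
  out <- snv(average_replicates(processed))
  if (!is.null(sid)) out$sample_id <- sid
  if ("group" %in% names(sample)) out$group <- sample$group[1]
  out
}

#' Build the samples-by-wavenumbers matrix for a cohort
#'
#' Runs [preprocess_sample()] on every sample and assembles the wide
#' analysis table: one row per sample, columns `sample_id`, `group`, then
#' one numeric column per grid wavenumber (named by its cm^-1 value).
#' This is the input to [run_univariate()] and [loocv_pca_lda()];
#' restrict it to a window with [restrict_range()].
#'
#' @param cohort Long cohort tibble ([simulate_cohort()] or
#'   [read_cohort()]); needs >= 2 samples and both group labels.
#' @param config [preprocess_config()].
#' @return A wide tibble (`spectral_matrix`-shaped).
#' @export
cohort_matrix <- function(cohort, config = preprocess_config()) {
  keys <- cohort |> dplyr::distinct(.data$sample_id, .data$group)
  if (nrow(keys) < 2) abort("cohort_matrix() needs at least 2 samples.")
  if (length(unique(keys$group)) < 2) {
    abort("cohort_matrix() needs both group labels present.")
  }
  samples <- split(cohort, factor(cohort$sample_id, levels = unique(cohort$sample_id)))
  rows <- lapply(samples, function(s) {
    sp <- preprocess_sample(s, config)
    vals <- as.list(sp$intensity)
    names(vals) <- as.character(sp$wavenumber)
    c(list(sample_id = as.character(s$sample_id[1]), group = s$group[1]), vals)
  })
  dplyr::bind_rows(rows)
}

# Split a wide spectral-matrix tibble into numeric matrix + metadata.
matrix_parts <- function(data) {
  w <- suppressWarnings(as.numeric(names(data)))
  spec_cols <- which(!is.na(w))
  if (length(spec_cols) < 2) {
    abort("Expected a wide spectral matrix with wavenumber-named columns.")
  }
  X <- as.matrix(data[spec_cols])
  storage.mode(X) <- "double"
  colnames(X) <- names(data)[spec_cols]
  list(
    X = X,
    wavenumbers = w[spec_cols],
    group = if ("group" %in% names(data)) data$group else NULL,
    sample_id = if ("sample_id" %in% names(data)) data$sample_id else NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
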