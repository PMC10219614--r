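#' Uniform wavenumber grid
#'
#' A uniform acquisition/resampling grid over a closed wavenumber interval.
#' The default corresponds to the usual biofluid SERS window: 350 to
#' 2350 cm^-1 sampled every 2 cm^-1, i.e. 1001 points with both endpoints
#' included.
#'
#' @param start,stop Interval bounds in cm^-1 (`start < stop`).
#' @param step Grid spacing in cm^-1 (`> 0`); `stop - start` must be an
#'   integer multiple of `step`.
#' @return An object of class `uniform_grid`: a list with `start`, `stop`,
#'   `step` and the expanded `wavenumbers` vector.
#' @examples
#' g <- uniform_grid()
#' length(g$wavenumbers) # 1001
#' @export
uniform_grid <- function(start = 350, stop = 2350, step = 2) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step)) {
    abort("`start`, `stop` and `step` must be numeric.")
  }
  if (start >= stop) abort("`start` must be strictly less than `stop`.")
  if (step <= 0) abort("`step` must be positive.")
  n_steps <- (stop - start) / step
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    abort("`stop - start` must be an integer multiple of `step`.")
  }
  structure(
    list(
      start = start, stop = stop, step = step,
      wavenumbers = seq(start, stop, by = step)
    ),
    class = "uniform_grid"
  )
}

#' @export
print.uniform_grid <- function(x, ...) {
  cat(sprintf(
    "<uniform_grid> %g-%g cm^-1, step %g (%d points)\n",
    x$start, x$stop, x$step, length(x$wavenumbers)
  ))
  invisible(x)
}

# Internal validator shared by I/O and preprocessing entry points.
validate_spectrum <- function(spectrum, arg = "spectrum") {
  if (!is.data.frame(spectrum)) {
    abort(sprintf("`%s` must be a data frame with wavenumber/intensity columns.", arg))
  }
  if (!all(c("wavenumber", "intensity") %in% names(spectrum))) {
    abort(sprintf("`%s` must have `wavenumber` and `intensity` columns.", arg))
  }
  w <- spectrum$wavenumber
  y <- spectrum$intensity
  if (nrow(spectrum) < 2) abort(sprintf("`%s` must contain at least 2 points.", arg))
  if (!all(is.finite(w)) || !all(is.finite(y))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  if (any(diff(w) <= 0)) {
    abort(sprintf("`%s` wavenumbers must be strictly increasing (no duplicates).", arg))
  }
  invisible(spectrum)
}

#' Read a two-column spectrum file
#'
#' Reads one Raman/SERS spectrum stored as delimited text with two numeric
#' columns (wavenumber in cm^-1, intensity in arbitrary units). Lines
#' starting with `#` are comments. The delimiter is auto-detected among
#' comma, tab and whitespace. Rows are returned sorted by ascending
#' wavenumber; duplicate wavenumbers are an error (they indicate an
#' acquisition fault and are never silently merged).
#'
#' @param path Path to the spectrum file.
#' @param sample_id,replicate Optional metadata attached as columns.
#' @return A tibble with columns `wavenumber` and `intensity` (plus
#'   `sample_id`/`replicate` when supplied), sorted by wavenumber.
#' @export
read_spectrum <- function(path, sample_id = NULL, replicate = NULL) {
  if (!file.exists(path)) abort(sprintf("Spectrum file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  line_no <- seq_along(lines)[keep]
  if (length(data_lines) < 2) {
    abort(sprintf("Spectrum file %s has fewer than 2 data rows.", path))
  }
  fields <- strsplit(trimws(data_lines), "\\s*,\\s*|\\t+|\\s+")
  bad_shape <- lengths(fields) != 2L
  if (any(bad_shape)) {
    abort(sprintf(
      "Malformed row in %s at line %d: expected 2 columns.",
      path, line_no[which(bad_shape)[1]]
    ))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 2, byrow = TRUE)
  bad_num <- !stats::complete.cases(m)
  if (any(bad_num)) {
    abort(sprintf(
      "Malformed row in %s at line %d: non-numeric value.",
      path, line_no[which(bad_num)[1]]
    ))
  }
  if (anyDuplicated(m[, 1])) {
    abort(sprintf("Duplicate wavenumbers in %s.", path))
  }
  ord <- order(m[, 1])
  out <- tibble::tibble(wavenumber = m[ord, 1], intensity = m[ord, 2])
  if (!is.null(sample_id)) out$sample_id <- sample_id
  if (!is.null(replicate)) out$replicate <- as.integer(replicate)
  validate_spectrum(out)
  out
}

#' Write a spectrum to a two-column file
#'
#' Writes `wavenumber,intensity` rows as comma-separated text at full
#' double precision, so `read_spectrum(write_spectrum(s))` round-trips
#' exactly.
#'
#' @param spectrum Data frame with `wavenumber` and `intensity` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  validate_spectrum(spectrum)
  lines <- paste(
    format(spectrum$wavenumber, digits = 17, trim = TRUE, scientific = FALSE),
    format(spectrum$intensity, digits = 17, trim = TRUE),
    sep = ","
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled cohort from a manifest
#'
#' The manifest is a CSV with header `sample_id,group,spectrum_path`, one
#' row per replicate file. Group labels must be `cancer` or `control`.
#' Samples keep their manifest order; replicates are numbered in manifest
#' order within each sample.
#'
#' @param manifest Path to the manifest CSV.
#' @return A long tibble with columns `sample_id`, `group`, `replicate`,
#'   `wavenumber`, `intensity` — one row per spectral point.
#' @export
read_cohort <- function(manifest) {
  if (!file.exists(manifest)) abort(sprintf("Manifest not found: %s", manifest))
  man <- readr::read_csv(manifest, show_col_types = FALSE)
  needed <- c("sample_id", "group", "spectrum_path")
  if (!all(needed %in% names(man))) {
    abort("Manifest must have columns sample_id, group, spectrum_path.")
  }
  bad_group <- setdiff(unique(man$group), c("cancer", "control"))
  if (length(bad_group) > 0) {
    abort(sprintf(
      "Unknown group label(s): %s (expected cancer/control).",
      paste(bad_group, collapse = ", ")
    ))
  }
  if (anyDuplicated(man[c("sample_id", "spectrum_path")])) {
    abort("Duplicate (sample_id, spectrum_path) rows in manifest.")
  }
  grp_by_sample <- man |>
    dplyr::distinct(.data$sample_id, .data$group)
  if (anyDuplicated(grp_by_sample$sample_id)) {
    abort("A sample_id appears with more than one group label.")
  }
  missing <- man$spectrum_path[!file.exists(man$spectrum_path)]
  if (length(missing) > 0) {
    bad <- man$sample_id[match(missing[1], man$spectrum_path)]
    abort(sprintf("Missing spectrum file for sample %s: %s", bad, missing[1]))
  }
  man <- man |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = unique(.data$sample_id))) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(replicate = dplyr::row_number()) |>
    dplyr::ungroup()
  purrr::pmap(
    list(man$spectrum_path, as.character(man$sample_id), man$group, man$replicate),
    function(path, sid, grp, rep) {
      sp <- read_spectrum(path, sample_id = sid, replicate = rep)
      sp$group <- grp
      sp
    }
  ) |>
    purrr::list_rbind() |>
    dplyr::select("sample_id", "group", "replicate", "wavenumber", "intensity")
}

#' Write a cohort as spectrum files plus a manifest
#'
#' The inverse of [read_cohort()]: one two-column file per replicate under
#' `dir`, plus `manifest.csv` in the dialect [read_cohort()] expects.
#'
#' @param cohort Long cohort tibble (see [simulate_cohort()]).
#' @param dir Output directory (created if absent).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  keys <- cohort |>
    dplyr::distinct(.data$sample_id, .data$group, .data$replicate)
  paths <- file.path(dir, sprintf("%s_rep%03d.csv", keys$sample_id, keys$replicate))
  for (i in seq_len(nrow(keys))) {
    sp <- cohort |>
      dplyr::filter(
        .data$sample_id == keys$sample_id[i],
        .data$replicate == keys$replicate[i]
      )
    write_spectrum(sp, paths[i])
  }
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(
    tibble::tibble(
      sample_id = keys$sample_id, group = keys$group, spectrum_path = paths
    ),
    manifest
  )
  invisible(manifest)
}

#' Restrict data to a closed wavenumber window
#'
#' Keeps exactly the points with `lo <= wavenumber <= hi` (closed interval:
#' on-grid endpoints are kept). Works on a long spectrum/cohort tibble with
#' a `wavenumber` column, or on a wide samples-by-wavenumbers matrix tibble
#' as produced by [cohort_matrix()] (wavenumber-named columns are
#' selected). Restriction is idempotent.
#'
#' @param data Long tibble with a `wavenumber` column, or wide spectral
#'   matrix tibble.
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return Data of the same shape, restricted to the window.
#' @examples
#' g <- uniform_grid()
#' s <- tibble::tibble(wavenumber = g$wavenumbers, intensity = 0)
#' nrow(restrict_range(s, 2000, 2200)) # 101
#' @export
restrict_range <- function(data, lo, hi) {
  if (lo >= hi) abort("`lo` must be strictly less than `hi`.")
  if ("wavenumber" %in% names(data)) {
    out <- dplyr::filter(data, .data$wavenumber >= lo, .data$wavenumber <= hi)
    if (length(unique(out$wavenumber)) < 2) {
      abort(sprintf("Window [%g, %g] contains fewer than 2 grid points.", lo, hi))
    }
    return(out)
  }
  w <- suppressWarnings(as.numeric(names(data)))
  is_spec <- !is.na(w)
  keep <- is_spec & w >= lo & w <= hi
  if (sum(keep) < 2) {
    abort(sprintf("Window [%g, %g] contains fewer than 2 grid points.", lo, hi))
  }
  dplyr::bind_cols(data[!is_spec], data[keep])
}
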