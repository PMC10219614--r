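#' Tentative band assignment table
#'
#' Twenty vibrational bands commonly observed in salivary-exosome SERS
#' spectra on silver substrates, with their tentative molecular
#' assignments (thiocyanate, saccharides, proteins, lipids, nucleic
#' acids). Ships as plain data so users can extend or replace it; note
#' that several bands carry overlapping literature assignments (e.g.
#' 1655 cm^-1 is both nucleic acids and Amide I) which are reported
#' verbatim, not adjudicated.
#'
#' @return Tibble with columns `center` (cm^-1) and `assignment`.
#' @export
default_assignment_table <- function() {
  dplyr::select(default_peak_table(), "center", "assignment")
}

#' Detect peaks by prominence
#'
#' Local maxima whose prominence — height above the higher of the two
#' flanking key saddles (the minima separating the peak from the nearest
#' higher terrain on each side, or from the spectrum edge) — reaches
#' `min_prominence`. Prominence is preferred over bare local maxima so
#' noise shoulders on the flank of a strong band are not reported.
#'
#' @param spectrum Spectrum tibble, length >= 5.
#' @param min_prominence Minimum prominence (a.u.).
#' @return Tibble with `center` (cm^-1), `height`, `prominence`, sorted
#'   by ascending center; zero rows when nothing qualifies.
#' @export
detect_peaks <- function(spectrum, min_prominence) {
  validate_spectrum(spectrum)
  if (nrow(spectrum) < 5) abort("detect_peaks() needs at least 5 points.")
  y <- spectrum$intensity
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  cand <- which(is_max)
  prom <- vapply(cand, function(i) {
    left_min <- y[i]
    j <- i
    while (j > 1 && y[j - 1] <= y[i]) {
      j <- j - 1
      left_min <- min(left_min, y[j])
    }
    right_min <- y[i]
    j <- i
    while (j < n && y[j + 1] <= y[i]) {
      j <- j + 1
      right_min <- min(right_min, y[j])
    }
    y[i] - max(left_min, right_min)
  }, numeric(1))
  keep <- prom >= min_prominence
  tibble::tibble(
    center = spectrum$wavenumber[cand[keep]],
    height = y[cand[keep]],
    prominence = prom[keep]
  )
}

#' Annotate peak centers against a band table
#'
#' Matches each detected center to the nearest table band within
#' `tolerance` cm^-1 (ties go to the nearer band; the result does not
#' depend on table row order). Centers beyond tolerance of every band
#' are reported unmatched (`NA` assignment).
#'
#' @param centers Numeric vector of peak centers (cm^-1), or the output
#'   of [detect_peaks()].
#' @param table Assignment table (default [default_assignment_table()]).
#' @param tolerance Maximum |center - band| distance (default 6 cm^-1,
#'   three grid steps).
#' @return Tibble with `center`, `band`, `assignment`, `distance`.
#' @export
annotate_peaks <- function(centers, table = default_assignment_table(),
                           tolerance = 6) {
  if (is.data.frame(centers)) centers <- centers$center
  stopifnot(tolerance > 0, all(c("center", "assignment") %in% names(table)))
  if (length(centers) == 0) {
    return(tibble::tibble(
      center = numeric(), band = numeric(),
      assignment = character(), distance = numeric()
    ))
  }
  purrr::map(centers, function(cc) {
    d <- abs(table$center - cc)
    i <- which.min(d)
    if (d[i] <= tolerance) {
      tibble::tibble(
        center = cc, band = table$center[i],
        assignment = table$assignment[i], distance = d[i]
      )
    } else {
      tibble::tibble(
        center = cc, band = NA_real_,
        assignment = NA_character_, distance = NA_real_
      )
    }
  }) |> purrr::list_rbind()
}
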