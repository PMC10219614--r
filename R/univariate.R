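#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. Degenerate inputs follow the
#' convention used for pointwise spectral testing: if both groups have
#' zero variance the test returns `t = 0, p = 1` when the means agree and
#' `p = 0` (with a warning) when they differ.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance Student statistic instead of
#'   Welch (default `FALSE`).
#' @return A one-row tibble with columns `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t <- function(a, b, pooled = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("Each group needs at least 2 values.")
  res <- col_welch(cbind(a), cbind(b), pooled = pooled)
  if (res$degenerate[1] && res$p[1] == 0) {
    warn("Both group variances are zero with unequal means; p-value forced to 0.")
  }
  tibble::tibble(t = res$t, df = res$df, p = res$p)
}

# Vectorised Welch (or pooled Student) t-test over matrix columns.
col_welch <- function(A, B, pooled = FALSE) {
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- colSums(sweep(A, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(B, 2, m2)^2) / (n2 - 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(t), df)
  degen <- v1 == 0 & v2 == 0
  if (any(degen)) {
    eq <- degen & (m1 == m2)
    t[eq] <- 0; df[eq] <- n1 + n2 - 2; p[eq] <- 1
    ne <- degen & (m1 != m2)
    t[ne] <- sign(m1[ne] - m2[ne]) * Inf; df[ne] <- n1 + n2 - 2; p[ne] <- 0
  }
  list(t = unname(t), df = unname(df), p = unname(p), degenerate = unname(degen))
}

#' Per-wavenumber two-group tests
#'
#' One Welch test per wavenumber column of the processed
#' samples-by-wavenumbers table, cancer minus control. Column order is
#' preserved. Zero-variance columns are kept (p = 1, flagged) so the
#' result always has one row per grid point.
#'
#' @param data Wide spectral matrix tibble (see [cohort_matrix()]) with a
#'   `group` column.
#' @param pooled Pooled-variance Student test instead of Welch.
#' @return A tibble with columns `wavenumber`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
pointwise_tests <- function(data, pooled = FALSE) {
  parts <- matrix_parts(data)
  if (is.null(parts$group)) abort("`data` needs a `group` column.")
  grp <- parts$group
  if (length(unique(grp)) < 2) abort("Both groups must be present.")
  if (sum(grp == "cancer") < 2 || sum(grp == "control") < 2) {
    abort("Each group needs at least 2 samples.")
  }
  res <- col_welch(
    parts$X[grp == "cancer", , drop = FALSE],
    parts$X[grp == "control", , drop = FALSE],
    pooled = pooled
  )
  if (any(res$degenerate & res$p == 0)) {
    warn("Some columns have zero variance in both groups with unequal means.")
  }
  tibble::tibble(
    wavenumber = parts$wavenumbers,
    t = res$t, df = res$df, p = res$p, degenerate = res$degenerate
  )
}

#' Benjamini-Hochberg step-up procedure
#'
#' Controls the false discovery rate at `target_fdr`: sort the m
#' p-values ascending, find the largest k with `p_(k) <= k * q / m`, and
#' reject every hypothesis with `p <= p_(k)`. Also returns BH-adjusted
#' p-values (`min over j >= i of m * p_(j) / j`, capped at 1, in input
#' order) and the realised raw-p cutoff `p_(k)` (0 when nothing is
#' rejected).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param target_fdr Target FDR level q (default 0.01).
#' @return A list with `p_adjusted`, `reject` (logical mask) and
#'   `raw_p_cutoff`.
#' @examples
#' benjamini_hochberg(c(0.001, 0.01, 0.02, 0.2), target_fdr = 0.05)
#' @export
benjamini_hochberg <- function(p_values, target_fdr = 0.01) {
  if (length(p_values) == 0) abort("Empty p-value vector.")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must be finite and in [0, 1].")
  }
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  k <- which(ps <= seq_len(m) * target_fdr / m)
  cutoff <- if (length(k) == 0) 0 else ps[max(k)]
  adj_sorted <- rev(cummin(rev(m * ps / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  p_adjusted <- numeric(m)
  p_adjusted[ord] <- adj_sorted
  list(
    p_adjusted = p_adjusted,
    reject = p_values <= cutoff & cutoff > 0,
    raw_p_cutoff = cutoff
  )
}

#' Group difference spectrum
#'
#' Pointwise mean over cancer rows minus mean over control rows of the
#' processed matrix.
#'
#' @param data Wide spectral matrix tibble with a `group` column.
#' @return A tibble with columns `wavenumber` and `difference`.
#' @export
difference_spectrum <- function(data) {
  parts <- matrix_parts(data)
  if (is.null(parts$group)) abort("`data` needs a `group` column.")
  if (length(unique(parts$group)) < 2) abort("Both groups must be present.")
  tibble::tibble(
    wavenumber = parts$wavenumbers,
    difference = unname(
      colMeans(parts$X[parts$group == "cancer", , drop = FALSE]) -
        colMeans(parts$X[parts$group == "control", , drop = FALSE])
    )
  )
}

#' Pointwise univariate analysis with FDR control
#'
#' Runs [pointwise_tests()] on every wavenumber, applies
#' [benjamini_hochberg()] at `target_fdr`, and attaches the group
#' [difference_spectrum()]. The realised raw-p significance cutoff is the
#' data-dependent analogue of the "BH threshold" a study would print as a
#' percentage.
#'
#' @param data Wide spectral matrix tibble with a `group` column.
#' @param target_fdr Target FDR (default 0.01).
#' @param pooled Pooled-variance Student test instead of Welch.
#' @return A `univariate_report` object; see [tidy()] / [glance()].
#' @export
run_univariate <- function(data, target_fdr = 0.01, pooled = FALSE) {
  tests <- pointwise_tests(data, pooled = pooled)
  bh <- benjamini_hochberg(tests$p, target_fdr)
  results <- tests |>
    dplyr::mutate(
      p_adjusted = bh$p_adjusted,
      significant = bh$reject
    )
  structure(
    list(
      results = results,
      difference = difference_spectrum(data),
      target_fdr = target_fdr,
      raw_p_cutoff = bh$raw_p_cutoff,
      test = if (pooled) "student" else "welch"
    ),
    class = "univariate_report"
  )
}

#' @export
print.univariate_report <- function(x, ...) {
  cat("<univariate_report>\n")
  cat(sprintf(
    "  %d wavenumbers tested (%s t-test), %d significant at FDR %g\n",
    nrow(x$results), x$test, sum(x$results$significant), x$target_fdr
  ))
  cat(sprintf(
    "  realised raw-p significance cutoff: %.4g (%.2f%%)\n",
    x$raw_p_cutoff, 100 * x$raw_p_cutoff
  ))
  invisible(x)
}

#' @rdname run_univariate
#' @param x A `univariate_report`.
#' @param ... Unused.
#' @export
tidy.univariate_report <- function(x, ...) {
  dplyr::left_join(x$results, x$difference, by = "wavenumber")
}

#' @rdname run_univariate
#' @export
glance.univariate_report <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$results),
    n_significant = sum(x$results$significant),
    raw_p_cutoff = x$raw_p_cutoff,
    target_fdr = x$target_fdr,
    test = x$test
  )
}
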