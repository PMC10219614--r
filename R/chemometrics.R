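#' Principal component analysis of a spectral matrix
#'
#' PCA on centered, unscaled data (SNV has already standardised each
#' spectrum, so no column autoscaling). Computed via singular value
#' decomposition of the centered matrix; eigenvalues use the n-1 sample
#' covariance convention; loadings are orthonormal and sorted by
#' decreasing eigenvalue; explained-variance ratios sum to 1 over the
#' returned components.
#'
#' @param data Wide spectral matrix tibble (see [cohort_matrix()]) or a
#'   plain numeric matrix (samples x features).
#' @return A `pca_fit` with `mean_vector`, `loadings` (features x k),
#'   `eigenvalues`, `explained_variance_ratio`, `scores` (samples x k).
#' @export
fit_pca <- function(data) {
  X <- if (is.data.frame(data)) matrix_parts(data)$X else as.matrix(data)
  n <- nrow(X)
  if (n < 2) abort("fit_pca() needs at least 2 samples.")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  k <- min(n - 1, ncol(X))
  sv <- svd(Xc, nu = k, nv = k)
  eigenvalues <- sv$d[seq_len(k)]^2 / (n - 1)
  total <- sum(sv$d^2) / (n - 1)
  structure(
    list(
      mean_vector = mu,
      loadings = sv$v,
      eigenvalues = eigenvalues,
      explained_variance_ratio = eigenvalues / total,
      scores = sv$u %*% diag(sv$d[seq_len(k)], k)
    ),
    class = "pca_fit"
  )
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf(
    "<pca_fit> %d components; first ratios: %s\n",
    length(x$eigenvalues),
    paste(sprintf("%.3f", utils::head(x$explained_variance_ratio, 3)), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname fit_pca
#' @param x A `pca_fit`.
#' @param ... Unused.
#' @export
tidy.pca_fit <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_ratio = x$explained_variance_ratio,
    cumulative_percent = 100 * cumsum(x$explained_variance_ratio)
  )
}

#' Cumulative explained variance
#'
#' @param model A `pca_fit`.
#' @param k Number of leading components.
#' @return Percentage of variance explained by the first `k` components.
#' @export
cumulative_variance <- function(model, k) {
  stopifnot(inherits(model, "pca_fit"))
  if (k < 1 || k > length(model$explained_variance_ratio)) {
    abort(sprintf("`k` must be in 1..%d.", length(model$explained_variance_ratio)))
  }
  100 * sum(model$explained_variance_ratio[seq_len(k)])
}

#' Project new spectra onto fitted principal components
#'
#' @param model A `pca_fit`.
#' @param newdata Matrix or wide tibble with the same feature columns.
#' @param n_components Number of leading components to keep.
#' @return Score matrix (samples x n_components).
#' @export
project_pca <- function(model, newdata, n_components = ncol(model$loadings)) {
  X <- if (is.data.frame(newdata)) matrix_parts(newdata)$X else
    matrix(newdata, ncol = length(model$mean_vector))
  sweep(X, 2, model$mean_vector) %*% model$loadings[, seq_len(n_components), drop = FALSE]
}

#' Two-class Fisher linear discriminant
#'
#' Fisher direction `w` proportional to `Sw^-1 (mu_cancer - mu_control)`
#' with the pooled within-class scatter `Sw`; `w` is scaled to unit
#' length and oriented so the cancer class mean score exceeds the
#' control mean score (larger score = more cancer-like). The decision
#' threshold is the midpoint of the projected class means (equal
#' priors); an option weights the threshold by class proportions. A
#' near-singular scatter is ridged by `1e-8 * mean(diag(Sw))`.
#'
#' @param scores Numeric matrix (samples x k), typically PC scores.
#' @param labels Character vector of `"cancer"` / `"control"`.
#' @param priors `"equal"` (midpoint threshold) or `"proportional"`.
#' @return An `lda_fit` with `weights`, `threshold`, `class_means`.
#' @export
fit_lda <- function(scores, labels, priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  scores <- as.matrix(scores)
  ca <- scores[labels == "cancer", , drop = FALSE]
  ct <- scores[labels == "control", , drop = FALSE]
  if (nrow(ca) < 2 || nrow(ct) < 2) abort("Each class needs at least 2 samples.")
  mu_ca <- colMeans(ca)
  mu_ct <- colMeans(ct)
  Sw <- crossprod(sweep(ca, 2, mu_ca)) + crossprod(sweep(ct, 2, mu_ct))
  w <- tryCatch(
    solve(Sw, mu_ca - mu_ct),
    error = function(e) {
      ridge <- 1e-8 * mean(diag(Sw))
      if (ridge == 0) ridge <- 1e-8
      solve(Sw + diag(ridge, ncol(Sw)), mu_ca - mu_ct)
    }
  )
  nrm <- sqrt(sum(w^2))
  if (nrm == 0 || !all(is.finite(w))) {
    # degenerate separation: fall back to the first axis, fixed sign
    w <- c(1, rep(0, length(w) - 1))
    nrm <- 1
  }
  w <- w / nrm
  m_ca <- sum(w * mu_ca)
  m_ct <- sum(w * mu_ct)
  if (m_ca < m_ct) {
    w <- -w; m_ca <- -m_ca; m_ct <- -m_ct
  }
  threshold <- if (priors == "equal" || m_ca == m_ct) {
    (m_ca + m_ct) / 2
  } else {
    n1 <- nrow(ca); n2 <- nrow(ct)
    # shift the midpoint by the log prior-odds over the pooled score sd
    s2 <- (sum((ca %*% w - m_ca)^2) + sum((ct %*% w - m_ct)^2)) / (n1 + n2 - 2)
    (m_ca + m_ct) / 2 - s2 * log(n1 / n2) / (m_ca - m_ct)
  }
  structure(
    list(
      weights = as.numeric(w),
      threshold = threshold,
      class_means = c(cancer = m_ca, control = m_ct),
      priors = priors
    ),
    class = "lda_fit"
  )
}

#' Score and classify with a fitted discriminant
#'
#' Scores are `scores %*% weights`; predicted label is `"cancer"` when
#' the score strictly exceeds the threshold (ties classify as control).
#'
#' @param object An `lda_fit`.
#' @param newdata Score matrix (samples x k).
#' @param ... Unused.
#' @return Tibble with `score` and `predicted`.
#' @export
predict.lda_fit <- function(object, newdata, ...) {
  s <- as.numeric(as.matrix(newdata) %*% object$weights)
  tibble::tibble(
    score = s,
    predicted = ifelse(s > object$threshold, "cancer", "control")
  )
}

#' Leave-one-out cross-validated PCA-LDA
#'
#' For each sample in turn: refit PCA on the remaining samples, project
#' everything onto the leading `n_components` components, fit the Fisher
#' discriminant on the training scores, then score and classify the
#' held-out sample. PCA is refit inside every fold, so the held-out
#' spectrum never influences its own projection. Deterministic.
#'
#' @param data Wide spectral matrix tibble with `sample_id` and `group`
#'   columns, or a numeric matrix plus `labels`.
#' @param n_components Retained components (default 19), or
#'   `"variance"` to retain the smallest k reaching
#'   `variance_target` cumulative explained variance in each fold.
#' @param labels,sample_ids Needed only when `data` is a bare matrix.
#' @param priors Passed to [fit_lda()].
#' @param variance_target Cumulative explained-variance fraction used
#'   when `n_components = "variance"` (default 0.99).
#' @return A `sers_cv` object: per-sample scores, truths, predictions.
#' @export
loocv_pca_lda <- function(data, n_components = 19, labels = NULL,
                          sample_ids = NULL, priors = "equal",
                          variance_target = 0.99) {
  if (is.data.frame(data)) {
    parts <- matrix_parts(data)
    X <- parts$X
    labels <- parts$group
    sample_ids <- parts$sample_id %||% as.character(seq_len(nrow(X)))
  } else {
    X <- as.matrix(data)
    if (is.null(labels)) abort("`labels` is required for matrix input.")
    sample_ids <- sample_ids %||% as.character(seq_len(nrow(X)))
  }
  n <- nrow(X)
  if (n < 3) abort("LOOCV needs at least 3 samples.")
  by_variance <- identical(n_components, "variance")
  if (!by_variance) {
    n_components <- as.integer(n_components)
    if (n_components > min(n - 2, ncol(X))) {
      abort(sprintf(
        "n_components = %d exceeds the per-fold limit min(n - 2, features) = %d.",
        n_components, min(n - 2, ncol(X))
      ))
    }
  }
  score <- numeric(n)
  predicted <- character(n)
  for (i in seq_len(n)) {
    pca <- fit_pca(X[-i, , drop = FALSE])
    k <- if (by_variance) {
      max(2L, which(cumsum(pca$explained_variance_ratio) >= variance_target)[1])
    } else n_components
    if (k > ncol(pca$loadings)) {
      abort(sprintf("Fold %d supports only %d components (requested %d).",
                    i, ncol(pca$loadings), k))
    }
    train <- pca$scores[, seq_len(k), drop = FALSE]
    lda <- fit_lda(train, labels[-i], priors = priors)
    held <- project_pca(pca, X[i, , drop = FALSE], k)
    pr <- predict(lda, held)
    score[i] <- pr$score - lda$threshold # center so 0 is the decision point
    predicted[i] <- pr$predicted
  }
  structure(
    list(
      results = tibble::tibble(
        sample_id = sample_ids,
        true_label = labels,
        score = score,
        predicted = predicted
      ),
      n_components = if (by_variance) "variance" else n_components,
      priors = priors
    ),
    class = "sers_cv"
  )
}

#' @export
print.sers_cv <- function(x, ...) {
  acc <- mean(x$results$predicted == x$results$true_label)
  cat(sprintf(
    "<sers_cv> %d samples, %s components; LOOCV accuracy %.1f%%\n",
    nrow(x$results), format(x$n_components), 100 * acc
  ))
  invisible(x)
}

#' @rdname loocv_pca_lda
#' @param x A `sers_cv`.
#' @param ... Unused.
#' @export
tidy.sers_cv <- function(x, ...) x$results

#' @rdname loocv_pca_lda
#' @export
glance.sers_cv <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n = nrow(r),
    accuracy = mean(r$predicted == r$true_label),
    auc = roc_auc(r$score, r$true_label)
  )
}
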