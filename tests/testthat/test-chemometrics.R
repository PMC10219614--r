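test_that("PCA agrees with the prcomp oracle on random matrices", {
  set.seed(30)
  for (i in 1:50) {
    X <- matrix(rnorm(10 * 6), 10, 6)
    fit <- fit_pca(X)
    ref <- prcomp(X, center = TRUE, scale. = FALSE)
    expect_equal(fit$eigenvalues, unname(ref$sdev^2)[1:length(fit$eigenvalues)],
                 tolerance = 1e-8)
    expect_equal(
      fit$explained_variance_ratio,
      unname(ref$sdev^2 / sum(ref$sdev^2))[1:length(fit$eigenvalues)],
      tolerance = 1e-8
    )
    # loadings agree up to sign
    for (k in 1:3) {
      expect_equal(abs(sum(fit$loadings[, k] * ref$rotation[, k])), 1,
                   tolerance = 1e-8)
    }
  }
})

test_that("PCA model invariants hold: orthonormal loadings, ordered eigenvalues, exact reconstruction", {
  set.seed(31)
  X <- matrix(rnorm(12 * 8), 12, 8)
  fit <- fit_pca(X)
  G <- crossprod(fit$loadings)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8)
  expect_true(all(diff(fit$eigenvalues) <= 1e-10))
  expect_true(all(fit$eigenvalues >= -1e-12))
  expect_equal(sum(fit$explained_variance_ratio), 1, tolerance = 1e-8)
  recon <- fit$scores %*% t(fit$loadings) + rep(1, 12) %o% fit$mean_vector
  expect_equal(recon, X, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rank-1 data put all variance on the first component", {
  v <- rnorm(20)
  X <- outer(c(1, 2, 5, -3), v) + rep(1, 4) %o% rnorm(20)
  fit <- fit_pca(X)
  expect_equal(fit$explained_variance_ratio[1], 1, tolerance = 1e-10)
  expect_equal(cumulative_variance(fit, 1), 100, tolerance = 1e-8)
})

test_that("isotropic data split variance evenly at large n", {
  set.seed(32)
  fit <- fit_pca(matrix(rnorm(4000 * 2), ncol = 2))
  expect_equal(fit$explained_variance_ratio, c(0.5, 0.5), tolerance = 0.05)
})

test_that("cumulative_variance is monotone, complete and validated", {
  set.seed(33)
  fit <- fit_pca(matrix(rnorm(9 * 5), 9))
  ks <- seq_along(fit$eigenvalues)
  cv <- vapply(ks, function(k) cumulative_variance(fit, k), numeric(1))
  expect_true(!is.unsorted(cv))
  expect_equal(cv[length(cv)], 100, tolerance = 1e-8)
  expect_error(cumulative_variance(fit, 0), "must be in")
  expect_error(cumulative_variance(fit, 99), "must be in")
})

test_that("Fisher LDA matches the explicit 2x2 formula and the MASS oracle", {
  set.seed(34)
  ca <- cbind(rnorm(20, 2), rnorm(20, 1, 2))
  ct <- cbind(rnorm(15, 0), rnorm(15, 0, 2))
  scores <- rbind(ca, ct)
  labels <- rep(c("cancer", "control"), c(20, 15))
  fit <- fit_lda(scores, labels)

  Sw <- crossprod(sweep(ca, 2, colMeans(ca))) + crossprod(sweep(ct, 2, colMeans(ct)))
  w_ref <- solve(Sw) %*% (colMeans(ca) - colMeans(ct))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(abs(sum(fit$weights * w_ref)), 1, tolerance = 1e-8)
  expect_gt(fit$class_means["cancer"], fit$class_means["control"])
  expect_equal(fit$threshold, mean(fit$class_means), tolerance = 1e-12)

  mass <- MASS::lda(scores, grouping = labels)
  dir_mass <- mass$scaling[, 1] / sqrt(sum(mass$scaling[, 1]^2))
  expect_equal(abs(sum(fit$weights * dir_mass)), 1, tolerance = 1e-6)
})

test_that("well-separated 1-D classes are classified perfectly; ties go to control", {
  scores <- matrix(c(10, 10.1, 0, 0.1), ncol = 1)
  labels <- c("cancer", "cancer", "control", "control")
  fit <- fit_lda(scores, labels)
  pred <- predict(fit, scores)
  expect_equal(pred$predicted, labels)
  at_threshold <- matrix(fit$threshold / fit$weights[1], ncol = 1)
  expect_equal(predict(fit, at_threshold)$predicted, "control")
})

test_that("equal class means fall back to the fixed orientation rule", {
  set.seed(35)
  X <- matrix(rnorm(40), 20, 2)
  X <- rbind(X, X) # identical class clouds
  labels <- rep(c("cancer", "control"), each = 20)
  fit <- fit_lda(X, labels)
  expect_true(all(is.finite(fit$weights)))
  expect_gte(fit$class_means["cancer"], fit$class_means["control"])
})

test_that("LDA predictions are invariant to affine re-parameterisations of score space", {
  set.seed(36)
  scores <- rbind(
    matrix(rnorm(40, 1), 20, 2),
    matrix(rnorm(30, 0), 15, 2)
  )
  labels <- rep(c("cancer", "control"), c(20, 15))
  base_pred <- predict(fit_lda(scores, labels), scores)$predicted
  for (i in 1:10) {
    A <- matrix(rnorm(4), 2, 2)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2, 2)
    b <- rnorm(2)
    mapped <- sweep(scores %*% A, 2, b, "+")
    pred <- predict(fit_lda(mapped, labels), mapped)$predicted
    expect_equal(pred, base_pred)
  }
})

test_that("LOOCV covers each sample once, separates strong cohorts, and chances on null ones", {
  strong <- cohort_matrix(simulate_cohort(clean_config(
    n_cancer = 5, n_control = 5, noise_sd = 0.05,
    between_sample_sd = 0.05, seed = 40
  )))
  cv <- loocv_pca_lda(strong, n_components = 5)
  expect_equal(nrow(cv$results), 10)
  expect_equal(sort(cv$results$sample_id), sort(strong$sample_id))
  expect_equal(cv$results$predicted, cv$results$true_label)
  expect_equal(cv$results$predicted, ifelse(cv$results$score > 0, "cancer", "control"))

  set.seed(41)
  Xnull <- matrix(rnorm(40 * 60), 40)
  null_cv <- loocv_pca_lda(
    as_spectral_matrix(Xnull, rep(c("cancer", "control"), each = 20)),
    n_components = 10
  )
  acc <- mean(null_cv$results$predicted == null_cv$results$true_label)
  expect_gt(acc, 0.2) # chance within wide binomial error at n = 40
  expect_lt(acc, 0.8)
})

test_that("LOOCV folds do not leak: a fold's model ignores its held-out sample", {
  set.seed(42)
  X <- matrix(rnorm(12 * 25), 12)
  labels <- rep(c("cancer", "control"), each = 6)
  X2 <- X
  X2[3, ] <- rnorm(25, sd = 5)
  base <- loocv_pca_lda(as_spectral_matrix(X, labels), n_components = 4)
  pert <- loocv_pca_lda(as_spectral_matrix(X2, labels), n_components = 4)
  # fold 3 trains on rows != 3, identical in X and X2, so its score must
  # equal scoring the perturbed row through the model refit on X[-3, ]
  pca <- fit_pca(X[-3, ])
  lda <- fit_lda(pca$scores[, 1:4], labels[-3])
  manual <- predict(lda, project_pca(pca, X2[3, , drop = FALSE], 4))
  expect_equal(pert$results$score[3], manual$score - lda$threshold, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(pert$results$score[3], base$results$score[3])))
})

test_that("component-count validation names the limit", {
  set.seed(43)
  X <- matrix(rnorm(8 * 30), 8)
  wide <- as_spectral_matrix(X, rep(c("cancer", "control"), each = 4))
  expect_error(loocv_pca_lda(wide, n_components = 7), "per-fold limit")
  cv <- loocv_pca_lda(wide, n_components = "variance", variance_target = 0.9)
  expect_equal(cv$n_components, "variance")
  expect_equal(nrow(cv$results), 8)
})
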