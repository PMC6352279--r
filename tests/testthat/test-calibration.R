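test_that("mean centering removes column means and round-trips", {
  X <- cbind(c(1, 2, 3), c(4, 6, 8))
  ctr <- mean_center(X)
  expect_equal(ctr[, 1], c(-1, 0, 1))
  expect_equal(attr(ctr, "column_means"), c(2, 6))
  expect_lt(max(abs(colMeans(ctr))), 1e-10)
  # an already-centered matrix is unchanged
  expect_equal(unname(mean_center(ctr)[, ]), unname(ctr[, ]))
  # center then uncenter is the identity
  expect_equal(mean_uncenter(ctr), X, tolerance = 1e-12)
  expect_error(mean_center(X[1, , drop = FALSE]), "at least 2")
})

test_that("rmsecv implements the cross-validation error formula", {
  expect_equal(rmsecv(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsecv(c(0, 0, 0, 0), c(2, 2, 2, 2)), 2)  # constant residual c -> |c|
  expect_equal(rmsecv(c(1, 2, 7), c(1, 2, 3)), sqrt(16 / 3))
  expect_error(rmsecv(1:3, 1:4), "length mismatch")
})

test_that("calibration fits recover constructed low-rank relations", {
  set.seed(4)
  y <- rnorm(8)
  direction <- rnorm(30)
  X <- outer(y, direction)              # rank 1, proportional to y
  for (alg in c("pls1", "pcr")) {
    fit <- fit_calibration(X, y, 1, alg)
    expect_lt(max(abs(predict(fit, X) - y)), 1e-8 * diff(range(y)))
  }
  # n_pc = 0 predicts the training mean everywhere
  fit0 <- fit_calibration(X, y, 0)
  expect_equal(predict(fit0, X), rep(mean(y), 8))
  expect_error(fit_calibration(X, y, 8), "n_pc")
  expect_error(fit_calibration(X, rep(1, 8), 1), "zero-variance")
  # rows with missing y are dropped
  y2 <- y; y2[3] <- NA
  expect_equal(fit_calibration(X, y2, 1)$n, 7)
})

test_that("two-component noiseless mixtures are recovered end to end", {
  lib <- default_library(8L)
  vals <- matrix(0, 14, 8)
  set.seed(5)
  vals[3, ] <- runif(8, 0.1, 2)
  vals[9, ] <- runif(8, 0.1, 3)
  conc <- make_conc(vals)
  study <- generate_study(lib, conc, noise_off(), n_replicates = 1)
  M <- spectra_matrix(study)
  y <- vals[3, ]
  fit <- fit_calibration(M, y, 2, "pls1")
  expect_lt(sqrt(mean((predict(fit, M) - y)^2)), 1e-6)
  # rank-2 data: LOOCV at 2 latent variables is essentially exact
  cv <- loocv_calibration(M, y, max_pc = 4)
  expect_lt(cv$rmsecv[cv$n_pc == 2], 1e-6 * diff(range(y)))
})

test_that("PLS1 fitted values match an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(9)
  X <- matrix(rnorm(10 * 40), 10, dimnames = list(NULL, paste0("V", 1:40)))
  y <- rnorm(10)
  for (k in 1:4) {
    fit <- fit_calibration(X, y, k, "pls1")
    ref <- mixOmics::pls(X, y, ncomp = k, scale = FALSE, mode = "regression")
    ref_fitted <- predict(ref, X)$predict[, , k]
    expect_equal(predict(fit, X), as.numeric(ref_fitted), tolerance = 1e-8)
  }
})

test_that("PCR fitted values match prcomp plus least squares", {
  set.seed(10)
  X <- matrix(rnorm(12 * 25), 12)
  y <- rnorm(12)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  for (k in c(1, 3, 5)) {
    fit <- fit_calibration(X, y, k, "pcr")
    ref <- stats::fitted(stats::lm(y ~ pc$x[, 1:k]))
    expect_equal(predict(fit, X), as.numeric(ref), tolerance = 1e-8)
  }
})

test_that("leave-one-out results equal a brute-force refit oracle", {
  set.seed(12)
  for (rep in 1:5) {
    X <- matrix(rnorm(10 * 50), 10)
    y <- rnorm(10)
    for (alg in c("pls1", "pcr")) {
      cv <- loocv_calibration(X, y, max_pc = 5, algorithm = alg)
      ref <- naive_loocv(X, y, 5, alg)
      expect_equal(cv$rmsecv, ref$rmsecv, tolerance = 1e-10)
      for (k in 1:5) {
        expect_equal(cv$predictions[[k]]$y_pred, ref$pred[[k]],
                     tolerance = 1e-10)
      }
      expect_equal(nrow(cv$predictions[[1]]), 10)  # n predictions per n_pc
    }
  }
})

test_that("fold-wise centering uses training rows only", {
  # a deliberately leaky principal-component regression: means and scores are
  # computed once from all n rows (the held-out spectrum included) before the
  # folds; on noisy data it must disagree with the honest fold-wise procedure
  leaky_loocv <- function(X, y, k) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    scores <- svd(Xc)$u %*% diag(svd(Xc)$d)
    vapply(seq_along(y), function(i) {
      fit <- stats::lm(y[-i] ~ scores[-i, 1:k, drop = FALSE])
      sum(coef(fit) * c(1, scores[i, 1:k]))
    }, numeric(1))
  }
  set.seed(13)
  X <- matrix(rnorm(10 * 30), 10)
  y <- rnorm(10)
  honest <- loocv_calibration(X, y, max_pc = 3,
                              algorithm = "pcr")$predictions[[3]]$y_pred
  leaky <- leaky_loocv(X, y, 3)
  expect_gt(max(abs(honest - leaky)), 1e-8)
})

test_that("cross-validation scores are scale equivariant", {
  set.seed(14)
  X <- matrix(rnorm(10 * 30), 10)
  y <- runif(10)
  cv1 <- loocv_calibration(X, y, max_pc = 4)
  cv2 <- loocv_calibration(X, 10 * y, max_pc = 4)
  expect_equal(cv2$rmsecv, 10 * cv1$rmsecv, tolerance = 1e-10)
  expect_equal(cv2$r2, cv1$r2, tolerance = 1e-10)
  expect_equal(select_pcs(cv2)$n_pc, select_pcs(cv1)$n_pc)
})

test_that("latent-variable selection minimizes RMSECV with ties toward fewer", {
  fake <- function(rmsecvs, pcs = seq_along(rmsecvs)) {
    out <- tibble::tibble(n_pc = pcs, rmsecv = rmsecvs,
                          r2 = NA_real_, slope = NA_real_, offset = NA_real_,
                          predictions = list(NULL))
    class(out) <- c("spectrocal_cv", class(out))
    out
  }
  expect_equal(select_pcs(fake(c(0.5, 0.2, 0.3)))$n_pc, 2)
  expect_equal(select_pcs(fake(c(0.4, 0.2, 0.2), pcs = 2:4))$n_pc, 3)
  sel <- select_pcs(fake(c(0.5, 0.4, 0.3)))
  expect_equal(sel$n_pc, 3)
  expect_true(sel$monotone_decreasing)
  expect_false(select_pcs(fake(c(0.5, 0.2, 0.3)))$monotone_decreasing)
})

test_that("LOOCV error vanishes as generator noise goes to zero", {
  lib <- default_library(16L)
  vals <- matrix(0, 14, 9)
  set.seed(16)
  vals[2, ] <- runif(9, 0.5, 2)
  vals[5, ] <- runif(9, 0.1, 1)
  conc <- make_conc(vals)
  best <- sapply(c(0.02, 0.005, 0), function(sigma) {
    nm <- if (sigma == 0) noise_off() else
      noise_model(additive_sd = sigma, baseline_drift_amplitude = 0,
                  scatter_slope_sd = 0, detector_spike_amplitude = 0,
                  saturation_level = Inf, saturation_sd = 0, seed = 2L)
    study <- generate_study(lib, conc, nm, n_replicates = 3)
    M <- spectra_matrix(average_replicates(study))
    min(loocv_calibration(M, vals[2, ], max_pc = 4)$rmsecv)
  })
  expect_true(all(diff(best) < 0))
  expect_lt(best[3], 1e-6)
})

test_that("robust screening flags the study's two concentration outliers", {
  conc <- arnica_concentrations()
  q <- detect_outliers(conc, 11)   # quercetin
  expect_equal(q$sample[q$flagged], "H")
  k <- detect_outliers(conc, 13)   # kaempferol
  expect_equal(k$sample[k$flagged], "G")
  expect_false(any(is.na(q$score)))
  # missing entries are never flagged (H is absent from kaempferol's column)
  expect_false("H" %in% k$sample)
  # constant columns flag nothing
  const <- make_conc(matrix(1, 1, 6))
  expect_false(any(detect_outliers(const, 1)$flagged))
  expect_error(detect_outliers(make_conc(matrix(1, 1, 3)), 1), "at least 4")
})
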