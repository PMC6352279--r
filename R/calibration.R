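#' Column mean-centering of a data matrix
#'
#' Subtracts each wavelength's across-sample mean from every spectrum, so
#' that modeling sees relative rather than absolute reflectance variation.
#' The removed means are stored in the `"column_means"` attribute for
#' back-transformation.
#'
#' @param X Numeric matrix, samples in rows.
#' @return The centered matrix with attribute `column_means`.
#' @export
mean_center <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) abort("mean centering needs at least 2 rows")
  mu <- colMeans(X)
  out <- sweep(X, 2, mu)
  attr(out, "column_means") <- mu
  out
}

#' Undo column mean-centering
#'
#' @param X A matrix produced by [mean_center()] (or any matrix plus means).
#' @param column_means Means to add back; defaults to the stored attribute.
#' @return The uncentered matrix.
#' @export
mean_uncenter <- function(X, column_means = attr(X, "column_means")) {
  if (is.null(column_means)) abort("no column means available")
  out <- sweep(X, 2, column_means, `+`)
  attr(out, "column_means") <- NULL
  out
}

#' Root mean square error of cross-validation
#'
#' `sqrt(sum((y_pred - y)^2) / n)` over left-out predictions, in the units of
#' `y` (mg/g for concentrations).
#'
#' @param y Reference values.
#' @param y_pred Cross-validated predictions, same length.
#' @return A single non-negative number.
#' @examples
#' rmsecv(c(1, 2, 7), c(1, 2, 3))  # sqrt(16/3)
#' @export
rmsecv <- function(y, y_pred) {
  if (length(y) != length(y_pred)) abort("length mismatch between y and y_pred")
  if (length(y) < 1) abort("need at least one prediction")
  sqrt(sum((y_pred - y)^2) / length(y))
}

# Core bilinear fits. X, y are NOT yet centered; returns the coefficient path
# in original (uncentered) space: column k gives the slope vector for a model
# with k latent variables; intercepts follow from the training means.
# Components beyond the effective rank contribute nothing (the path column is
# carried forward unchanged), keeping the noiseless rank-deficient case
# well defined and deterministic.
fit_latent_path <- function(X, y, max_pc, algorithm = c("pls1", "pcr")) {
  algorithm <- match.arg(algorithm)
  n <- nrow(X)
  p <- ncol(X)
  if (max_pc > n - 1) abort("n_pc must be <= n - 1")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  coefs <- matrix(0, p, max_pc)
  xvar <- numeric(max_pc)
  total_ss <- sum(Xc^2)
  tol <- 1e-12
  if (algorithm == "pls1") {
    W <- matrix(0, p, 0)
    P <- matrix(0, p, 0)
    q <- numeric(0)
    Xr <- Xc
    yr <- yc
    used <- 0L
    w_scale <- sqrt(sum((crossprod(Xc, yc))^2)) + tol
    for (a in seq_len(max_pc)) {
      w <- as.numeric(crossprod(Xr, yr))
      nw <- sqrt(sum(w^2))
      if (!is.finite(nw) || nw < tol * w_scale) break
      w <- w / nw
      t_a <- as.numeric(Xr %*% w)
      tt <- sum(t_a^2)
      if (tt < tol * max(total_ss, 1)) break
      p_a <- as.numeric(crossprod(Xr, t_a)) / tt
      q_a <- sum(yr * t_a) / tt
      Xr <- Xr - tcrossprod(t_a, p_a)
      yr <- yr - q_a * t_a
      W <- cbind(W, w)
      P <- cbind(P, p_a)
      q <- c(q, q_a)
      used <- a
      coefs[, a] <- W %*% solve(t(P) %*% W, q)
      xvar[a] <- tt * sum(p_a^2)
    }
    if (used < max_pc && used > 0) {
      for (a in (used + 1):max_pc) {
        coefs[, a] <- coefs[, used]
        xvar[a] <- 0
      }
    }
  } else {
    s <- svd(Xc, nu = min(n, max_pc), nv = min(p, max_pc))
    d <- s$d
    r <- sum(d > tol * max(d, 1))
    k_eff <- min(max_pc, r)
    gamma <- numeric(0)
    for (a in seq_len(max_pc)) {
      if (a <= k_eff) {
        gamma <- c(gamma, sum(s$u[, a] * yc) / d[a])
        coefs[, a] <- s$v[, seq_len(a), drop = FALSE] %*% gamma
        xvar[a] <- d[a]^2
      } else {
        coefs[, a] <- coefs[, max(k_eff, 1)]
        xvar[a] <- 0
      }
    }
  }
  list(coefs = coefs, x_mean = x_mean, y_mean = y_mean,
       algorithm = algorithm,
       x_variance_explained = if (total_ss > 0) xvar / total_ss else xvar * 0)
}

#' Fit a latent-variable calibration model for one component
#'
#' Mean-centers the training spectra and concentrations, fits either a PLS1
#' (NIPALS) or principal-component regression model with `n_pc` latent
#' variables, and stores the coefficient vector in the original (uncentered)
#' variable space. `n_pc = 0` is the null model predicting the training mean.
#' Rows with missing `y` are excluded before fitting. The fit is fully
#' deterministic.
#'
#' @param X Numeric sample-by-wavelength matrix (see [spectra_matrix()]).
#' @param y Concentration vector (mg/g), one value per row of `X`; `NA`
#'   values drop the row.
#' @param n_pc Number of latent variables, `0 <= n_pc <= n - 1`.
#' @param algorithm `"pls1"` (default) or `"pcr"`.
#' @return An object of class `calibration_model`.
#' @export
fit_calibration <- function(X, y, n_pc, algorithm = c("pls1", "pcr")) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(X)
  if (n < 2) abort("need at least 2 samples with reference values")
  if (n_pc < 0 || n_pc > n - 1) abort("n_pc must be between 0 and n - 1")
  if (n_pc >= 1 && sd(y) == 0) abort("zero-variance y")
  if (n_pc == 0) {
    fit <- list(coefs = matrix(0, ncol(X), 1), x_mean = colMeans(X),
                y_mean = mean(y), algorithm = algorithm,
                x_variance_explained = numeric(0))
    beta <- fit$coefs[, 1]
  } else {
    fit <- fit_latent_path(X, y, n_pc, algorithm)
    beta <- fit$coefs[, n_pc]
  }
  structure(list(
    coefficients = beta,
    intercept = fit$y_mean - sum(fit$x_mean * beta),
    n_pc = as.integer(n_pc),
    algorithm = algorithm,
    x_mean = fit$x_mean,
    y_mean = fit$y_mean,
    x_variance_explained = fit$x_variance_explained,
    n = n,
    wavelengths = if (is.null(colnames(X))) seq_len(ncol(X)) else
      suppressWarnings(as.numeric(colnames(X)))
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> ", x$algorithm, " with ", x$n_pc,
      " latent variable(s), ", x$n, " training samples, ",
      length(x$coefficients), " wavelengths\n", sep = "")
  invisible(x)
}

#' Predict concentrations from spectra
#'
#' @param object A `calibration_model`.
#' @param newdata Matrix (or vector) of spectra in the model's variable space.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (mg/g).
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  as.numeric(newdata %*% object$coefficients + object$intercept)
}

#' Tidy the coefficient vector of a calibration model
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return A tibble with `wavelength_nm` and `coefficient`.
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(wavelength_nm = x$wavelengths, coefficient = x$coefficients)
}

#' One-row model summary of a calibration model
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return A one-row tibble with the algorithm, latent-variable count,
#'   training size and cumulative explained spectral variance.
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_pc = x$n_pc,
    n = x$n,
    x_variance_explained = sum(x$x_variance_explained)
  )
}

cv_stats <- function(y, y_pred) {
  r2 <- if (sd(y_pred) == 0 || sd(y) == 0) NA_real_ else cor(y, y_pred)^2
  # least-squares line of predicted on reference
  slope <- if (sd(y) == 0) NA_real_ else
    sum((y - mean(y)) * (y_pred - mean(y_pred))) / sum((y - mean(y))^2)
  offset <- if (is.na(slope)) NA_real_ else mean(y_pred) - slope * mean(y)
  list(r2 = r2, slope = slope, offset = offset)
}

#' Leave-one-out cross-validation across latent-variable counts
#'
#' For each number of latent variables from 1 to `max_pc`, each sample is
#' left out in turn, the model (including the column means used for
#' centering) is recomputed from the remaining samples only, and the left-out
#' sample is predicted; no information from the held-out row enters the fit.
#' Per latent-variable count the function records RMSECV, the squared
#' correlation between cross-validated predictions and reference values, and
#' the slope/offset of the predicted-versus-reference least-squares line.
#'
#' @inheritParams fit_calibration
#' @param max_pc Largest latent-variable count; defaults to `n - 2` and is
#'   clipped to it (with a warning) when infeasible, since each training fold
#'   holds `n - 1` samples and centering consumes one degree of freedom.
#' @return A tibble of class `spectrocal_cv` with one row per latent-variable
#'   count: `n_pc`, `rmsecv`, `r2`, `slope`, `offset` and a `predictions`
#'   list-column of per-sample tibbles. The full-data explained-variance
#'   profile is stored in the `"variance_profile"` attribute.
#' @export
loocv_calibration <- function(X, y, max_pc = NULL,
                              algorithm = c("pls1", "pcr")) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  ids <- ids[keep]
  n <- nrow(X)
  if (n < 3) abort("leave-one-out cross-validation needs at least 3 samples")
  feasible <- n - 2L
  max_pc <- as.integer(max_pc %||% feasible)
  if (max_pc > feasible) {
    warn(paste0("max_pc = ", max_pc, " infeasible with n = ", n,
                "; clipped to ", feasible))
    max_pc <- feasible
  }
  if (max_pc < 1) abort("max_pc must be >= 1")
  pred <- matrix(NA_real_, n, max_pc)
  for (i in seq_len(n)) {
    fit <- fit_latent_path(X[-i, , drop = FALSE], y[-i], max_pc, algorithm)
    for (k in seq_len(max_pc)) {
      beta <- fit$coefs[, k]
      pred[i, k] <- sum(X[i, ] * beta) + fit$y_mean - sum(fit$x_mean * beta)
    }
  }
  full_fit <- fit_latent_path(X, y, max_pc, algorithm)
  out <- purrr::map_dfr(seq_len(max_pc), function(k) {
    st <- cv_stats(y, pred[, k])
    tibble::tibble(
      n_pc = k,
      rmsecv = rmsecv(y, pred[, k]),
      r2 = st$r2,
      slope = st$slope,
      offset = st$offset,
      predictions = list(tibble::tibble(sample = ids, y = y,
                                        y_pred = pred[, k]))
    )
  })
  class(out) <- c("spectrocal_cv", class(out))
  attr(out, "algorithm") <- algorithm
  attr(out, "n") <- n
  attr(out, "variance_profile") <- full_fit$x_variance_explained
  out
}

#' Select the number of latent variables from cross-validation results
#'
#' Chooses the latent-variable count minimizing RMSECV, breaking ties toward
#' fewer latent variables (favoring the simplest model that describes the
#' cross-validated variation). When RMSECV decreases strictly monotonically
#' up to `max_pc` the choice sits on the search boundary and may be
#' under-smoothed; this is flagged in `monotone_decreasing`.
#'
#' @param cv A `spectrocal_cv` tibble from [loocv_calibration()].
#' @param variance_profile Optional explained-spectral-variance profile;
#'   defaults to the one stored on `cv`.
#' @return A one-row tibble: `n_pc`, `rmsecv`, `r2`, `slope`, `offset`,
#'   `monotone_decreasing`, with the variance profile attached as the
#'   `"variance_profile"` attribute.
#' @export
select_pcs <- function(cv, variance_profile = attr(cv, "variance_profile")) {
  if (nrow(cv) == 0) abort("no cross-validation results")
  best <- which.min(cv$rmsecv)  # which.min already breaks ties to the first
  out <- tibble::tibble(
    n_pc = cv$n_pc[best],
    rmsecv = cv$rmsecv[best],
    r2 = cv$r2[best],
    slope = cv$slope[best],
    offset = cv$offset[best],
    monotone_decreasing = all(diff(cv$rmsecv) < 0)
  )
  attr(out, "variance_profile") <- variance_profile
  out
}

#' Robust screening for concentration outliers
#'
#' Flags samples whose concentration of one component deviates from the
#' component's median by more than `threshold` robust standard deviations,
#' using the scaled median absolute deviation (`MAD * 1.4826`) as the robust
#' scale. Samples with missing concentrations are never flagged; a constant
#' column flags nothing. Flagged samples are meant to be excluded from that
#' component's calibration set only, since a single extreme sample distorts
#' the linearity of a small calibration.
#'
#' @param conc A concentration tibble (see [read_concentration_table()]).
#' @param component Component index to screen.
#' @param threshold Robust z-score cutoff. The default 5 reproduces the
#'   study's screening outcome on the packaged reference table: quercetin
#'   flags exactly sample H and kaempferol exactly sample G, with no flags in
#'   any other component.
#' @return A tibble of class `outlier_report` with columns `sample`,
#'   `concentration_mg_g`, `score`, `flagged`; the component and threshold
#'   are stored as attributes.
#' @export
detect_outliers <- function(conc, component, threshold = 5) {
  rows <- conc[conc$component_index == component &
                 !is.na(conc$concentration_mg_g), ]
  if (nrow(rows) < 4) {
    abort("outlier screening needs at least 4 non-missing values")
  }
  x <- rows$concentration_mg_g
  med <- median(x)
  scale <- mad(x)  # stats::mad already includes the 1.4826 consistency factor
  dev <- abs(x - med)
  score <- if (scale == 0) ifelse(dev == 0, 0, Inf) else dev / scale
  out <- tibble::tibble(
    sample = rows$sample,
    concentration_mg_g = x,
    score = score,
    flagged = score > threshold
  )
  class(out) <- c("outlier_report", class(out))
  attr(out, "component_index") <- component
  attr(out, "component_name") <- rows$component_name[1]
  attr(out, "threshold") <- threshold
  out
}
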