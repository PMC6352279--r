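test_that("Savitzky-Golay weights match a brute-force least-squares solve", {
  # 5-point quadratic smoother, solved here by explicit polynomial regression
  brute <- function(m, d, k) {
    x <- (-m):m
    A <- outer(x, 0:d, `^`)
    w <- numeric(2 * m + 1)
    for (i in seq_along(x)) {
      e <- numeric(2 * m + 1); e[i] <- 1
      beta <- qr.solve(A, e)        # fit to an impulse at point i
      w[i] <- factorial(k) * beta[k + 1]
    }
    w
  }
  expect_equal(gs_coefficients(2, 2, 0), c(-3, 12, 17, 12, -3) / 35)
  expect_equal(gs_coefficients(2, 2, 0), brute(2, 2, 0))
  expect_equal(gs_coefficients(5, 3, 1), brute(5, 3, 1))
  for (m in c(2, 5, 10)) {
    expect_equal(sum(gs_coefficients(m, 2, 0)), 1)           # preserves constants
    w1 <- gs_coefficients(m, 2, 1)
    expect_equal(sum(w1), 0)                                 # annihilates constants
    expect_equal(w1, -rev(w1))                               # antisymmetric
  }
  expect_error(gs_coefficients(1, 4, 1), "too small")
})

test_that("Savitzky-Golay weights agree with the signal package", {
  skip_if_not_installed("signal")
  for (m in c(2, 5, 10)) for (d in c(2, 3)) {
    ref <- signal::sgolay(p = d, n = 2 * m + 1, m = 1)[m + 1, ]
    expect_equal(gs_coefficients(m, d, 1), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("the symmetric filter reproduces polynomial derivatives and loses m points per end", {
  s <- linear_spectrum(slope = 2.5, from = 400, to = 500)
  d <- gs_first_derivative(s, window = 5, degree = 2)
  expect_equal(d$value, rep(2.5, 101 - 10))
  expect_equal(nrow(d), nrow(s) - 2 * 5)
  expect_equal(range(d$wavelength_nm), c(405, 495))
  # quadratic: exact at degree 2 for any half-window
  x <- seq(300, 420)
  q <- make_spectrum(x, 1 + 0.02 * x - 3e-4 * x^2)
  for (m in c(2, 7, 12)) {
    dq <- gs_first_derivative(q, window = m, degree = 2)
    expect_equal(dq$value, 0.02 - 6e-4 * dq$wavelength_nm, tolerance = 1e-9)
  }
  expect_error(gs_first_derivative(linear_spectrum(1, from = 400, to = 410),
                                   window = 5, degree = 2), "shorter")
})

test_that("the symmetric filter tracks a smooth analytic derivative", {
  x <- seq(0, 2000)
  s <- make_spectrum(x, sin(2 * pi * x / 400))
  d <- gs_first_derivative(s, window = 5, degree = 2)
  truth <- (2 * pi / 400) * cos(2 * pi * d$wavelength_nm / 400)
  expect_lt(max(abs(d$value - truth)), 1e-3 * (2 * pi / 400))
})

test_that("the forward filter loses points only at the red end and is exact on cubics", {
  s <- linear_spectrum(slope = -1.25, from = 500, to = 600)
  d <- sbsf_first_derivative(s)  # window 2, degree 3
  expect_equal(d$value, rep(-1.25, nrow(d)))
  expect_equal(d$wavelength_nm[1], s$wavelength_nm[1])       # blue end preserved
  expect_lt(max(d$wavelength_nm), max(s$wavelength_nm))      # red-end loss
  expect_equal(nrow(d), nrow(s) - (3 + 2 - 1))
  x <- seq(300, 400)
  cubic <- make_spectrum(x, 2 + 0.01 * x - 3e-4 * x^2 + 5e-7 * x^3)
  dc <- sbsf_first_derivative(cubic, window = 2, degree = 3)
  truth <- 0.01 - 6e-4 * dc$wavelength_nm + 1.5e-6 * dc$wavelength_nm^2
  expect_lt(max(abs(dc$value - truth)) / max(abs(truth)), 1e-8)
  expect_error(sbsf_first_derivative(make_spectrum(1:4, rnorm(4))), "footprint")
})

test_that("filters are linear and act per contiguous segment", {
  set.seed(21)
  wl <- seq(300, 500)
  f1 <- rnorm(length(wl)); f2 <- rnorm(length(wl))
  sA <- make_spectrum(wl, f1); sB <- make_spectrum(wl, f2)
  sMix <- make_spectrum(wl, 2 * f1 - 3 * f2)
  for (spec in list(filter_spec("gs", 5, 2), filter_spec("sbsf", 2, 3))) {
    dA <- derive_spectra(sA, spec); dB <- derive_spectra(sB, spec)
    dMix <- derive_spectra(sMix, spec)
    expect_equal(dMix$value, 2 * dA$value - 3 * dB$value, tolerance = 1e-10)
  }
  # two segments: point loss applies to each independently
  gap <- dplyr::filter(make_spectrum(seq(300, 500), seq(300, 500) * 2),
                       wavelength_nm <= 380 | wavelength_nm >= 420)
  dg <- gs_first_derivative(gap, window = 5, degree = 2)
  expect_equal(nrow(dg), (81 - 10) + (81 - 10))
  expect_equal(unique(round(dg$value, 10)), 2)
  ds <- sbsf_first_derivative(gap)
  expect_true(300 %in% ds$wavelength_nm && 420 %in% ds$wavelength_nm)
  expect_false(380 %in% ds$wavelength_nm || 500 %in% ds$wavelength_nm)
})

test_that("wider symmetric windows attenuate a narrow derivative extremum more", {
  x <- seq(1000, 1200)
  band <- make_spectrum(x, exp(-(x - 1100)^2 / (2 * 4^2)))  # narrower than windows
  peaks <- sapply(c(2, 5, 10, 15), function(m) {
    max(abs(gs_first_derivative(band, window = m, degree = 2)$value))
  })
  expect_true(all(diff(peaks) < 0))
})

test_that("filtered derivatives beat naive differencing under white noise", {
  x <- seq(0, 600)
  truth <- make_spectrum(x, 0.5 * x)
  truth_deriv <- rep(0.5, length(x))
  # zero noise on a linear signal: both estimators exact, ratio 1
  expect_equal(snr_gain(truth, truth, filter_spec("gs", 5, 2), truth_deriv), 1)
  set.seed(33)
  gains <- replicate(100, {
    noisy <- make_spectrum(x, truth$value + rnorm(length(x), sd = 0.05))
    snr_gain(noisy, truth, filter_spec("gs", 5, 2), truth_deriv)
  })
  expect_gt(min(gains), 1)
  # gain grows with the half-window on white noise over a linear truth
  set.seed(34)
  mean_gain <- sapply(c(2, 5, 7), function(m) {
    mean(replicate(40, {
      noisy <- make_spectrum(x, truth$value + rnorm(length(x), sd = 0.05))
      snr_gain(noisy, truth, filter_spec("gs", m, 2), truth_deriv)
    }))
  })
  expect_true(all(diff(mean_gain) > 0))
})
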