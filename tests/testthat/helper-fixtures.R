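# Builders for small in-code fixtures shared across test files.

make_spectrum <- function(wavelengths, values, sample = "A", replicate = 1L) {
  tibble::tibble(sample = sample, replicate = as.integer(replicate),
                 wavelength_nm = wavelengths, value = values)
}

linear_spectrum <- function(slope, intercept = 0, from = 400, to = 500,
                            sample = "A", replicate = 1L) {
  wl <- seq(from, to)
  make_spectrum(wl, intercept + slope * wl, sample, replicate)
}

# A tiny concentration table: `values` is a component-by-sample matrix
# (NA = missing), samples labelled A, B, ...
make_conc <- function(values, names = NULL) {
  values <- as.matrix(values)
  samples <- LETTERS[seq_len(ncol(values))]
  names <- names %||% paste0("component ", seq_len(nrow(values)))
  purrr::map_dfr(seq_len(nrow(values)), function(i) {
    tibble::tibble(component_index = i, component_name = names[i],
                   sample = samples, concentration_mg_g = values[i, ],
                   sd = NA_real_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force leave-one-out oracle: one fresh model per (fold, n_pc) pair.
naive_loocv <- function(X, y, max_pc, algorithm = "pls1") {
  n <- length(y)
  purrr::map_dfr(seq_len(max_pc), function(k) {
    pred <- vapply(seq_len(n), function(i) {
      fit <- fit_calibration(X[-i, , drop = FALSE], y[-i], k, algorithm)
      predict(fit, X[i, , drop = FALSE])
    }, numeric(1))
    tibble::tibble(n_pc = k, rmsecv = rmsecv(y, pred), pred = list(pred))
  })
}
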