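#' Derivative-filter configuration
#'
#' Bundles the preprocessing choice: the method (`"gs"` for the symmetric
#' Savitzky-Golay convolution filter, `"sbsf"` for the forward step-by-step
#' filter, `"none"` for untreated spectra), the filter window parameter (in
#' points), the fitted polynomial degree, and the derivative order (fixed at
#' 1 in this package). Method defaults follow the settings used for the
#' Arnicae flos calibration: window 10, degree 2 for `gs`; window 2, degree 3
#' for `sbsf`.
#'
#' For `gs` the window parameter is interpreted as the HALF-window `m`, i.e.
#' a `2m + 1`-point convolution footprint losing `m` points at each end of a
#' contiguous segment (see [gs_half_window()]). For `sbsf` the footprint is
#' `degree + window` forward points, losing `degree + window - 1` points at
#' the red (long-wavelength) end only.
#'
#' @param method One of `"gs"`, `"sbsf"`, `"none"`.
#' @param window Positive integer filter-window parameter, in points.
#' @param degree Polynomial degree (`>= deriv_order`).
#' @param deriv_order Derivative order; only 1 is supported.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(method = c("gs", "sbsf", "none"),
                        window = NULL, degree = NULL, deriv_order = 1L) {
  method <- match.arg(method)
  if (method == "gs") {
    window <- window %||% 10L
    degree <- degree %||% 2L
  } else if (method == "sbsf") {
    window <- window %||% 2L
    degree <- degree %||% 3L
  } else {
    window <- window %||% 0L
    degree <- degree %||% 0L
  }
  if (deriv_order != 1L && method != "none") {
    abort("only first derivatives are supported")
  }
  if (method != "none") {
    if (window < 1) abort("window must be >= 1")
    if (degree < deriv_order) abort("degree must be >= deriv_order")
  }
  structure(list(method = method, window = as.integer(window),
                 degree = as.integer(degree),
                 deriv_order = as.integer(deriv_order)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec> method=", x$method,
      " window=", x$window, " degree=", x$degree,
      " deriv_order=", x$deriv_order, "\n", sep = "")
  invisible(x)
}

#' Map the Savitzky-Golay window parameter to its half-window
#'
#' The reported "filter window = 10 points" is read as the half-window `m`,
#' giving a `2m + 1`-point convolution. The alternative reading (a total
#' footprint of 10 points) would make the symmetric point-loss formula
#' `(window - 1) / 2` non-integer; the mapping is isolated here so that
#' reading would be a one-line change.
#'
#' @param window The filter-window parameter of a `filter_spec`.
#' @return The half-window `m` (integer).
#' @export
gs_half_window <- function(window) {
  as.integer(window)
}

#' Savitzky-Golay convolution weights
#'
#' Weights of the least-squares polynomial convolution filter on a unit grid:
#' fitting a degree-`degree` polynomial to the `2m + 1` points at offsets
#' `-m..m` and taking the `deriv_order`-th derivative of the fit at the
#' center is a fixed linear combination of the samples; this returns those
#' weights. At application time the result is scaled by the grid step raised
#' to the derivative order.
#'
#' @param half_window Half-window `m`; footprint is `2m + 1` points.
#' @param degree Polynomial degree, `2m + 1 > degree >= deriv_order`.
#' @param deriv_order Derivative order `k >= 0`.
#' @return Numeric weight vector of length `2m + 1` (offsets `-m..m`).
#' @examples
#' gs_coefficients(2, 2, 0)  # the classic 5-point quadratic smoother /35
#' @export
gs_coefficients <- function(half_window, degree, deriv_order = 1L) {
  m <- as.integer(half_window)
  d <- as.integer(degree)
  k <- as.integer(deriv_order)
  if (m < 1) abort("half_window must be >= 1")
  if (k < 0 || d < k) abort("need degree >= deriv_order >= 0")
  if (2 * m + 1 <= d) abort("window too small for polynomial degree")
  x <- (-m):m
  A <- outer(x, 0:d, `^`)
  # derivative of the fitted polynomial at 0: k! * row (k+1) of (A'A)^-1 A'
  pinv <- solve(crossprod(A), t(A))
  factorial(k) * pinv[k + 1, ]
}

#' Forward (step-by-step) derivative filter weights
#'
#' Weights of the one-sided first-derivative filter: a degree-`degree`
#' polynomial is least-squares fitted to the `degree + window` forward points
#' at offsets `0..(degree + window - 1)` and its derivative taken at the left
#' edge (offset 0). Equivalently, a fixed weighted combination of forward
#' differences. Because the footprint extends only toward longer wavelengths,
#' all point loss accrues at the red end of a segment.
#'
#' @param window Window parameter (extra points beyond the `degree + 1`
#'   minimum is `window - 1`); footprint is `degree + window` points.
#' @param degree Polynomial degree.
#' @return Numeric weight vector of length `degree + window` (offsets
#'   `0..degree+window-1`).
#' @export
sbsf_coefficients <- function(window, degree) {
  w <- as.integer(window)
  d <- as.integer(degree)
  if (w < 1) abort("window must be >= 1")
  if (d < 1) abort("degree must be >= 1 for a first derivative")
  npts <- d + w
  x <- 0:(npts - 1)
  A <- outer(x, 0:d, `^`)
  pinv <- solve(crossprod(A), t(A))
  pinv[2, ]
}

split_segments <- function(wl, tol = 1e-6) {
  d <- diff(wl)
  step <- min(d)
  breaks <- which(d > step * (1 + 0.5))
  start <- c(1, breaks + 1)
  end <- c(breaks, length(wl))
  lapply(seq_along(start), function(i) start[i]:end[i])
}

check_uniform <- function(wl) {
  d <- diff(wl)
  if (max(d) - min(d) > 1e-9 * max(abs(d))) {
    abort("segment grid is not uniform")
  }
  d[1]
}

apply_conv <- function(f, w) {
  k <- length(w)
  E <- stats::embed(f, k)     # row i = f[i+k-1], ..., f[i]
  as.numeric(E %*% rev(w))
}

derive_one <- function(wl, v, spec) {
  segs <- split_segments(wl)
  out_wl <- numeric(0)
  out_v <- numeric(0)
  for (idx in segs) {
    swl <- wl[idx]
    sv <- v[idx]
    if (spec$method == "gs") {
      m <- gs_half_window(spec$window)
      if (length(sv) <= 2 * m + 1) {
        abort("spectrum segment shorter than filter window")
      }
      step <- check_uniform(swl)
      w <- gs_coefficients(m, spec$degree, 1L)
      dv <- apply_conv(sv, w) / step
      out_wl <- c(out_wl, swl[(m + 1):(length(swl) - m)])
      out_v <- c(out_v, dv)
    } else if (spec$method == "sbsf") {
      w <- sbsf_coefficients(spec$window, spec$degree)
      loss <- length(w) - 1L
      if (length(sv) <= length(w)) {
        abort("spectrum segment shorter than the forward footprint")
      }
      step <- check_uniform(swl)
      dv <- apply_conv(sv, w) / step
      out_wl <- c(out_wl, swl[1:(length(swl) - loss)])
      out_v <- c(out_v, dv)
    } else {
      out_wl <- c(out_wl, swl)
      out_v <- c(out_v, sv)
    }
  }
  list(wavelength_nm = out_wl, value = out_v)
}

#' First-derivative preprocessing of spectra
#'
#' Applies the configured derivative filter to every spectrum, separately on
#' each contiguous constant-step segment of its grid (trimming creates gaps,
#' e.g. around the 900 nm detector switch). Output values are in reflectance
#' per nm. `method = "none"` returns the input unchanged. The symmetric
#' Savitzky-Golay filter loses `m` points at each segment end; the forward
#' step-by-step filter loses its whole footprint minus one point at the red
#' end only, so a segment's first wavelength is preserved.
#'
#' @param spectra A spectra table.
#' @param spec A [filter_spec()].
#' @return A spectra tibble of derivative values, with the filter recorded in
#'   the `"filter_spec"` attribute.
#' @export
derive_spectra <- function(spectra, spec = filter_spec("gs")) {
  spectra <- as_spectra(spectra)
  out <- spectra |>
    dplyr::group_by(.data$sample, .data$replicate) |>
    dplyr::group_modify(function(g, key) {
      r <- derive_one(g$wavelength_nm, g$value, spec)
      tibble::tibble(wavelength_nm = r$wavelength_nm, value = r$value)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("sample", "replicate", "wavelength_nm", "value")
  attr(out, "filter_spec") <- spec
  out
}

#' Convenience wrapper: Savitzky-Golay first derivative
#'
#' @inheritParams derive_spectra
#' @param window Half-window parameter (see [gs_half_window()]).
#' @param degree Polynomial degree.
#' @return A derivative spectra tibble.
#' @export
gs_first_derivative <- function(spectra, window = 10L, degree = 2L) {
  derive_spectra(spectra, filter_spec("gs", window = window, degree = degree))
}

#' Convenience wrapper: step-by-step (forward) first derivative
#'
#' @inheritParams derive_spectra
#' @param window Window parameter.
#' @param degree Polynomial degree.
#' @return A derivative spectra tibble.
#' @export
sbsf_first_derivative <- function(spectra, window = 2L, degree = 3L) {
  derive_spectra(spectra, filter_spec("sbsf", window = window, degree = degree))
}

#' Signal-to-noise gain of a derivative filter
#'
#' Compares the filtered derivative of a noisy spectrum against naive
#' two-point forward differencing, both scored by RMS error relative to the
#' derivative of the clean signal. Values above 1 mean the filter improves
#' the derivative-domain signal-to-noise ratio.
#'
#' @param noisy Single noisy spectrum (spectra table with one spectrum).
#' @param truth The clean signal on the same grid.
#' @param spec A [filter_spec()].
#' @param truth_deriv Optional numeric vector: the exact derivative of the
#'   clean signal on the `truth` grid. If omitted, it is estimated from
#'   `truth` with a wide high-order Savitzky-Golay filter, which is accurate
#'   for smooth signals.
#' @return The RMS-error ratio (naive / filtered), a single number.
#' @export
snr_gain <- function(noisy, truth, spec, truth_deriv = NULL) {
  noisy <- as_spectra(noisy)
  truth <- as_spectra(truth)
  if (!isTRUE(all.equal(noisy$wavelength_nm, truth$wavelength_nm))) {
    abort("noisy and truth spectra must share a grid")
  }
  wl <- truth$wavelength_nm
  step <- check_uniform(wl)
  if (is.null(truth_deriv)) {
    m_ref <- min(8L, (length(wl) - 1L) %/% 2L)
    w_ref <- gs_coefficients(m_ref, min(7L, 2L * m_ref - 1L), 1L)
    inner <- (m_ref + 1):(length(wl) - m_ref)
    truth_deriv <- rep(NA_real_, length(wl))
    truth_deriv[inner] <- apply_conv(truth$value, w_ref) / step
  }
  if (length(truth_deriv) != length(wl)) {
    abort("truth_deriv must match the grid length")
  }
  # naive two-point forward difference, assigned to the left point
  naive <- diff(noisy$value) / step
  naive_ref <- truth_deriv[seq_len(length(wl) - 1)]
  ok_n <- is.finite(naive_ref)
  rms_naive <- sqrt(mean((naive[ok_n] - naive_ref[ok_n])^2))
  filt <- derive_spectra(noisy, spec)
  idx <- match(filt$wavelength_nm, wl)
  filt_ref <- truth_deriv[idx]
  ok_f <- is.finite(filt_ref)
  rms_filt <- sqrt(mean((filt$value[ok_f] - filt_ref[ok_f])^2))
  # both estimators exact up to roundoff (e.g. polynomial truth, no noise)
  eps <- 1e-12 * max(max(abs(truth_deriv[is.finite(truth_deriv)])), 1)
  if (rms_filt < eps && rms_naive < eps) return(1)
  rms_naive / rms_filt
}
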