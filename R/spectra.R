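#' Validate a tidy table of reflectance spectra
#'
#' A spectra table is a long tibble with one row per measured point and the
#' columns `sample` (character label, e.g. `"A"`), `replicate` (integer),
#' `wavelength_nm` (numeric, nm) and `value` (reflectance, arbitrary units).
#' Within each `(sample, replicate)` pair the wavelength grid must be strictly
#' increasing and all values finite.
#'
#' @param x A data frame in the long spectra layout.
#' @param harmonized If `TRUE`, additionally require every spectrum to share
#'   an identical wavelength grid.
#' @return `x`, invisibly coerced to a tibble, after validation.
#' @export
as_spectra <- function(x, harmonized = FALSE) {
  required <- c("sample", "replicate", "wavelength_nm", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("spectra table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  x$sample <- as.character(x$sample)
  x$replicate <- as.integer(x$replicate)
  if (anyNA(x$wavelength_nm) || any(!is.finite(x$value))) {
    abort("spectra contain non-finite wavelengths or values")
  }
  bad <- x |>
    dplyr::group_by(.data$sample, .data$replicate) |>
    dplyr::summarise(ok = !is.unsorted(.data$wavelength_nm, strictly = TRUE),
                     .groups = "drop")
  if (any(!bad$ok)) {
    who <- bad[!bad$ok, ]
    abort(paste0("non-monotone grid in spectrum ",
                 who$sample[1], "_", who$replicate[1]))
  }
  if (harmonized) {
    grids <- x |>
      dplyr::group_by(.data$sample, .data$replicate) |>
      dplyr::summarise(key = paste(.data$wavelength_nm, collapse = ","),
                       .groups = "drop")
    if (length(unique(grids$key)) > 1) {
      abort("spectra do not share a common wavelength grid")
    }
  }
  x
}

#' Construct a set of retained wavelength regions
#'
#' Regions are closed intervals `[lo, hi]` in nm, used to cut away spectral
#' ranges dominated by artifacts (detector switch near 900 nm, UV saturation
#' below 270 nm). Intervals must be sorted, non-overlapping and satisfy
#' `lo <= hi`.
#'
#' @param ... Numeric vectors of length 2, one per interval, in nm.
#' @return A tibble with columns `lo_nm` and `hi_nm`.
#' @examples
#' spectral_regions(c(270, 850), c(907, 2000))
#' @export
spectral_regions <- function(...) {
  ivs <- list(...)
  if (length(ivs) == 0) abort("at least one interval is required")
  m <- do.call(rbind, lapply(ivs, function(iv) {
    if (length(iv) != 2 || !is.numeric(iv)) {
      abort("each interval must be a numeric vector c(lo, hi)")
    }
    iv
  }))
  out <- tibble::tibble(lo_nm = m[, 1], hi_nm = m[, 2])
  if (any(out$lo_nm > out$hi_nm)) abort("interval with lo > hi")
  if (is.unsorted(out$lo_nm, strictly = TRUE) && nrow(out) > 1) {
    abort("intervals must be sorted ascending")
  }
  if (nrow(out) > 1 && any(out$lo_nm[-1] <= out$hi_nm[-nrow(out)])) {
    abort("intervals overlap")
  }
  out
}

#' Default retained wavelength regions per preprocessing method
#'
#' The retained intervals used throughout the workflow: `270-850` and
#' `907-2000` nm for untreated (zero-order) spectra, and the narrower
#' post-derivative windows `270-850` plus `935-1920` nm (Savitzky-Golay) or
#' `935-1980` nm (step-by-step filter), which additionally absorb the points
#' each filter consumes at segment edges.
#'
#' @param method One of `"none"`, `"gs"`, `"sbsf"`.
#' @return A regions tibble as produced by [spectral_regions()].
#' @export
default_regions <- function(method = c("none", "gs", "sbsf")) {
  method <- match.arg(method)
  switch(method,
    none = spectral_regions(c(270, 850), c(907, 2000)),
    gs   = spectral_regions(c(270, 850), c(935, 1920)),
    sbsf = spectral_regions(c(270, 850), c(935, 1980))
  )
}

#' Trim spectra to a set of retained wavelength regions
#'
#' Keeps exactly those grid points lying inside some closed interval of
#' `regions`; point order is preserved. Intervals are closed on both ends, so
#' a point at 850 nm is retained by `[270, 850]` while 851 nm is not.
#'
#' @param spectra A spectra table (see [as_spectra()]).
#' @param regions A regions tibble from [spectral_regions()].
#' @return The trimmed spectra table.
#' @export
trim_regions <- function(spectra, regions) {
  spectra <- as_spectra(spectra)
  keep <- rep(FALSE, nrow(spectra))
  for (i in seq_len(nrow(regions))) {
    keep <- keep | (spectra$wavelength_nm >= regions$lo_nm[i] &
                    spectra$wavelength_nm <= regions$hi_nm[i])
  }
  out <- spectra[keep, , drop = FALSE]
  if (nrow(out) == 0) abort("regions exclude all points")
  out
}

#' Average replicate spectra within each sample
#'
#' Replicates of a sample must share an identical wavelength grid; the
#' averaged value at each wavelength is the arithmetic mean over replicates.
#' Averaging replicate scans suppresses the between-replicate variation caused
#' by inhomogeneous packing of the powdered material.
#'
#' @param spectra A spectra table.
#' @return A spectra table with a single spectrum (`replicate = 1`) per sample.
#' @export
average_replicates <- function(spectra) {
  spectra <- as_spectra(spectra)
  grids <- spectra |>
    dplyr::group_by(.data$sample, .data$replicate) |>
    dplyr::summarise(key = paste(.data$wavelength_nm, collapse = ","),
                     .groups = "drop") |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_grids = dplyr::n_distinct(.data$key), .groups = "drop")
  if (any(grids$n_grids > 1)) {
    abort(paste0("replicates of sample ",
                 grids$sample[grids$n_grids > 1][1],
                 " have mismatched grids"))
  }
  spectra |>
    dplyr::group_by(.data$sample, .data$wavelength_nm) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(replicate = 1L) |>
    dplyr::select("sample", "replicate", "wavelength_nm", "value") |>
    dplyr::arrange(.data$sample, .data$wavelength_nm)
}

#' Assemble the sample-by-wavelength data matrix
#'
#' Expects one spectrum per sample (average replicates first) on a common
#' grid, and returns the `n x p` matrix used for calibration, with samples as
#' named rows and wavelengths as named columns.
#'
#' @param spectra A spectra table with one replicate per sample.
#' @return A numeric matrix, `rownames` = sample labels, `colnames` =
#'   wavelengths in nm.
#' @export
spectra_matrix <- function(spectra) {
  spectra <- as_spectra(spectra, harmonized = TRUE)
  reps <- spectra |>
    dplyr::distinct(.data$sample, .data$replicate) |>
    dplyr::count(.data$sample)
  if (any(reps$n > 1)) {
    abort("multiple replicates per sample; call average_replicates() first")
  }
  wide <- spectra |>
    dplyr::arrange(.data$sample, .data$wavelength_nm) |>
    tidyr::pivot_wider(id_cols = "sample",
                       names_from = "wavelength_nm",
                       values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  storage.mode(m) <- "double"
  m
}
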