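#' Spectral band library for the synthetic reflectance generator
#'
#' Builds the component library used to simulate diffuse-reflectance spectra
#' of powdered Arnicae flos. The shared background carries the morphology of
#' the measured raw curves: three broad NIR bands centered at 1920, 1720 and
#' 1450 nm (water/CH overtone and combination regions), two visible bands at
#' 650 nm (orange petal pigments) and 500 nm (green involucral bracts), and a
#' steep UV edge below ~270 nm that drives the detector into saturation. Each
#' of the 14 quantified components additionally receives 2-4 reproducibly
#' pseudo-random narrow Gaussian bands in 300-1980 nm whose amplitudes scale
#' linearly with concentration (mg/g).
#'
#' @param seed Integer seed; the same seed yields a bitwise-identical library.
#' @param n_components Number of concentration-driven components (default 14).
#' @return An object of class `component_library`: a list with elements
#'   `base_level` (constant reflectance offset), `background` (tibble of
#'   Gaussian bands: `center_nm`, `width_nm`, `amplitude`) and `components`
#'   (tibble keyed by `component_index` with per-band amplitude in
#'   reflectance units per mg/g).
#' @export
default_library <- function(seed = 1L, n_components = 14L) {
  background <- tibble::tibble(
    center_nm = c(250, 500, 650, 1450, 1720, 1920),
    width_nm  = c(15, 45, 55, 70, 75, 60),
    amplitude = c(1.5, 0.25, 0.30, 0.45, 0.40, 0.50)
  )
  components <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_components), function(j) {
      n_bands <- sample(2:4, 1)
      tibble::tibble(
        component_index = as.integer(j),
        center_nm = runif(n_bands, 300, 1980),
        width_nm = runif(n_bands, 10, 30),
        amplitude = runif(n_bands, 0.015, 0.04)
      )
    })
  })
  structure(list(base_level = 0.15,
                 background = background,
                 components = components,
                 seed = as.integer(seed)),
            class = "component_library")
}

#' Noise and artifact model for simulated reflectance spectra
#'
#' Parameters of the replicate-level stochastic structure: additive white
#' noise, a random quadratic baseline drift over the full range, a single
#' multiplicative scatter factor per replicate (particle-packing variation),
#' the sharp detector-switch artifact near 900 nm, and signal saturation
#' below 270 nm (clipping at `saturation_level` plus elevated noise). All
#' standard deviations and amplitudes are in reflectance units and must be
#' non-negative.
#'
#' @param additive_sd Additive white-noise sd per point.
#' @param baseline_drift_amplitude Sd of the three random coefficients of the
#'   quadratic baseline (constant, linear, quadratic in scaled wavelength).
#' @param scatter_slope_sd Sd of the multiplicative scatter factor.
#' @param detector_spike_center_nm Center of the detector-switch artifact.
#' @param detector_spike_amplitude Height of the artifact.
#' @param detector_spike_width_nm Gaussian sigma of the artifact (sharp).
#' @param saturation_below_nm Wavelength below which the signal saturates.
#' @param saturation_level Clipping ceiling in the saturated region; `Inf`
#'   disables saturation.
#' @param saturation_sd Extra noise sd added in the saturated region.
#' @param seed Integer seed from which all replicate-level draws derive.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.002,
                        baseline_drift_amplitude = 0.01,
                        scatter_slope_sd = 0.01,
                        detector_spike_center_nm = 900,
                        detector_spike_amplitude = 0.2,
                        detector_spike_width_nm = 2,
                        saturation_below_nm = 270,
                        saturation_level = 1.0,
                        saturation_sd = 0.02,
                        seed = 1L) {
  nm <- list(additive_sd = additive_sd,
             baseline_drift_amplitude = baseline_drift_amplitude,
             scatter_slope_sd = scatter_slope_sd,
             detector_spike_center_nm = detector_spike_center_nm,
             detector_spike_amplitude = detector_spike_amplitude,
             detector_spike_width_nm = detector_spike_width_nm,
             saturation_below_nm = saturation_below_nm,
             saturation_level = saturation_level,
             saturation_sd = saturation_sd,
             seed = as.integer(seed))
  sds <- c(nm$additive_sd, nm$baseline_drift_amplitude, nm$scatter_slope_sd,
           nm$detector_spike_amplitude, nm$detector_spike_width_nm,
           nm$saturation_sd)
  if (any(!is.finite(sds) & !is.infinite(sds)) || any(sds < 0)) {
    abort("noise sd/amplitude parameters must be >= 0")
  }
  structure(nm, class = "noise_model")
}

#' All-zero noise model
#'
#' Convenience constructor for the noiseless limit: no additive noise, drift,
#' scatter, detector spike or saturation. With this model the generated
#' spectrum is an exact linear function of the concentrations.
#'
#' @param seed Integer seed (kept for interface symmetry; no draws are used).
#' @return A `noise_model`.
#' @export
noise_off <- function(seed = 1L) {
  noise_model(additive_sd = 0, baseline_drift_amplitude = 0,
              scatter_slope_sd = 0, detector_spike_amplitude = 0,
              saturation_level = Inf, saturation_sd = 0, seed = seed)
}

gaussian_bands <- function(wl, bands) {
  v <- numeric(length(wl))
  for (i in seq_len(nrow(bands))) {
    v <- v + bands$amplitude[i] *
      exp(-(wl - bands$center_nm[i])^2 / (2 * bands$width_nm[i]^2))
  }
  v
}

#' Noiseless background reflectance curve of a library
#'
#' @param lib A `component_library`.
#' @param wavelengths_nm Wavelength grid (default 250-2000 nm, 1-nm step).
#' @return Numeric vector of background reflectance values.
#' @export
library_background <- function(lib, wavelengths_nm = seq(250, 2000, by = 1)) {
  lib$base_level + gaussian_bands(wavelengths_nm, lib$background)
}

replicate_seed <- function(seed, sample_pos, replicate_id) {
  as.integer((as.numeric(seed) * 1009 + sample_pos * 101 + replicate_id) %%
               .Machine$integer.max)
}

#' Simulate one replicate reflectance spectrum of a sample
#'
#' The clean signal is `background + sum_j c_j * bands_j` on a 1-nm grid from
#' 250 to 2000 nm, with `c_j` the sample's concentration of component `j`
#' (missing concentrations contribute zero). Replicate-level effects are then
#' applied in order: multiplicative scatter, quadratic baseline drift, the
#' detector-switch spike, additive noise, and saturation below 270 nm.
#' Deterministic given the noise model's seed, the sample and the replicate.
#'
#' @param lib A `component_library` from [default_library()].
#' @param conc A concentration tibble (see [read_concentration_table()]).
#' @param sample_id Sample label present in `conc`.
#' @param noise A `noise_model`.
#' @param replicate_id Small integer replicate label.
#' @return A spectra tibble with one spectrum.
#' @export
generate_sample_spectrum <- function(lib, conc, sample_id,
                                     noise = noise_model(),
                                     replicate_id = 1L) {
  samples <- unique(conc$sample)
  pos <- match(sample_id, samples)
  if (is.na(pos)) abort(paste0("unknown sample_id '", sample_id, "'"))
  comps <- unique(conc$component_index)
  if (!all(comps %in% lib$components$component_index)) {
    abort("library lacks bands for some components in the table")
  }
  wl <- seq(250, 2000, by = 1)
  value <- library_background(lib, wl)
  rows <- conc[conc$sample == sample_id, ]
  for (i in seq_len(nrow(rows))) {
    c_j <- rows$concentration_mg_g[i]
    if (is.na(c_j) || c_j == 0) next
    bands <- lib$components[lib$components$component_index ==
                              rows$component_index[i], ]
    value <- value + c_j * gaussian_bands(wl, bands)
  }
  withr::with_seed(replicate_seed(noise$seed, pos, replicate_id), {
    scatter <- rnorm(1, 0, noise$scatter_slope_sd)
    drift_coef <- rnorm(3, 0, noise$baseline_drift_amplitude)
    u <- (wl - mean(range(wl))) / (diff(range(wl)) / 2)
    value <- value * (1 + scatter) +
      drift_coef[1] + drift_coef[2] * u + drift_coef[3] * u^2
    if (noise$detector_spike_amplitude > 0) {
      value <- value + noise$detector_spike_amplitude *
        exp(-(wl - noise$detector_spike_center_nm)^2 /
              (2 * noise$detector_spike_width_nm^2))
    }
    value <- value + rnorm(length(wl), 0, noise$additive_sd)
    if (is.finite(noise$saturation_level)) {
      sat <- wl < noise$saturation_below_nm
      value[sat] <- pmin(value[sat], noise$saturation_level) +
        rnorm(sum(sat), 0, noise$saturation_sd)
    }
  })
  tibble::tibble(sample = sample_id, replicate = as.integer(replicate_id),
                 wavelength_nm = wl, value = value)
}

#' Simulate a full replicated study
#'
#' One spectrum per replicate per sample in the concentration table, with
#' independent replicate-level noise, fully determined by the noise model's
#' seed.
#'
#' @inheritParams generate_sample_spectrum
#' @param n_replicates Replicates per sample (the measurement protocol used
#'   three).
#' @return A harmonized spectra tibble of `n_samples * n_replicates` spectra.
#' @export
generate_study <- function(lib, conc, noise = noise_model(),
                           n_replicates = 3L) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  samples <- unique(conc$sample)
  purrr::map_dfr(samples, function(s) {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      generate_sample_spectrum(lib, conc, s, noise, r)
    })
  })
}
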