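---
title: "Chemometric calibration of phytochemical content from UV-Vis-NIR reflectance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric calibration of phytochemical content from UV-Vis-NIR reflectance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrocal)
library(dplyr)
```

## The problem

Dried *Arnicae flos* (arnica flower) is a pharmacologically active raw
material whose quality is judged by the content of phenolic acids,
flavonoids and sesquiterpene lactones. The reference assay is HPLC-UV:
accurate, destructive and slow. Diffuse-reflectance UV-Vis-NIR spectroscopy
of the powdered material is fast and non-destructive, but its broad,
overlapping overtone and combination bands carry the composition signal
only indirectly, buried under baseline drift, particle-scatter variation
and instrument artifacts. `spectrocal` implements the complete chemometric
route from raw reflectance curves to per-component calibration models, and
a controlled comparison of three preprocessing variants: untreated
("zero-order") spectra, first derivatives by the symmetric Savitzky-Golay
(GS) convolution filter, and first derivatives by a forward "step-by-step"
filter (SBSF) that sacrifices points only at the long-wavelength end.

The packaged study comprises ten samples (A-J) of diverse origin with
reference concentrations for 14 components (mg/g, some entries not
determined), available via `arnica_concentrations()`.

## Data model and preprocessing

Spectra live in long tibbles (`sample`, `replicate`, `wavelength_nm`,
`value`) on a 1-nm grid nominally spanning 250-2000 nm. Three replicate
scans per sample are averaged (`average_replicates()`) before any
modeling; replicate averaging is the cheapest suppressor of the
particle-packing variation that dominates the visible region, and doing it
first keeps every later stage deterministic in a single curve per sample.

Two instrument artifacts are cut away by closed-interval trimming
(`trim_regions()`): the detector change-over near 900 nm, which leaves a
sharp spike that would explode under differentiation, and the region below
270 nm, where signal saturation and stray light make the values
meaningless. The retained intervals are `270-850` and `907-2000` nm for
zero-order spectra; after differentiation the red interval narrows to
`935-1920` nm (GS) or `935-1980` nm (SBSF). These post-derivative windows
are configured constants, not quantities derived from the point-loss
formulas - the filters themselves already drop their edge points, and the
extra margin keeps the worst spike-adjacent derivatives out of the model
(`default_regions()`).

## The two derivative filters

Both filters estimate d(reflectance)/d(wavelength) by local least-squares
polynomial fitting, expressed as a fixed convolution; both reproduce the
exact derivative of any polynomial up to their configured degree, and both
are linear operators. They differ in where the footprint sits:

* **GS** (`gs_first_derivative()`): symmetric footprint of `2m + 1` points,
  polynomial degree 2, derivative evaluated at the center; loses `m`
  points at *each* end of every contiguous segment. The window parameter
  reported for this workflow ("10 points") is interpreted as the
  half-window `m`; the mapping is isolated in `gs_half_window()` so the
  alternative reading is a one-line change.
* **SBSF** (`sbsf_first_derivative()`): one-sided footprint of
  `degree + window` points extending toward longer wavelengths, degree 3,
  derivative evaluated at the left edge - equivalently a fixed weighted
  combination of forward differences. All point loss (here 4 points)
  accrues at the red end; the blue end of every segment is preserved, and
  there is no attenuation penalty from a wide symmetric window.

The trade-off the comparison probes: wider symmetric windows suppress more
noise (`snr_gain()` grows with `m`) but attenuate narrow derivative
extrema, while the forward filter keeps long-wavelength peak intensities at
the price of losing the red tail of each segment. Weight vectors come from
`gs_coefficients()` / `sbsf_coefficients()`, which solve the local
polynomial least-squares system directly; the unit tests cross-check them
against `signal::sgolay()` and against analytic derivatives of sines and
cubics.

A note on the SBSF formulation: a literal "difference quotient then smooth
the quotient" two-stage scheme cannot be exact on cubics, because the
symmetric difference quotient of a cubic carries a constant
`h^2 f'''/24` bias that no polynomial smoothing of the quotient removes.
The one-sided local-polynomial-derivative form used here is the member of
the same family that satisfies all the observable requirements (red-end
loss, small window, cubic exactness), and is the package's definition of
the filter.

## Calibration and validation

For each component, the sample-by-wavelength matrix is mean-centered by
column (`mean_center()`) and regressed on its reference concentrations
with either PLS1 (NIPALS, the default) or principal-component regression
(`fit_calibration()`); the reported workflow's software labels latent
variables "PCs" without stating the algorithm, so both are provided behind
one interface. `n_pc = 0` is the null model predicting the training mean.
Components beyond the effective rank of a training set contribute nothing,
which keeps noiseless (rank-deficient) fits well defined.

Validation is leave-one-out (`loocv_calibration()`): for every fold the
column means, the response mean and the whole model are recomputed from
the `n - 1` training rows only - no statistic of the held-out row enters
the fit, which the tests verify by disagreement with a deliberately leaky
variant. Per latent-variable count the function reports

* RMSECV `= sqrt(sum((y_hat_i - y_i)^2) / n)` over left-out predictions,
* R² as the squared Pearson correlation of cross-validated predictions
  with the reference values (the conventional summary of this workflow;
  the phrase "square root of the correlation coefficient" sometimes seen
  for it is garbled),
* the slope and offset of the predicted-versus-reference line.

`select_pcs()` picks the latent-variable count minimizing RMSECV, ties
toward fewer; a strictly decreasing profile is flagged
(`monotone_decreasing`), since the minimum then sits on the search
boundary. `max_pc` defaults to `n - 2`: folds train on `n - 1` samples and
centering consumes one degree of freedom. With ten samples this caps the
search at 8 - published per-component tables quoting 9-10 latent variables
for ten LOOCV samples cannot arise under fold-wise refitting as defined
here.

### Outlier screening

Before modeling, each component's concentrations are screened with a
robust z-score, `|x - median| / (1.4826 * MAD)` (`detect_outliers()`);
flagged samples are excluded from that component's calibration only. The
default cutoff is 5.0, chosen so that on the packaged reference table the
screen reproduces the study's reported outcome exactly: quercetin flags
only sample H (score 12.9) and kaempferol only sample G (score 7.4), with
nothing flagged elsewhere (largest other score 4.98, caffeic acid in
sample F). The more common 3.5 cutoff would additionally flag three
borderline values (caffeic acid/F 4.98, isoquercitrin/I 3.97,
luteolin-7-glucoside/J 3.64); any cutoff in (4.98, 7.42) yields the
reported set, and the threshold is an argument for users who prefer the
stricter convention.

## The synthetic study generator

No raw spectra of the ten samples were ever deposited, so the package
ships a generator (`default_library()`, `generate_study()`) that emulates
the measured curves' structure and lets every downstream stage be tested
end to end. The clean signal is a fixed background - base level plus broad
Gaussian bands at 1920, 1720, 1450 nm (NIR), 650 nm (orange petals),
500 nm (green bracts), and a steep UV edge at 250 nm - plus, per
component, 2-4 seed-reproducible narrow Gaussian bands (widths 10-30 nm)
whose amplitudes scale linearly with concentration. Replicate-level
effects mirror the artifacts the pipeline must survive: one multiplicative
scatter factor per replicate, a random quadratic baseline, additive white
noise (default sd 0.002 on a ~0.2-1 reflectance scale), the sharp detector
spike at 900 nm, and clipping plus elevated noise below 270 nm. All draws
derive from one integer seed through a per-replicate counter;
`noise_off()` gives the exactly linear noiseless limit.

What the generator does *not* emulate - and hence what passing tests do
not show about real data: real absorption-band shapes and their true
overlap structure, wavelength-dependent instrument response beyond the
spike, nonlinear reflectance physics (no Kubelka-Munk transformation), and
concentration errors in the reference assay itself. The generator is a
statistical stand-in, not a spectral database.

## What recovery experiments can and cannot show

On low-rank noiseless mixtures (two varying components, ten samples) the
pipeline recovers concentrations essentially exactly: training residuals
and LOOCV error fall below 1e-6 at the matching latent-variable count, and
RMSECV decreases to zero as generator noise goes to zero. These are the
regimes where leave-one-out is informative about model correctness.

On the *full* 14-component table the noiseless LOOCV error does **not**
vanish, for a structural reason worth stating precisely: the concentration
matrix of the ten samples has full row rank, so each training fold of nine
centered spectra spans at most eight dimensions, while the left-out
sample's centered spectrum generally has a component orthogonal to that
span. No amount of latent variables can recover what the training fold has
never seen; the cross-validated R² of low-variance components is
accordingly poor even with zero noise. This is a property of
leave-one-out with more independent constituents than samples, not of the
implementation (training fits are exact, and the brute-force refit oracle
agrees to 1e-10). It is also why halving the additive noise below the
default level improves the median RMSECV only marginally: the structural
floor dominates. The packaged acceptance checks report these quantities as
measured.

## Problem sizes and numerical choices

The test suite and the acceptance script use the study's own scale
throughout: ten samples, three replicates, 1751-point grids, 14
components, three methods (42 model cells per pipeline run), five seeds
and three noise levels for the noise-halving experiment, 100 Monte-Carlo
draws for signal-to-noise ratios, and twenty random small problems
(n = 10, p = 50) for the LOOCV oracle. Rank deficiency in NIPALS/SVD is
detected at a 1e-12 relative tolerance and handled by freezing the
coefficient path; ties in model selection go to fewer latent variables;
ties in the best-method tally credit no method. Wavelength intervals are
closed on both ends; grids must be strictly increasing, and filters
operate per contiguous constant-step segment after trimming.

## A worked comparison

```{r pipeline, eval = FALSE}
conc <- arnica_concentrations()
lib <- default_library(seed = 42)
study <- generate_study(lib, conc, noise_model(seed = 1), n_replicates = 3)

report <- run_pipeline(study, conc)
count_best_by_method(report)
autoplot(report)
```

The same tally applied to the packaged published summary
(`arnica_model_summary()`) credits the step-by-step filter with the
strictly lowest RMSECV for eight of the thirteen monitored components
(1, 2, 3, 4, 5, 8, 9, 12 in the summary's numbering), the GS derivative
with three, and the untreated spectra with two. The narrative
accompanying that summary counts seven for SBSF, treating component 9
(apigenin-7-glucoside, margin 3.7%) as "similar" while crediting
component 1 (margin 2.4%); no monotone tie tolerance reproduces that
reading, so the package reports the strict arithmetic result and leaves
the interpretation to the analyst.

## Known limitations

* With ten samples, LOOCV statistics are noisy and the latent-variable
  search is capped at eight; no independent test set is supported because
  the study design has none.
* The SBSF definition is a reconstruction from its observable properties;
  it is not guaranteed to bit-match other software of the same name.
* Concentration-table column numbering differs between the concentration
  fixture and the published model summary for components 7-12 (e.g.
  quercetin is component 11 in the former, 12 in the latter); the package
  keeps each table's own numbering and documents the discrepancy rather
  than renumbering either.
* The simulated spectra justify software correctness claims only; they
  say nothing about the chemical attainability of any calibration quality
  on real arnica material.
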