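---
title: "Quantifying multiplicative synaptic scaling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multiplicative synaptic scaling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synscale)
```

## The scientific problem

Homeostatic synaptic scaling is the hypothesis that a neuron adjusts the
strength of *all* of its excitatory synapses by a common multiplicative
factor, preserving relative synaptic weights while shifting the overall
operating point. Two observables carry the evidence:

1. **mEPSC amplitudes.** Miniature excitatory postsynaptic currents are
   recorded under voltage clamp; each event's peak amplitude reflects the
   AMPA-receptor content of one synapse. If treatment scales synapses
   multiplicatively by a factor $c$, then the amplitude distribution of
   treated cells is that of control cells with every quantile multiplied
   by $c$.
2. **Surface-receptor puncta.** Immunolabelling of surface AMPAR subunits
   produces diffraction-limited fluorescent puncta whose background-
   subtracted integrated intensity measures receptor content per synapse.
   Multiplicative scaling predicts the same quantile relationship for
   punctum intensities.

The core statistic in both cases is the **rank-order plot**: sort the
treated values, sort the control values, pair them by rank, and fit a
straight line of treated against control. Under multiplicative scaling
the points fall on a line of slope $c$ through the origin; under an
additive change of $a$ they fall on a line of slope 1 with intercept $a$.
The fitted slope *is* the scaling factor, and the intercept is the
diagnostic that separates the two hypotheses.

Formally, if $F^{-1}$ is the control quantile function and treated values
are distributed as $cX$, then the $k$-th order statistics of equal-sized
samples estimate $F^{-1}(k/n)$ and $cF^{-1}(k/n)$: their regression has
slope $c$ and intercept 0 in expectation. This quantile-matching argument
is what the package's recovery tests assert on synthetic data.

## The mEPSC route

`scaling_pipeline()` composes the full procedure:

* **Per-cell subsampling** (`subsample_per_cell()`, default `k = 100`):
  a fixed number of amplitudes is drawn without replacement from every
  recording, because high-frequency cells would otherwise dominate the
  pooled distribution. Strict mode refuses cells with fewer than `k`
  events; permissive mode takes all of them with a warning.
* **Pooling, count matching and sorting** (`build_rank_order()`): if the
  two pools differ in size, the larger is randomly subsampled (seeded) to
  the smaller; both are then sorted ascending with a stable sort.
* **Top exclusion** (default `exclude_top = 0.01`): the largest 1% of
  rank *pairs* is dropped. The largest amplitudes are outlier-prone and
  have enormous leverage on an ordinary least-squares fit. We apply the
  exclusion to rank pairs after matching (rather than per condition
  before pairing) so the two vectors stay aligned; the two readings are
  equivalent for equal pools.
* **Fitting** (`fit_scaling_factor()`): ordinary least squares of treated
  on control with a free intercept, which is what standard curve-fitting
  software does by default. A through-origin mode is available as a
  diagnostic; multiplicative scaling predicts the two agree.

```{r mepsc-example}
model <- amplitude_model(cell_cv = 0)
ctrl <- sample_cell_amplitudes(model, 20, 150, seed = 1)
trt <- sample_cell_amplitudes(model, 20, 150, seed = 2)
trt[] <- lapply(trt, apply_scaling,
                transform = scaling_transform("multiplicative", 1.43))
scaling_pipeline(ctrl, trt, seed = 3)
```

### Statistical behaviour of the slope estimate

A point that matters for interpreting single fits: with 20 cells times
100 subsampled events per condition, the fitted slope has a standard
deviation of roughly 0.04 around the true factor even for homogeneous
populations. The variance is dominated by the highest retained order
statistics, whose sampling noise is large and highly influential on the
fit; the 1% top exclusion removes the worst of it but not all. The
package therefore states its recovery guarantees over replicate
ensembles (the mean of 50 seeded replicates recovers factors in
{1.0, 1.2, 1.42, 1.43, 2.0} to about +/-0.01) and treats any single
fitted slope as carrying sampling uncertainty of a few hundredths. The
same caveat applies to published single-realisation slopes from
recordings of this size.

### Event detection

`detect_events()` finds mEPSCs in raw current traces: deflections in the
configured polarity measured against a running-median local baseline
(50 ms window), pre-screened on a 1 ms moving average so single-sample
noise excursions do not trigger, with the final amplitude read from the
unsmoothed deflection. Two merge rules prevent double counting: peaks
closer than `min_separation_ms` (default 5 ms) merge, and a later peak
only counts as a new event if the deflection dipped below half the
threshold in between -- otherwise it is ripple on the previous event's
decay tail. The conventional thresholds are 5 pA for AMPAR-mEPSCs and
10 pA for NMDAR-mEPSCs. On synthetic recordings with events at four or
more noise standard deviations and separations of at least three decay
constants, recall and precision both exceed 0.95 and amplitude estimates
are unbiased within three noise SDs.

`fepsp_initial_slope()` measures field-potential synaptic strength as the
OLS slope over the contiguous run of samples between 10% and 40% of the
baseline-to-peak excursion, after a 2 ms stimulus-artifact blank;
`evoked_measures()` reports the AMPA peak (at -70 mV), the NMDA value
exactly 150 ms after EPSC onset (at +40 mV, linearly interpolated), and
their ratio.

## The imaging route

`quantify_puncta()` chains the image-processing steps in the order a
practitioner would run them interactively:

1. **Sum projection** across the z-stack (`zproject_sum()`), preserving
   integrated intensity.
2. **Li minimum-cross-entropy threshold** (`li_threshold()`), computed by
   exhaustive minimisation of the cross-entropy objective over a 256-bin
   histogram -- exact on the binned data by construction, and verified in
   the test suite against an independent brute-force evaluation of the
   objective.
3. **FFT band-pass** (`fft_bandpass()`): a frequency-domain
   difference-of-Gaussians with documented transfer function
   $H(f) = e^{-2\pi^2 (s/2)^2 f^2} - e^{-2\pi^2 (l/2)^2 f^2}$,
   suppressing structure smaller than $s$ px (default 1) and larger than
   $l$ px (default four times the PSF full width at half maximum). The DC
   component is removed entirely.
4. **h-watershed segmentation** (`hwatershed_segment()`): watershed on
   the supra-threshold intensity landscape in which a local maximum seeds
   an object only if it exceeds its surroundings by at least `h` (the
   seed dynamic; default 10% of the supra-threshold dynamic range). Two
   equal-width Gaussian spots develop an intensity valley only beyond
   two sigma separation, so closer pairs are physically unresolvable and
   correctly stay single objects.
5. **Particle analysis** (`particle_analysis()`): label areas converted
   to um^2, particles kept within 0.05-1 um^2 (bracketing the 178 nm
   diffraction limit: `lateral_resolution(488, 1.4)` = 177.8 nm), and
   background-subtracted integrated intensity measured on the *unfiltered*
   projection so photometry is unbiased by the band-pass. Background
   defaults to the median of sub-mask pixels.

By default the watershed mask is recomputed by Li thresholding the
band-passed image, since thresholding after background suppression is
better-posed; `strict_order = TRUE` uses the raw-projection threshold
instead, matching the strictly sequential reading of the interactive
workflow.

**Size classification.** `fit_area_gaussian()` fits a Gaussian to the
punctum-area histogram by least squares on bin centres
(Freedman-Diaconis binning with a fixed-bin fallback) and reports the
Mean+3SD cutoff delimiting single postsynaptic structures from merged
multi-synapse blobs. The fitted peak is constrained to lie inside the
observed area range, which keeps the fit stable when the particle-area
window truncates one flank of the histogram. `puncta_scaling()` filters
each set to its cutoff, count-matches by seeded subsampling, ranks
intensities, and fits the lowest 90% of ranks -- the brightest puncta
deviate from linearity (they are disproportionately multi-synaptic), so
the 0-90% fraction carries the scaling estimate.

## The synthetic-data generators

Every analysis stage is validated against generators with exact ground
truth; all are bit-reproducible given a seed.

* **Amplitude populations** (`amplitude_model()`,
  `sample_cell_amplitudes()`): log-normal with `mu_log = log(12)` and
  `sigma_log = 0.35` (median 12 pA, CV about 36%, typical of
  hippocampal-culture AMPAR-mEPSCs), truncated at the 5 pA detection
  floor *by redraw* rather than clipping -- rejection sampling keeps a
  scaled population an exact scalar multiple of the control population in
  distribution, which is the generator contract the recovery tests rely
  on. Cell-to-cell heterogeneity is a log-normal multiplicative factor
  with unit mean and CV `cell_cv` (default 0.1). Recovery experiments use
  the homogeneous model (`cell_cv = 0`): the recovery claims concern the
  statistic, and cell heterogeneity is a separately-dialled robustness
  factor (20 cells of CV 0.1 add about 0.03 of slope noise per
  condition pair).
* **Current traces** (`synth_trace()`): difference-of-exponentials event
  kernel normalised to unit peak, rise/decay defaults 0.5/5 ms (typical
  AMPAR kinetics), Gaussian baseline noise, inward events negative. The
  kernel, noise level and rates are fixture choices -- they model no
  particular amplifier -- and are fully configurable.
* **Punctum fields** (`puncta_field_model()`, `synth_puncta_image()`):
  Poisson-distributed punctum positions at 0.3/um^2 default density,
  log-normal integrated intensities, rendered as pixel-integrated 2D
  Gaussians over +/-4 sigma windows (truncation < 0.01% of the
  integral), on a uniform background with Poisson-Gaussian noise.
  The rendered spot width is the PSF (sigma 0.0755 um for 488 nm / NA
  1.4) convolved with a physical receptor-cluster source of sigma
  0.10 um: surface-receptor puncta are not point emitters, and with the
  default source size the synthetic punctum-area histograms land where
  measured surface-AMPAR histograms do (single-punctum Mean+3SD cutoffs
  near 0.25 um^2, comfortably above the 0.05 um^2 particle-analysis
  floor). Set `source_sigma_um = 0` for ideal point sources. A
  configurable doublet fraction places companions at 0.8-1.6 spot sigma
  -- deliberately at or below the resolvability limit -- to exercise the
  pipeline's handling of merged adjacent synapses. Calling the generator
  twice with one seed and two transforms yields seed-matched field
  pairs whose true per-punctum intensity ratio is exactly the factor.

### What the generators do and do not emulate

They reproduce the statistical structure the analyses assume: truncated
right-skewed amplitude populations, linear superposition of stereotyped
events on stationary noise, and spot fields with realistic size/intensity
distributions, adjacency and camera noise. They do not emulate kinetic
variability between events, correlated or non-stationary noise, uneven
illumination or staining background gradients, out-of-focus haze in the
z-direction, or non-Gaussian PSF tails. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every artefact of real recordings; the configurable models
are the place to probe such deviations.

## Numerical choices and degenerate inputs

* Seeds: every stochastic function takes an explicit `seed`; pipelines
  derive per-stage child seeds so stages are individually reproducible.
  `NULL` uses the ambient RNG stream.
* Ties in sorting are broken by a stable radix sort (value, then original
  index): immaterial to fits, material to bit-reproducibility.
* `li_threshold()` shifts non-positive images into positive support (the
  criterion needs positive intensities) and returns thresholds on the
  original scale; constant images are flagged degenerate and return the
  constant with a warning.
* `fit_scaling_factor()` refuses zero-variance control values;
  `build_rank_order()` refuses exclusions that leave fewer than two
  pairs; `fit_area_gaussian()` requires 50 areas (configurable) and
  errors on degenerate histograms rather than reporting a meaningless
  cutoff.
* `compare_rank_distributions()` is exact where feasible -- the exact
  U distribution without ties, full enumeration with ties when the
  assignment count is small -- and a tie-corrected normal approximation
  otherwise. All-tied input is flagged degenerate with p = 1.
* Problem sizes in the test suite (20-cell recordings, 20-30 um fields,
  up to 16 pooled field pairs, 50-200 replicate batteries) were chosen so
  that ensemble estimates have standard errors several times smaller than
  the tolerances they are tested against.

## Known limitations

* The rank-order statistic assumes equal-sized, independently sampled
  populations; it does not model within-cell correlation beyond the
  subsampling step, and it is not a goodness-of-fit test for
  multiplicativity (inspect the intercept and the upper-rank curvature).
* Detection is threshold-based, as in common interactive analysis
  software; heavily overlapping events at high frequencies are merged by
  design, not deconvolved.
* Segmentation is 2D on the projection; genuinely three-dimensionally
  adjacent puncta merged by projection are handled only via the area
  cutoff.
* The interactive watershed's `h`, the band-pass radii and the pixel size
  are acquisition-dependent and exposed as configuration with documented
  defaults rather than fixed constants.
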