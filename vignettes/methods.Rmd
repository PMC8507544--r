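---
title: "Models and methods behind cytoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cytoscreen)
```

`cytoscreen` implements an automated Raman cytology screen in five layers:
domain containers and I/O, a synthetic instrument, bright-spot nucleus
targeting, spectral pre-processing, and cross-validated classification. This
vignette explains the models each layer assumes, the parameters that matter,
the numerical decisions taken where the design was genuinely open, and what
the synthetic benchmark does and does not demonstrate about real data.

## Spectra and axes

A spectrum is a vector of detector counts over a shared wavenumber axis; the
default axis is 1024 samples spanning −34 to 2517 cm⁻¹, treated as linear in
wavenumber. Real spectrographs have a mildly nonlinear pixel-to-wavenumber
map, which is instrument-specific; all downstream operations are therefore
defined by wavenumber bounds, never by sample counts. In particular
`crop_fingerprint()` keeps the closed interval 600–1800 cm⁻¹ — the window
holding most biomolecular bands — whatever number of channels that happens
to select. Axes are stored ascending regardless of source order, and the
canonical on-disk format is a plain CSV (`wavenumber_cm1` plus one column
per spectrum) with labels and per-spectrum metadata in a JSON sidecar, so
nothing in the pipeline depends on a binary vendor format.

## The synthetic instrument

The phantom layer exists so that every stage of the pipeline can be tested
against known ground truth. It emulates, phenomenologically, the observables
the automation routine actually uses — not the underlying optics.

**Bright spots.** A cell nucleus under near-coherent illumination acts as a
microlens, focusing light into a bright spot in a plane displaced from focus
by an amount that depends on cell morphology (14 µm for round ThinPrep
cells, 50 µm for flat adherent ones; both presets are provided). Rather than
model diffraction, `render_image()` gives each nucleus an isotropic Gaussian
spot whose amplitude follows a Gaussian envelope in z centred on the
bright-spot plane (axial width ζ = 5 µm), plus a faint ring whose amplitude
grows with defocus as z²/(z²+z_c²) and decays under a wide Gaussian. The
ring serves one purpose: it makes the variance-contrast profile rise on both
sides of focus so the focal plane is an interior local minimum, as observed
on real variance profiles, while the spot makes the bright-spot plane the
global maximum. Far from both planes the rendered contrast falls below 1% of
the bright-spot contrast. Spot amplitudes (120–200 counts over a
100-count background) give single-spot SNR well above the ≈3 detection
limit; they are free parameters chosen so the targeting benchmark is
non-trivial but not fragile.

**Camera.** Counts are Poisson shot noise on the accumulated signal plus
dark charge, plus Gaussian read noise, at unit gain. The defaults — read
noise 4 e⁻/sample, dark current 0.0512 e⁻/s/sample — describe a cooled
deep-depletion spectroscopy CCD in full-vertical-bin mode. A Monte-Carlo
test verifies the per-channel variance budget (signal + dark + read²)
against 200 replicates.

**Spectra.** A raw cell spectrum is generated as
`t·(cr·R_class + cb·Glass + baseline) + dark + noise + cosmic rays`, the
weighted superposition the pre-processing model assumes — by design, since
the point of the phantom is to exercise that model, not to defeat it. The
two classes share a 16-band cell signature (DNA backbone 680/789/1093/1490,
phenylalanine 1003, tyrosine 1170, amide III ~1245, CH₂/CH₃ 1303/1449,
amide I 1660 cm⁻¹, and others); only three DNA-associated bands —
789, 1003 and 1490 cm⁻¹ — differ between classes, by a 15% amplitude
contrast split symmetrically. Band shapes are Gaussians of width 8–20 cm⁻¹
(adequate stand-ins for pseudo-Voigt lines at this resolution). The glass
signature is three broad humps, strongest at ~1100 cm⁻¹; the
autofluorescence baseline is a random cubic kept strictly positive (a
clamped-negative baseline would introduce kinks no smooth-background model
could fit); `cr` and `cb` are lognormal with σ_log 0.25 and 0.2, emulating
focus- and morphology-driven amplitude variation. Peak count rates are of
order 10–90 counts/s, giving fingerprint peaks near 10³ counts at the 10 s
cell exposure — typical of a 532 nm, ~150 mW confocal system. Cosmic rays
arrive as a Poisson process (default 0.01 events/s), are 1–3 channels wide
with per-channel amplitudes uniform in 20–200 local noise SDs, and distinct
events are kept more than 3 channels apart so the recorded ground truth is
unambiguous about event widths.

**Instrument contract.** `simulated_instrument()` exposes `move_stage()`,
`set_z()`, `snap_image()` and `acquire_spectrum()`. Stage moves are
quantised to the 0.1 µm encoder resolution and jittered with a 0.25 µm
(3σ) repeatability error; the laser spot is displaced from the imaging axis
by a fixed calibrated offset; `acquire_spectrum()` returns the class
spectrum of the nucleus nearest the laser point if within the 3 µm capture
radius, else glass-plus-baseline only. Every stochastic call derives its
seed from the master seed and a call counter, so identical call sequences
are identical.

What the phantom does **not** emulate: diffractive point-spread functions
and aberrations, cell-to-cell biochemical heterogeneity beyond the scalar
`cr` (real nuclei vary band-by-band), fluorescence photobleaching dynamics,
substrate inhomogeneity, wavenumber calibration drift, and sub-nuclear
structure (nucleoli). Tests passing on this benchmark demonstrate that the
algorithms are implemented correctly and are self-consistent under realistic
noise; they do not demonstrate classification performance on real cell
lines, whose class differences and artefact structure are richer.

## Targeting

The contrast metric is the population variance over the mean of pixel
intensities, σ²/µ; the alternative reading (σ/µ)² is available via
`definition = "cv_squared"` and recorded per run — both are monotone in
contrast for a fixed mean, and the choice does not move the argmax on the
rendered stacks. `autofocus()` takes the interior global maximum as the
bright-spot plane (a boundary maximum means the scan range failed to bracket
it and is an error) and the interior local minimum nearest that plane as the
focal plane, ties broken toward smaller |z|.

Stitching is translation-only — a motorised stage does not rotate the camera
— with nominal offsets from the commanded stage positions and the pixel
size, refined by phase correlation computed on the nominally overlapping
strips of each left/top neighbour pair (the strips share almost all their
content, so the correlation peak stays sharp even at 10% overlap, where
whole-tile correlation fails). A refinement is accepted only when the peak
is at least 3× the strongest off-peak value and consistent with the nominal
layout; otherwise the nominal offset is used, so featureless tiles degrade
gracefully. Overlaps are blended by a feathered (edge-distance-weighted)
average. The pixel→stage affine map is still fitted with a full 2×2 linear
part (from tile-centre correspondences) so camera/stage axis skew and flips
are absorbed by least squares; it recovers synthetic maps to machine
precision and reports its RMS residual.

Detection smooths with a Gaussian of width ≈ spot radius / pixel size
(default 4 px), then keeps local maxima above
`background + 0.25·(max − background)` (background = smoothed median) that
are ≥ 8 px apart, with plateaus collapsed to centroids; none of these three
constants is dictated by the problem, so all are configuration with logged
defaults, and a mosaic whose dynamic range does not clear five robust SDs of
the smoothed image is declared empty rather than mined for noise peaks.
Isolation filtering ranks candidates by distance to their nearest neighbour
and keeps the most isolated — clustered cells are the ones that get double
targeted. Route ordering is the classic greedy nearest-neighbour chain; it
is not an optimal tour, but it is never longer than visiting targets in
detection order, which is the property that matters for stage travel.

## Pre-processing

**Cosmic rays.** The removal follows the matched-spectrum idea — find a
closely matching spectrum in the dataset and substitute the corrupted
channels — with a detection model made robust enough to hold a recall of
1.0 with zero false positives on the benchmark: (i) candidate matches are
the most correlated spectra, with suspect channels (narrow departures from
a running median, judged per channel against the whole dataset) patched out
before correlating so a spike can neither distort the ranking nor leak into
the model; (ii) the best two matches plus a cubic polynomial are fitted by
least squares, so mismatch in the cell weight, the substrate weight and the
baseline all cancel, not just overall scale; (iii) the residual is detrended
with a width-21 running median (reflection-padded; blind to features up to
the 3-channel maximum spike width); (iv) the threshold is k·σ with σ a
per-channel MAD across spectra — shot noise makes strong-band channels
2–3× noisier than quiet ones, and one global σ either misses spikes or
flags band apexes — inflated per spectrum when a spectrum has no close
match in the set; (v) only positive excursions are flagged (cosmic rays
deposit charge; a residual pushed the other way is model mismatch), and a
flag must either be pre-suspect in its own spectrum or clear 1.5k·σ.
Flagged runs wider than `max_width = 3` channels are left untouched —
broad structure is signal, not a spike. Two passes guarantee that a spike
sitting in a spectrum's best match cannot survive. Clean data pass through
bit-identically, and the k = 8 default sits far from both the noise tail
and the ≥20σ spike amplitudes.

**References.** The cell reference is the unsmoothed mean of the top-k
(default 50) spectra of a reference set. "Highest quality" is undefined in
the abstract problem statement, so the default ranks by Pearson correlation
against the channel-wise median spectrum — robust to spikes and outliers —
with an SNR ranking available by option. The substrate reference is the
channel-wise mean of the glass spectra smoothed with Savitzky–Golay order 3,
window 9.

**EMSC.** The correction solves `X0 ≈ cr·R + cb·B + Σ₀⁵ cm·Pm` by ordinary
least squares and returns `(X0 − cb·B − Σ cm·Pm)/cr`. The polynomial basis
is Legendre on the axis rescaled to [−1, 1]: the monomial basis on raw
wavenumbers is catastrophically ill-conditioned at order 5, while the
orthogonal basis keeps the design condition number small; reported
coefficients are in that basis (the decomposition itself fixes no basis).
The design matrix is column-equilibrated and its condition number checked
(> 1e10 raises a collinearity error naming the offending component, e.g. a
substrate equal to the reference); a reference weight below 1e-6 is a
degenerate fit and an error rather than a division. Division by `cr`
performs the normalisation to reference scale that makes the Pearson cull
meaningful. On noise-free constructions the fit recovers all weights to
< 1e-8 and the corrected spectrum equals the reference to < 1e-8.

**Denoising and culling.** Savitzky–Golay (order 3, window 7) uses the
standard centre-point convolution weights in the interior; each edge channel
is refit on its truncated window, so polynomials up to the filter order pass
through unchanged everywhere, not just in the interior. The quality cull
retains spectra with Pearson r ≥ 0.99 against the cell reference (boundary
retained), computed after EMSC and denoising on the fingerprint window —
whether the original procedure used the full window or a sub-window is
unknowable from the problem statement, and the fingerprint window is the
conservative reading since it is where the reference carries structure.

The pipeline order is: cosmic-ray removal → reference construction → EMSC →
Savitzky–Golay → fingerprint crop → cull → classification.

## Chemometrics

The marginal-relevance score of channel j is `B_j/W_j`, the between-class
over within-class sum of squares, with the conventions `W=0, B>0 → +Inf` and
`0/0 → 0`. It is invariant to per-channel shifts and to global rescaling.
Because neighbouring wavelengths score alike, taking the global top-10
channels would pick one band's apex and its shoulders; instead the axis is
split into 10 contiguous equal-width (±1 channel) regions and each
contributes its argmax (ties to the lowest index). One channel per region is
the default; the count is configurable since "the wavelengths with highest
scores from ten regions" admits either reading.

Cross-validation is stratified 10-fold: within each class a seeded
permutation is dealt round-robin, so per-fold class counts differ by at most
one. PCA (3 components, on mean-centred unscaled data — spectra share units
after EMSC normalisation) and MR are fitted on the training rows of each
split only, and the same fold assignment is shared by all eleven pipeline
configurations, so differences between classifiers are not fold noise. The
eleven configurations are fixed — PCA×{LDA, QDA, kNN}, MR×{LDA, QDA, kNN,
RF, SVM}, and RF/SVM/PLS on all wavelengths — with untuned hyperparameters:
kNN k = 5 (Euclidean, no extra scaling), RF 500 trees with mtry = ⌊√p⌋, SVM
with a Gaussian kernel whose bandwidth is the midrange of the 0.1/0.9
quantiles of 1/(2‖x−x′‖²) over a seeded subsample, and PLS with 15 latent
variables deliberately set large rather than tuned. PLS is used as a
classifier by regressing a ±1 class code and thresholding at 0, the simplest
PLS-DA decision rule; the in-package NIPALS implementation caps components
at the training rank. A fold whose QDA covariance is singular is recorded,
excluded and warned about — never silently dropped. Metrics (accuracy,
sensitivity, specificity; positive class = the high-grade line) are pooled
over folds (micro-average); per-fold accuracies are also kept for box
plots, since the aggregation rule is itself a reporting choice.

LDA/QDA, kNN, RF and SVM are delegated to MASS, class, ranger and kernlab —
the standard engines for these models in R; MR, the region selection, the
stratification, the CV harness, the leakage handling, the metrics and the
PLS classifier are implemented in the package and oracle-tested.

## Problem sizes and calibration checks

The shipped verification suite uses problem sizes chosen to exercise every
code path at full fidelity while staying desk-scale: 100 random EMSC
constructions on the full 1024-channel axis; 50 random spectra against a
sliding least-squares oracle; 100 spectra with ground-truth spikes for the
cosmic-ray benchmark; 50×200 matrices for the MR oracle; n = 200 for the
null (label-shuffled) and separable (10σ) cross-validation calibrations;
300 spectra per class for the end-to-end screen; 40 nuclei for targeting
recall; 10 seeded slides per morphology preset for autofocus. Under the
default generator settings the end-to-end screen yields accuracy,
sensitivity and specificity above 0.95 for SVM, RF and PLS, the
quality cull retains everything, and the MR selection recovers the three
planted discriminating bands — properties of the synthetic benchmark, to be
read as implementation verification, not as expected field performance.

## Known limitations

* The bright-spot and ring rendering is phenomenological; detection
  parameters transferred to a real instrument need recalibration against
  fluorescence ground truth.
* The cosmic-ray remover requires at least two spectra (by design: it is a
  matched-spectrum method); the single-spectrum fallback is a running
  median, available only behind an explicit error message.
* Classification currently supports two classes; MR and the folds
  generalise, but the confusion-matrix metrics and the PLS code assume a
  binary problem.
* The greedy route is a 2-approximation-style heuristic, not an optimal
  tour; for the ~40-target runs of interest the difference is negligible
  stage time.
* The pixel→stage map is a single global affine; field-dependent distortion
  (barrel/pincushion) is not modelled, consistent with the small fields
  stitched here.
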