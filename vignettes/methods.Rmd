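---
title: "Methods: ATR-FTIR metabolic fingerprinting of cell spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ATR-FTIR metabolic fingerprinting of cell spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Attenuated total reflectance Fourier-transform infrared (ATR-FTIR)
spectroscopy measures mid-infrared absorbance of a dried biological sample as
a function of wavenumber (cm^-1). Because every biomolecule class absorbs at
characteristic frequencies — lipid C–H stretches around 3000–2800 cm^-1,
ester carbonyls near 1747 cm^-1, the protein amide I/II envelope in
1700–1500 cm^-1, carbohydrate and nucleic-acid bands in 1200–900 cm^-1 — a
single spectrum is a metabolic fingerprint. The analysis implemented here
asks whether such fingerprints discriminate groups of cultured skin
fibroblasts that differ in disease severity (e.g. myotonic dystrophy type 1
cell lines with different CTG repeat lengths or ages of onset), and whether
specific lipid intensity ratios differ between groups.

The workflow is: read spectra → baseline-correct → area-normalize →
Savitzky–Golay second derivative → (a) region-restricted PCA with
side/quadrant readouts and loading-peak band assignment, and (b) lipid
intensity ratios with a nonparametric test battery. A synthetic cohort
generator reproduces the statistical structure this analysis assumes, so
every stage can be validated against analytic ground truth without any
external data.

## Preprocessing

**Baseline.** The default is the rubberband method: the lower convex hull of
the (wavenumber, absorbance) points is subtracted, which removes any smooth,
convex drift (ATR contact and scattering artifacts) and leaves the corrected
spectrum nonnegative at the hull's support points. A two-point linear
baseline is available as an option. Which method the original workflow used
is not stated by typical acquisition software exports; the second derivative
downstream is in any case insensitive to smooth baselines, so this choice
does not propagate into the ratio or PCA results.

**Normalization.** Spectra are scaled so that the trapezoidal integral of
|A| over the full acquired range equals 1 (before any region selection).
Scaling is by a positive scalar, so band shapes, band positions and all
intensity ratios are invariant; what normalization removes is the arbitrary
overall pathlength/amount-of-sample factor that would otherwise dominate
between-replicate variance. Whether to integrate |A| or signed A is
config-exposed; |A| is the default since baseline-corrected absorbance is
essentially nonnegative and |A| remains well defined for derivative-shaped
inputs.

**Second derivative.** A Savitzky–Golay filter differentiates twice while
smoothing: a polynomial of order `sg_polyorder` is least-squares fitted over
a sliding window of `2*sg_half_width + 1` points and its second derivative
at the window center is taken. Output values are scaled by the true grid
spacing (AU·cm^2), and the output grid is trimmed by `sg_half_width` points
per side so only full-window estimates are returned. The published
description of this step ("3 smoothing points") is ambiguous about window
semantics; we read it as 3 points per side, i.e. a 7-point window, and
expose both parameters.

The default polynomial order is 4, not the more common 2. On bands of width
σ ≈ 8 cm^-1 — the narrow end of what cellular mid-IR spectra contain — a
7-point *quadratic* window at 1 cm^-1 spacing underestimates the central
second-derivative magnitude by ≈3.7% (13.6% at 2 cm^-1 spacing), because
the local quadratic over-smooths the curvature maximum. A 7-point quartic
fit reduces this discretization bias below 0.1% at 1 cm^-1 and below 0.6%
at 2 cm^-1 while keeping the same window; equal-width biases also largely
cancel in ratios. The quartic filter passes more noise than the quadratic;
the peak-intensity estimator below is designed so that this does not reach
the ratios.

**Regions.** PCA is run per spectral region (defaults 3000–2800, 1800–1500,
1200–900 cm^-1, closed intervals). The derivative is always computed on the
full grid first so window-edge loss falls outside the analysis regions, and
regions are cropped afterwards. Note the olefinic band at 3013 cm^-1 lies
*outside* the lipid PCA region, which is why intensity ratios are computed
from the full-range derivative, never from region crops.

## PCA readouts

PCA uses column mean centering only (no variance scaling — area
normalization already removed the scale factor, and per-wavenumber scaling
would inflate baseline noise). Decomposition is by SVD; explained variance
per component is `100 * sigma_i^2 / sum(sigma^2)`. Replicates enter as
independent rows, matching how per-replicate point clouds are usually
plotted. A deterministic sign convention (each loading's largest-|value|
element made positive) makes score signs reproducible across platforms.

Three readouts mirror how such studies report discrimination:

* **Side tables**: per group, the fraction of samples with a strictly
  positive score on a PC. "Clean separation" means every group is
  sign-homogeneous, i.e. the PC induces a bipartition of groups with no
  sample on the wrong side. A score of exactly zero counts as nonpositive
  (documented tie-break; it cannot occur generically).
* **Quadrants**: the sign pair of two chosen PCs, with the standard
  mathematical convention Q1=(+,+), Q2=(−,+), Q3=(−,−), Q4=(+,−). Published
  quadrant descriptions of this kind are occasionally internally
  inconsistent (the same sign pair attributed to two quadrants); we fix the
  mathematical convention rather than attempt to resolve such slips.
  On-axis samples (a zero score) are flagged and excluded from group purity.
* **Loading peaks**: local maxima (side "positive") and minima (side
  "negative") of a loading profile, kept when |value| ≥ `min_prominence`
  (default 0.1) times the loading's maximum |value|, sorted by |value|.
  On second-derivative spectra an absorbance band characterizing the
  negative-score groups appears as a loading minimum, so both sides carry
  information. Peaks are annotated from a packaged band-assignment table
  (centers, vibrational modes, biomolecule classes for the three regions),
  matched to the nearest entry within 8 cm^-1 (the nominal instrument
  resolution), ties toward the lower wavenumber.

## Intensity ratios

On a second derivative, an absorbance maximum is a negative lobe, so "peak
intensity" is the magnitude of a second-derivative minimum. Three
dimensionless ratios are computed per spectrum:

* CH2/CH3 = I(~2922) / I(~2959) — lipid acyl chain length;
* carbonyl/total lipid = I(~1747) / (I(~2922) + I(~2851)) — lipid
  peroxidation (ester C=O against the saturated CH2 bands);
* unsaturated/saturated = I(~3013) / (I(~2922) + I(~2851)) — acyl chain
  double-bond content.

The estimator searches a ±15 cm^-1 window around each literature target
(wide enough to track the ~9 cm^-1 group-dependent shifts of the CH2
asymmetric stretch without capturing neighboring bands), takes the local
minimum below zero *nearest* the target, and reads the magnitude from the
vertex of a least-squares parabola over ±3 grid points around it. Two
details are deliberate. Nearest-selection (rather than deepest-in-window)
measures the band that is actually at the assignment, and under noise it
avoids the systematic upward bias of picking the deepest excursion in the
window. The parabola vertex averages ~7 filtered points, suppressing point
noise while changing a clean band minimum by well under 1%. Whether the
original workflow measured at the fixed literature wavenumber or at the
located extremum is unstated; the located-extremum rule is used so that a
shifted band is measured at its true center. A band that is genuinely
absent raises a "no peak" error rather than silently contributing zero; a
zero numerator must be requested explicitly (`allow_zero`).

All three ratios are invariant under positive scaling of the spectrum, so
they are unaffected by normalization choices.

## Statistical battery

All tests are two-sided; significance is declared at p ≤ 0.05 (≤, not <,
following the published convention).

* **Normality screen**: D'Agostino K² (skewness z by D'Agostino 1970,
  kurtosis z by Anscombe–Glynn 1983, K² = Z1² + Z2² ~ χ²(2)), with a
  parametric/nonparametric recommendation. With n < 8 the transforms are
  unreliable and the screen returns an "insufficient n" result. The screen
  informs but does not gate: the nonparametric branch is always available.
* **Kruskal–Wallis** omnibus across groups (midranks, tie-corrected,
  χ²(k−1) reference), via `stats::kruskal.test`.
* **Many-to-one rank post hoc**: the published workflow names a parametric
  many-to-one procedure after a rank omnibus, which is statistically
  incoherent as printed; the rank analogue (Dunn-type z on pooled midranks
  with tie correction) preserves the many-to-one intent. Family control
  over the k−1 comparisons is Bonferroni (default) or Šidák.
* **Mann–Whitney U** for pairwise comparisons, U = min(U_x, U_y); the exact
  null distribution for tie-free samples with both sizes ≤ 8, otherwise a
  tie-corrected normal approximation with continuity correction. An exact
  request on tied data falls back to the normal path with a recorded
  notice.
* **Welch's t** for peak-intensity comparisons, with Welch–Satterthwaite
  degrees of freedom.

Replicates enter as observations by default (`pool_replicates = TRUE`),
matching per-replicate reporting; averaging replicates per sample first is a
config switch. With few samples per group, replicate-level observations
within a sample are correlated through the shared biological draw, which
rank tests do not model — the null scenario below is therefore defined with
no between-sample variability, where observations are exchangeable.

## The synthetic cohort generator

Each spectrum is a sum of Gaussian bands plus a quadratic baseline plus
i.i.d. Gaussian noise:

`A(x) = sum_i a_i exp(-(x - c_i)^2 / (2 s_i^2)) + b0 + b1 x + b2 x^2 + e`.

Gaussian band shape (rather than Voigt) is chosen because its second
derivative has the closed form `a ((d^2/s^4) - 1/s^2) exp(-d^2/(2 s^2))`,
giving analytic ground truth for the Savitzky–Golay estimates and for every
ratio. The default grid is 4000–600 cm^-1 at 2 cm^-1 spacing — finer than
the 8 cm^-1 nominal instrument resolution, so derivative discretization
error stays below test tolerances. Three replicates per sample are
generated, as in the emulated acquisition protocol.

Biological variability acts on amplitudes only: per sample, each band
amplitude is drawn once from a lognormal with mean equal to the nominal
amplitude and coefficient of variation `amplitude_cv` (default 0.10), and
shared across that sample's replicates; baseline coefficients and noise are
redrawn per replicate. Center jitter is deliberately off by default to keep
peak-location tests sharp. Baseline coefficients are drawn uniformly from
ranges producing drifts up to ~0.1 AU across the range — large against the
band structure, so baseline correction is genuinely exercised — while the
curvature's second-derivative contribution (2·b2 ≈ 1e-8 AU·cm^-2) is
negligible against band curvature, as for real smooth drifts. The noise sd
defaults to 2e-4 AU, the 100%-line noise scale of a benchtop diamond-ATR
instrument averaging 64 scans, relative to an amide-I amplitude of 1.

Three scenarios encode the study designs the analysis must handle. The
group effects are not quantified by the emulated study, so they are fixed
here, once, to encode its qualitative contrasts at what we consider
realistic effect sizes:

* **coriell** (control, DM1_1000, DM1_2000; 2 samples × 3 replicates per
  group): DM1_2000 carries the CH2 asymmetric stretch at 2916 instead of
  2925 cm^-1, CH3 asymmetric at 2953, CH2 symmetric at 2849, an elevated
  amide-I parallel β-sheet band at 1628 (0.40 vs 0.22), a reduced ester
  carbonyl (0.055 vs 0.10) and shifted carbohydrate/nucleic-acid weights;
  DM1_1000 differs from control by an elevated carbonyl (0.135 vs 0.10).
  The resulting group ordering of the carbonyl/total-lipid ratio
  (DM1_1000 > control > DM1_2000) makes all three pairwise contrasts real.
* **neurolab** (control plus five age-of-onset groups): the severe-onset
  groups (jDM1, iDM1, cDM1) carry elevated CH2/CH3 amplitudes with centers
  at 2919/2851, and iDM1/cDM1 additionally an elevated carbonyl.
* **null**: three groups with identical band tables and `amplitude_cv = 0`.
  This is the type-I calibration condition: with no between-sample
  variability every replicate-level observation is exchangeable, which is
  exactly the null the rank tests assume.

The generator emulates band positions/amplitudes, replicate structure,
smooth baselines and white noise. It does **not** emulate water-vapor and
CO2 lines, ATR penetration-depth wavelength dependence, scattering
distortions, detector nonlinearity, or center shifts from chemical
environment. Passing tests therefore demonstrate that the analysis recovers
the structure this model generates — not that it is robust to every
artifact of real instruments.

## Numerical choices and problem sizes

* Grid storage is ascending; descending text exports are auto-reversed.
  Shared-grid equality tolerance is 1e-6 cm^-1 (text round-trip noise).
  Resampling is linear (standard and monotone-safe on dense FTIR grids).
* SG defaults: half-width 3 (7-point window), polyorder 4, derivative
  order 2, for the reasons above.
* The type-I calibration experiment uses 5000 null cohorts with 3 samples ×
  3 replicates per group (9 observations per group). At 6 observations per
  group the χ² reference for Kruskal–Wallis is intrinsically conservative
  (exact rejection ≈0.042 at nominal 0.05, by 200k-rep Monte Carlo of the
  rank statistic itself), which would measure the χ² approximation rather
  than the implementation; at 9 per group the exact rate is ≈0.046.
* Discrimination and power frequencies use 100 cohorts; ratio-recovery
  checks use 50 noise seeds per amplitude ratio. The `analysis/` drivers
  run reduced versions (500/25) for quick desk runs; the test suite and
  `scripts/acceptance.R` run the full versions.
* The published preprocessing description mentions a "duplicated matrix"
  after normalization; this is an artifact of the acquisition software's
  workflow and is not reproduced (no row duplication).

## Known limitations

* Band assignment is nearest-neighbor within a tolerance; overlapping
  assignments at 3 cm^-1 spacing (e.g. the amide-II cluster) resolve to the
  closest table entry, which may not be the biologically intended one when
  a band shifts by more than half the entry spacing.
* The many-to-one z uses the large-sample normal reference; at 2–3 samples
  per group its p-values are approximate (the omnibus carries the
  calibrated inference).
* `pool_replicates = TRUE` treats correlated replicates as observations
  when `amplitude_cv > 0`; between-group inference on tiny cohorts should
  be read as descriptive of the simulated design, as in the emulated study.
* The PCA quadrant readout is reported for the leading PC pair; the
  emulated study occasionally reports other pairs (e.g. PC-1/PC-3), which
  `quadrant_assign(pca, i, j)` supports directly.
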