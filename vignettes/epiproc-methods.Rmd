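---
title: "Methods: single-subject FMRI processing with epiproc"
author: "epiproc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-subject FMRI processing with epiproc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`epiproc` processes a single subject's echo-planar (EPI) FMRI time series
from raw volumes through a general linear model (GLM), with an integrated
quality-control battery.  The design follows the two-stage philosophy of
modern pipeline tools: a compact block+option *specification* is compiled
into a fully resolved *execution plan*, which can be rendered as a
commented, runnable script (carrying the generating command verbatim and
every resolved default) or executed directly.  Both routes call the same
stage executor, so the script is provenance, not a reimplementation.

The processing stream is built from *blocks*.  Automatic blocks (`setup`,
`tcat`, `outcount`, `QC_review`) always run; default blocks (`tshift`,
`volreg`, `blur`, `mask`, `scale`, `regress`) form the standard stream;
optional blocks (`despike`, `ricor`, `align`, `tlrc`, `combine`, `empty`)
are added by the user, except that multi-echo input adds `combine`
implicitly.  `despike` and `ricor` run before `tshift` because slicewise
physiological regressors must meet the data on its original slice grid;
when both are present we order `despike` before `ricor`.  Surface
processing, nonlinear warping, blip/B0 distortion correction and
echo-level denoising beyond optimal combination are out of scope;
requesting them is a loud error, never a silent ignore.  Alignment to
anatomy and to a final space is supported through user-supplied affine
matrices (estimated elsewhere); the package estimates only the rigid
motion transforms itself.

# Data model and conventions

A `volume4d` carries the intensity array (x, y, z, t), the spatial grid
(0-based voxel indices, RAS world mm, 4x4 affine), the repetition time TR
in seconds, per-slice acquisition times in `[0, TR)`, run lengths, and a
units tag that records the meaning of the values (`raw`, `percent`,
`correlation`, `tsnr`, `statistic`).  Motion parameters use the fixed
column order (roll, pitch, yaw, dS, dL, dP) — rotations in degrees about
the z, x and y world axes, then mm translations along z, x, y — matching
the standard 6-column motion file layout.  Only NIFTI-1 is supported on
disk; a 4D file with a zero header TR is read with TR set to 1 s plus a
warning, so a broken header surfaces without stopping a batch.  Every
written NIFTI/column/JSON artifact carries a version-stamped provenance
note; a fixed timestamp option makes renders byte-identical.

# Stage-by-stage methods

**Outlier counting.**  Each voxel's run is detrended with the per-run
baseline polynomial; a time point is an outlier where the residual
magnitude exceeds `k * MADN` of that voxel's residuals, with
`MADN = 1.4826 * median|resid|` and `k = qnorm(1 - 0.001/2) ~ 3.29` (a
two-sided 0.001 Gaussian tail).  The per-volume outlier *fraction* is the
share of in-mask voxels flagged.  This fraction drives both the
minimum-outlier registration reference (argmin, ties to the earliest
index) and outlier-based censoring.

**Pre-steady-state check.**  Leading volumes whose in-mask mean exceeds
the run's robust level (median + 2 MADN of the last 80% of volumes) are
flagged; a flag that survives `tcat` trimming becomes a warning in the
report, since T1-saturated volumes inflate baselines.

**Slice-timing correction.**  Each slice's series is shifted by
`(align_to - slice_time)/TR` samples with linear, Keys cubic, or
Hann-windowed sinc interpolation (half-widths 5 or 9), edge-held at run
boundaries.  On a known sinusoid the sinc kernels hold mid-series phase
error well under one degree.

**Rigid motion estimation.**  Each volume is registered to the reference
by minimising the mean squared intensity difference under a 6-parameter
rigid transform — least squares is appropriate because all volumes share
one EPI contrast.  Three choices matter and are deliberate:

1. *Pre-smoothing*: both images are blurred (default FWHM twice the mean
   voxel size) before the cost is evaluated, so the cost surface is wide
   enough to capture whole-voxel displacements.
2. *Symmetric resampling*: the cost compares the moving volume resampled
   through the half-transform against the reference resampled through the
   inverse half-transform.  A one-sided cost smooths only the moving
   image, which rewards the identity transform on sharp-edged data; the
   symmetric form cancels that bias.
3. *Search*: Nelder–Mead on a 2x mean-pooled grid warm-started from the
   neighbouring volume, then a restarted Nelder–Mead polish at full
   resolution evaluated on up to 4000 signal-bearing voxels.

On the standard 32x32x20 phantom, injected transforms within +/-5 mm and
+/-5 degrees are recovered with median absolute error below 0.1 mm and
0.2 degrees.

**Single-step resampling.**  The per-volume motion transform, the
EPI-to-anatomical affine and the anatomical-to-final affine are composed
into one coordinate map and applied with a single interpolation per voxel
(trilinear, cubic, or windowed sinc).  Sequential application smooths the
data at each step; on a delta image the one-step route always preserves
at least as high a peak, which the tests assert.  The default output grid
is the input grid; `volreg_warp_dxyz = "auto"` selects an isotropic grid
at the minimum input voxel dimension truncated to 0.1 mm.

**Multi-echo combination.**  Per voxel, log mean signal is regressed on
echo time to give T2* (clamped to 2–300 ms; voxels with non-positive
means are marked invalid and averaged uniformly) and S0; echoes are
averaged with weights `TE_i * exp(-TE_i / T2*)`, normalized to sum to 1 —
the BOLD-contrast-optimal combination.  Only this "OC" method (and a
plain mean) is provided; component-based echo denoising is out of scope.

**Masking and scaling.**  The EPI automask thresholds the temporal mean
at a two-class (Ridler–Calvard) clip level, keeps the largest 6-connected
component and fills holes; it may be intersected with an anatomical mask.
The mask is *never* multiplied into the data — QC maps are computed over
the full field of view so ghosts and artifacts outside the brain stay
visible; the mask only scopes summary statistics.  The scale block maps
each voxel's run to percent of its run mean, capped at 200, after which
GLM effect estimates are in BOLD percent signal change.  On cap-free
voxels the scaled run mean is exactly 100 and rescaling is a no-op.

**Physiological regressors.**  Cardiac phase advances linearly from 0 to
2*pi between detected heartbeats; respiratory phase uses the
amplitude-histogram transform signed by the trace derivative (the
literature names the construction but not one canonical formula; both
choices are stated here as the package's conventions).  `sin(k phi)` and
`cos(k phi)` for k = 1..2 per trace, evaluated at each slice's
acquisition time, give the 8 slicewise regressors; respiration volume per
time (breathing envelope over period) interpolated to volume times and
delayed by 0, 5, 10, 15, 20 s gives the 5 volumetric columns.  The shift
set is a convention chosen to realize the standard column count, not a
published constant.  At the ricor stage these are projected out of the
data slice by slice, and their count is carried into the DF ledger.

**Regression.**  The design matrix is assembled from category-tagged
parts: per-run Legendre-style baseline polynomials (orthonormalized on
the sample grid; automatic order `1 + floor(run_seconds / 150)`), motion
parameters (per-run demeaned and/or their backward differences,
optionally block-diagonal per run), ROI principal components (after a
one-voxel erosion), stimulus regressors, and — when requested — bandpass
sine/cosine pairs at every DFT frequency outside the keep band (band
edges inclusive; Nyquist contributes a cosine only; the constant belongs
to the baseline).  Implementing the filter as regressors makes its
degrees-of-freedom cost explicit: the predicted fractional loss is
`1 - 2 TR (ftop - fbot)`, which is 60% at TR = 2 s and 80% at TR = 1 s
for the standard 0.1 Hz band — and the tests verify that projecting the
columns out equals FFT band rejection to 1e-8 RMS on an uncensored run.

HRF bases: `BLOCK(d)`/`dmUBLOCK` convolve a d-second boxcar with the
impulse response `(t/4)^4 exp(4 - t)` and are normalized so a 1 s event
peaks at exactly 1 (longer events rise toward the basis ceiling);
`GAM(p, q)` (defaults 8.6, 0.547) peaks at exactly 1 at `t = p q`;
`SPMG1` is the peak-normalized difference-of-gammas; `TENT(b, c, n)` is a
partition-of-unity triangular set.  Stimulus types: `time` (sum of event
responses), `AM1` (response scaled by the married modulator), `AM2`
(unmodulated column plus mean-centred modulator columns; centring uses
the within-class event mean), `IM` (one column per event).  Per-event
durations reshape `dmUBLOCK` responses.

**Censoring.**  A volume is censored when its Enorm — the L2 norm of the
motion-parameter first difference, degrees and mm combined unscaled,
hence "approximate mm" — exceeds the threshold (censoring both flagged
time points, since the metric is a difference), or when its outlier
fraction exceeds its threshold (that volume only).  Censored rows are
*deleted* from the solve, not zero-weighted, so bandpassing, censoring
and regression happen in one consistent model; the identity "row deletion
equals refitting with those rows replaced by the model's own prediction"
is asserted on toy cases.  Enorm is computed on raw parameters (before
any demeaning).

**GLM.**  Ordinary least squares per voxel via QR, with t statistics per
coefficient and a full-model F against the baseline-only model.
Slicewise physio columns are substituted per slice at solve time.
`whiten = "ar1"` estimates a single lag-1 residual autocorrelation pooled
over mask voxels (runs separately), prewhitens rows with weights
`(1, -rho)` (first row scaled by `sqrt(1 - rho^2)`), and refits — a
two-pass AR(1) approximation to generalized least squares, applied before
censored-row deletion; full ARMA likelihood modelling is intentionally
not attempted.  The DF ledger records total, censored, per-category and
remaining degrees of freedom exactly (warn below 30% remaining; error at
or below zero), and the model warnings check stimulus collinearity
(|r| > 0.4 medium, > 0.7 severe), overall censor fraction (> 0.1),
per-class censor-event overlap (> 50% of events), unremoved
pre-steady-state volumes and DF overuse.  The censor-fraction warning
thresholds are the package's own choices.

# Quality control

Scalar metrics and maps are computed unmasked: TSNR (baseline-fitted mean
over residual sd; 0 where the residual is numerically constant), radial
correlation (each voxel against the Gaussian-weighted neighbourhood
average, default 20 mm half width at half maximum), GCOR (the mean of the
full pairwise correlation matrix, computed as the squared norm of the
mean unit-variance series; verified against the brute-force mean on small
instances), ROI-average and seed correlation maps (censor-aware; three
shipped template-space seeds when a template is declared, otherwise two
central left-right offset seeds), through-plane variance lines (median
in-mask column variance against robust centre + 4 MADN — a ratio test,
invariant to global scaling), and a TSNR/shape table per ROI (voxel
count, zero-count, maximum 6-connected erosion depth, TSNR quantiles,
with shape and low-TSNR warnings).

For cross-modal alignment QC the local Pearson correlation cost
partitions the FOV into ~8 mm patches and averages `-rho |rho|` weighted
by patch size: identical images score -1, contrast-reversed +1.  The
patch scheme is this package's concretization of the named cost family,
validated behaviourally (the left-right flip check must separate mirrored
from unmirrored anatomy on 20/20 constructed pairs) rather than by
numeric equality with any external implementation.  The flip check
aligns the anatomical and its x-mirrored copy to the EPI reference with
a small rigid search and compares costs; differences under 0.02 are
`inconclusive`, which a perfectly symmetric brain forces by construction.

The static HTML report has sections `vorig`, `ve2a`, `mot`, `regr`,
`warns`, `radcor`, `qsumm`.  Statistical overlays use transparent
thresholding: below threshold, opacity rises linearly with
|stat|/threshold (the transfer function is our choice and is stated
here); above, the overlay is opaque.  The motion plot draws the censor
threshold line and shades censored intervals.  The report is fully
static; the rating widget is rendered inert.  Scalars are duplicated into
the machine-readable uvars JSON (flat, sorted keys) and the basic-review
text, and `review_table()` aggregates uvars files across subjects with
optional outlier criteria.

# The phantom generator

`make_phantom()` builds an ellipsoidal three-shell "brain" (CSF rim,
grey shell, white core) with tissue S0 and T2*, a smooth random texture
field (default sd 10% of S0 — real tissue is heterogeneous, and a
textureless ellipsoid is rotationally symmetric, which would make
rotation recovery and the flip check degenerate), and signal
`S0 exp(-TE / T2*)` per echo.  Defaults mirror a typical acquisition:
32x32x20 grid of 3x3x4 mm voxels, TR 2.2 s, 150 volumes, sequential
ascending slice timing, echo times 12.5/27.6/42.7 ms when multi-echo,
noise sd 1.25% of baseline (TSNR ~ 80), motion random walks bounded at
1 mm/degree, 0.5% polynomial drift.  Optional ingredients: task responses
at stated percent amplitudes evaluated at each slice's true acquisition
time, physiological sinusoids with slice-dependent phase (strongest in
the CSF rim), multiplicative spikes, leading pre-steady-state
brightening, and a half-FOV ghost replica for the unmasked-QC tests.
Motion is injected with the package's own resampler; everything injected
is returned as ground truth.

What the phantom does *not* emulate: anatomical texture at realistic
spatial spectra, k-space sampling and EPI distortion, spatially varying
coil sensitivity, physiological noise beyond sinusoids, and non-rigid
motion.  Passing tests therefore demonstrate internal correctness and
recovery of known effects under controlled conditions — not performance
on real scanner data.

# Numerical choices and test scale

Interpolation kernels: trilinear (fast path; a sample whose full support
leaves the volume is zero), Keys cubic (a = -0.5), Hann-windowed sinc of
half-width 5 or 9 voxels with weight renormalization so constants are
preserved.  Blur uses reflective boundaries, which conserves total
intensity exactly.  Connected components are 6-connected; erosion depth
uses the same neighbourhood.  Registration injections in tests use the
cubic kernel: injecting with trilinear leaves the moving volume
once-smoothed relative to the reference, which biases any
intensity-difference optimum by a few tenths of a degree — an artifact
of test construction rather than of the estimator.  Tie-breaks: the
minimum-outlier reference takes the earliest index; band edges belong to
the keep band.

The default test suite runs phantoms of 6–80 volumes on 32x32x20 (and
24x24x14 for the flip battery) — sizes chosen so the full suite with its
registration and end-to-end pipeline runs completes in a few minutes on
one core while keeping every recovery property measurable at its stated
tolerance.

# Known limitations

Rigid-only motion model; affine-only (and externally supplied) anatomical
and template alignment; AR(1) rather than full REML serial-correlation
modelling, applied before row deletion; RETROICOR phase conventions as
stated above; NIFTI-1 slice-timing encoding limited to standard patterns;
the lpc patch cost is a variant, not a byte-compatible reimplementation;
the HTML report is static.  These boundaries are deliberate: each is
either scientifically secondary to the single-subject stream implemented
here or belongs to specialised external tooling.
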