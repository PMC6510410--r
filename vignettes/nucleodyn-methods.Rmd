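---
title: "Methods: models, parameters and design choices in nucleodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in nucleodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleodyn)
```

`nucleodyn` quantifies where a GFP-tagged nuclear protein sits relative to
chromatin landmarks and how fast it moves, from two kinds of raw data:
multi-channel fluorescence images (DAPI, GFP, and immunolabeled histone
marks H3K4me3 / H3K9me3) and FRAP movies or traces. Because studies of this
kind rarely deposit raw images, the package pairs every analysis stage with
a seeded simulator that generates data with known ground truth. This
vignette documents the models, the parameters that matter, and the design
decisions taken where the underlying procedures are conventionally left
unspecified.

## Per-cell Pearson colocalization

The colocalization measurement follows the standard confocal workflow:

1. **Nuclear masking.** The DAPI channel is Gaussian-smoothed
   (`smooth_sigma`, default 2 px), thresholded by Otsu's method, holes are
   filled, objects smaller than `min_area_px` (default 200 px) and objects
   touching the image border are discarded, and the remainder is labeled.
   Otsu was chosen because it is parameter-free; the smoothing sigma only
   needs to exceed the noise grain, and results are insensitive to it over
   1–4 px for nuclei tens of pixels across.
2. **Background subtraction.** A single scalar background — the median
   intensity over all extra-nuclear pixels — is subtracted from each
   channel and the result clipped at zero. The median is robust to the
   bright minority of cytoplasmic or debris pixels outside nuclei. The
   operation is idempotent: a second pass subtracts zero.
3. **Per-cell Pearson ρ.** For each labeled nucleus and each requested
   channel pair, ρ is the ordinary product-moment correlation over the
   nucleus's pixels. A phrase sometimes used for this procedure — that the
   ROI in each channel is "summed" for the correlation — is read here as
   *collecting* the per-pixel values within the ROI; computing a
   correlation from one summed scalar per channel would not yield a
   per-cell ρ at all, so the per-pixel reading is the only self-consistent
   one. Nuclei in which a channel has zero variance get `NA` with a
   warning and are excluded from population statistics rather than scored
   0, which would bias population means toward zero.

ρ is invariant under positive affine rescaling of either channel, so gain
and offset differences between detectors do not affect it; this is asserted
to 1e-12 in the test suite, along with exact +1 / −1 anchors for identical
and affinely inverted channels.

**Calibration ceiling.** Even perfectly colocalized labels do not reach
ρ = 1 in a real instrument, because the two detection channels add
independent noise. `calibration_ceiling()` quantifies this with a
double-label design: one structure imaged through two channels differing
only in gain and noise (`simulate_double_label()`). For additive Gaussian
noise of sd σ on a structure of pixelwise sd *s*, the expected ceiling is
*s*²/(*s*² + σ²): 1 at zero noise, decreasing monotonically with σ.
`double_label_noise_for_ceiling()` inverts this identity to produce the
noise level for any target ceiling; the default target of 0.70 matches the
ceiling typically reported for confocal double-secondary calibrations. The
ceiling's numeric value is a property of the noise model, so the package
demonstrates it rather than asserting a particular number.

**Brightness QC.** `rho_vs_intensity_qc()` regresses per-cell ρ on
per-cell mean intensity (OLS with a 95% CI on the slope). A slope
indistinguishable from zero indicates the measured colocalization is not
an artifact of expression level or staining intensity.

## Puncta segmentation and GFP overlap

High-resolution imaging shows H3K4me3 concentrated in discrete puncta.
`segment_puncta()` detects them per nucleus as 4-connected components of
pixels above a robust threshold, size-filtered at `min_area_px` (default
4 px). The threshold is median + *k*·spread with *k* = 3, where the spread
is the larger of the normal-scaled MAD and the mean absolute deviation
about the median. The second term matters for sparse bright signal on a
near-flat background: there the MAD collapses toward zero and would let
the faint blur tails of the puncta merge into single components.
4-connectivity splits touching puncta more conservatively than
8-connectivity. Published analyses of this kind typically outline puncta
by hand; the threshold rule is therefore a package choice, exposed via
`k`.

`gfp_positive_mask()` applies the same rule to the GFP channel to decide
which pixels "contain GFP label", with one special case: a nucleus whose
GFP signal has no spread at all is treated as uniformly labeled (all
positive pixels count), since enrichment against the nucleus's own
distribution is meaningless for a flat signal. `overlap_fractions()` then
scores, for each punctum, the fraction of its pixels inside the GFP mask,
and histograms the fractions in ten fixed bins of width 0.1.

## FRAP: normalization and kinetics

A FRAP measurement bleaches a small circular spot in the nucleus and
follows its fluorescence recovery. Two instrumental effects contaminate
the raw spot intensity: the whole cell dims from acquisition
photobleaching, and the bleach itself destroys part of the nuclear
fluorophore pool. Both are corrected by the whole-nucleus ratio

$$R(t) = \frac{A_o \, I_t}{A_t \, I_o},$$

where \(I\) is the bleach-spot intensity, \(A\) the whole-nucleus
intensity, and the subscript \(o\) denotes the prebleach frame. Any
multiplicative loss applied equally to spot and nucleus cancels exactly
in \(R\) — the test suite checks this both analytically and on simulated
movies with a global gain change.

The normalized recovery is fit with the one-component exponential

$$R(t) = P - (P - R_0)\,e^{-k t},$$

with a free post-bleach intercept \(R_0\) (recovery captured within the
bleach frame makes real curves intercept above the bleach depth), plateau
\(P\) and rate constant \(k\). Bounds are \(k \in (0, 100]\) s⁻¹ and
\(0 \le R_0 \le P \le 1.5\); initial guesses are \(R_0\) = first point,
\(P\) = mean of the last five points, \(k = \ln 2 / t_{1/2}\) from the
observed half-rise. Fitting uses Levenberg–Marquardt least squares
(unweighted, the standard curve-fit workflow). **Percent recovery** is
defined as \(100 \times P\) — the plateau of the prebleach-normalized
curve — which is the definition under which a freely mobile protein shows
"essentially complete recovery" near 91%; the classical mobile fraction
\((P - R_0)/(1 - R_0)\) is reported as a secondary column. Time is zero
at the first post-bleach frame and the prebleach frame is excluded from
the fit.

Multi-trial designs are aggregated two ways, both reported: per-trial
curves are averaged pointwise and fitted once per trial (giving mean ±
SEM of \(k\) and percent recovery over trials, with SEM suppressed below
three trials), and the trial-mean curves are averaged again into one
condition-level curve that receives a single fit. The SEM convention is
trial-level throughout: variability is measured across independent
trials, never across pooled cells.

`bleach_depth_qc()` computes each trace's first-post-bleach-to-prebleach
spot ratio and compares two conditions by t-test; equal bleach depths
justify attributing kinetic differences to the protein rather than to the
bleach.

## The synthetic-data generator

The simulator emulates the statistical structure the analyses assume,
not optical physics. Per nucleus it draws an ellipse (mean radius
`nucleus_radius_px` = 24 px at 0.1 µm/px, ±10% jitter per axis), places
heterochromatin as a peripheral rim plus 3–8 random interior blobs
(target fraction 0.35 of nuclear area, split ~60/40 rim/blobs), and
renders four channels: DAPI bright over heterochromatin and dim over the
interchromatin space; H3K9me3 following the heterochromatin pattern;
H3K4me3 as Gaussian puncta (σ = 1.5 px, default 10 per nucleus, minimum
separation 10 px) whose centers are sampled only from DAPI-poor pixels;
and GFP splitting its nuclear mass between a uniform DAPI-poor pool
(with partial leak into heterochromatin, `gfp_het_leak`) and the puncta,
in proportion to `gfp_puncta_association`. A dim cytoplasmic annulus
(`gfp_cytoplasm_fraction`) emulates the extranuclear pool, which nuclear
masking excludes from all analyses. All channels receive Gaussian PSF
blur (σ = 1.1 px confocal-like, ~0.45 px SIM-like) and channel-independent
Poisson shot noise (`poisson_scale` photons per intensity unit, default
200) plus Gaussian read noise (sd 0.01). Magnitudes for heterochromatin
domain size and puncta density are not constrained by published
measurements; the defaults are chosen to look like confocal images of
pre-B cell nuclei and are free parameters, not claims.

A design point worth recording: the simulated H3K4me3 channel is *purely*
punctate. An earlier draft added a diffuse euchromatin base to it, but
then the GFP channel — itself a mixture of a uniform zone term and a
puncta term — aligned best with H3K4me3 at an intermediate association
value, making mean ρ peak mid-sweep. With a purely punctate target the
GFP mixture moves along a straight path toward the H3K4me3 pattern as
association grows, and mean ρ (and the puncta overlap fraction) is
provably nondecreasing in `gfp_puncta_association` — the property the
construct comparisons rely on. This matches the superresolution
observation that H3K4me3 is localized to puncta.

`pda_mode` emulates histone-demethylase inhibition: puncta count and
amplitude scale up by 1.5 (raising total H3K4me3 signal and leaving
H3K9me3 untouched), and a *nonzero* `gfp_puncta_association` is
multiplied by 1.25 (capped at 1) as a proxy for PHD-dependent binding of
the enlarged H3K4me3 pool. The unfused-GFP preset (association 0) is
structurally unaffected. Limitation: the simulator keys PDA
responsiveness to nonzero association only, so the Core preset
(association 0.25) responds to PDA even though a real PHD-less core
truncation does not; emulating that distinction would require a separate
PHD-competence flag.

Construct presets (`nucleus_preset()`) order the association strengths
T490A (0.60) > FL (0.30) ≈ W453A,T490A (0.30) ≈ Core (0.25) ≫ GFP (0),
with the GFP control given high heterochromatin leak (0.85) and a large
cytoplasmic fraction (0.5) to produce near-homogeneous labeling. These
are qualitative-ordering choices, not measured values.

The FRAP simulator works in the normalized-recovery domain: the true
curve is \(R(t) = P - (P - B)e^{-kt}\) with plateau \(P\)
(`plateau_true`), bleach depth \(B\) and rate `k_true`. Raw series are
then constructed so that the whole-nucleus total is reduced by the
destroyed fluorophore mass and both series decay multiplicatively by
`acquisition_decay_per_frame` (default 0.2% per frame), applied
identically to spot and nucleus so that the ratio correction is exactly
valid — a uniform-illumination assumption. Gaussian noise is added with
sd `noise_sd` on the spot (in prebleach-spot units) and
`noise_sd * sqrt(spot_area/nucleus_area)` relative on the nucleus total
(area averaging). The condition presets
(`frap_condition_presets()`) use published pre-B-cell kinetics for the
four GFP-RAG2 constructs — k of 1.6, 0.8, 1.9 and 1.8 s⁻¹ with plateaus
0.90–0.91 — and simulator-chosen bleach depths of 0.30 (0.25 for the slow
mutant, whose slower exchange captures less recovery within the bleach
frame, giving it the lower intercept real curves show). The movie
simulator renders the same model spatially (uniform nucleus, one
prebleach frame, spot pixels following the recovery while the remaining
pixels carry the conserved balance), so the trace measured from a
noise-free movie equals the trace-level output to numerical precision.

One consequence of defining `bleach_depth` in the normalized domain: the
raw post-bleach spot intensity carries a factor
\((N - (1-B)m)/N\) (nucleus area \(N\), spot area \(m\)) — the remaining
pool's concentration — so it depends weakly on nucleus size. The tests
therefore verify area scaling against the analytic area integral rather
than assuming raw spot intensities are size-free.

All randomness flows from one integer seed per simulation call, with
derived sub-streams per nucleus and per trace so that outputs are
bit-reproducible and stable under changes in `n_nuclei` or trace count.

## Statistics and reporting

Group comparisons use the two-tailed Student's t-test (pooled variance)
by default, matching the convention of the studies this package serves;
Welch's variant is available via `var.equal = FALSE`. Star annotations
follow the standard four cut points (**** < 0.0001, *** < 0.001,
** < 0.01, * < 0.05, otherwise ns), implemented as a pure step function.
No multiple-testing correction is applied — comparisons are annotated
pairwise, which is a documented limitation, not an oversight. SEMs are
computed over trial means (≥ 3 trials; suppressed with a warning below
that).

## Numerical choices and degenerate inputs

* Pixel coordinates are (row, col) with pixel centers at integer
  positions; line profiles (`line_profile()`) sample at unit-pixel
  spacing by bilinear interpolation, which is exact on linear ramps.
* A blank DAPI image yields an empty mask, not an error; an empty mask
  propagates as empty record tables and empty puncta sets.
* Constant recovery traces are flagged non-converged and excluded from
  summaries; fits require ≥ 10 post-bleach points.
* A mask covering the whole image leaves no background pixels and is an
  error; non-positive whole-nucleus intensities during normalization
  signal segmentation failure and are an error.
* TIFF pages must lie in [0, 1], so multi-channel images are stored as
  32-bit float pages scaled by per-channel maxima recorded in a JSON
  sidecar together with channel names and pixel size; round trips are
  exact to float32 precision. Label masks are stored as 16-bit TIFF.

## Problem sizes used in the shipped checks

The validation suite runs entirely on simulated data at sizes a desktop
reproduces in minutes: colocalization sweeps use 20 nuclei of radius
22 px in 360 × 432 px fields; FRAP checks use the standard sampling
design of 0.1 s × 60 frames, 10 cells × 3 trials, with noise sd 0.03 and
0.2% per-frame acquisition decay; estimator-bias checks use 200
replicates of that design per rate constant; the bleach-depth type-I
check uses 100 runs of 6 + 6 traces.

## What passing tests do and do not show

The simulator reproduces the *statistical structure* the analyses
assume: anti-correlated chromatin compartments, punctate H3K4me3, a
tunable GFP–puncta association, exponential FRAP recovery with
multiplicative acquisition decay. It does not model optics (no real PSF
shape, no SIM reconstruction artifacts), 3D structure, chromatin polymer
behavior, photophysics (blinking, reversible dark states), or
reaction–diffusion FRAP kinetics. Passing tests therefore demonstrate
that the pipeline measures correctly *given* those assumptions — they
cannot certify segmentation performance on real images with debris,
uneven illumination or clumped nuclei, nor that a one-component
exponential is the right kinetic model for any particular protein.
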