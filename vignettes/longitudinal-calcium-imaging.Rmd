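---
title: "Methods: longitudinal two-photon calcium imaging analysis with longca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal two-photon calcium imaging analysis with longca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longca)
```

# Scope

`longca` implements the analysis chain used to follow the same cortical
neurons across imaging sessions weeks apart with a multi-plane two-photon
microscope: cross-day 3-D field alignment on a structural (nuclear) channel,
cell-mask detection and seeded trace extraction on the functional
(calcium-indicator) channel, AR(1) transient deconvolution and component
screening, moving-percentile ΔF/F, assignment-based cross-session cell
matching, trial-aligned activity maps for a virtual-reality T-maze task, and
watershed particle counting for glial immunostains. A synthetic-data
generator with full ground truth stands in for animal data so that every
stage is verifiable at desk scale.

# Cross-day 3-D alignment

**Model.** Between sessions the imaged field moves rigidly by an unknown
`(dx, dy, dz)` relative to the objective. The structural channel is a
nuclear marker whose image content is stable across weeks, unlike calcium
fluorescence.

**Procedure.** A structural stack is acquired at objective offsets +30 to
−30 μm in 5 μm steps (13 positions), averaging `frames_per_z` frames per
position. Alignment is two-step:

1. *XY*: the stack's top plane at each Z is cross-correlated against the
   reference top plane; the shift with the highest correlation peak across
   all Z positions wins (`best_xy_over_stack()`).
2. *Z*: after applying that XY shift, the top-plane image at each Z is
   correlated with the reference image and a linear-offset Gaussian
   `a·exp(−(z−μ)²/(2σ²)) + b` is fitted to correlation versus Z
   (`fit_linear_offset_gaussian()`); the center `μ` is the axial shift.

The loop `acquire → estimate → move` repeats until every computed shift is
below 5 μm (`align_iterative()`, `tol_um = 5`, `max_iter = 10`). The
accumulated correction estimates the drift.

**Numerical choices.** Correlation is zero-mean normalized cross-correlation
computed with FFTs (circular), with the peak searched in a ±20 px window and
refined to sub-pixel precision by parabolic interpolation; circular
correlation makes the integer-shift equivariance property exact. The
Gaussian fit uses bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
initialization `b = min`, `a = max − min`, `μ = argmax`, `σ = 2·step`,
bounds `σ ∈ [step/2, range]`, `μ ∈ sampled range ± step`, and solver
tolerances of 1e−10; a flat profile or vanishing amplitude raises a
"no axial peak" error rather than returning a spurious center. Ties between
equal correlation peaks resolve to the smallest-magnitude shift. Coordinates
are `(row = y, col = x)` with x along columns; shifts are reported in μm
using the per-axis pixel size.

# Detection, extraction, and screening

Mean projections are brightness-corrected by dividing by a 25×25 px median
filter of themselves, then binarized by a local-mean adaptive threshold
(block 51 px; offset 3 robust SDs by default — the field's standard practice
names neither constant, so both are configurable). Holes below 4 px² are
filled, components below 6 px² dropped, and 4-connected components become
cell masks.

Each mask seeds a component: its raw trace is the mean over mask pixels per
frame. A rank-1 nonnegative background (smooth spatial map × temporal
trace) is fitted by alternating least squares on the non-cell pixels; on
cell pixels the spatial weight is interpolated from the surrounding
non-cell pixels. The interpolation matters: regressing cell pixels on the
background trace would attribute each cell's constant resting fluorescence
to the background (a near-constant regressor), destroying the ΔF/F
baseline downstream.

**Deconvolution.** The denoised trace is the convolution of a nonnegative
spike train with an AR(1) kernel, `c(t) = γ·c(t−1) + s(t)`, obtained by
minimizing `½‖c − y‖² + λ·Σs` with a pool-adjacent-violators active-set
pass (`deconvolve_ar1()`). With `λ = 0` on a noiseless AR(1) input the
recursion is inverted exactly; the default `λ` is twice the trace's robust
noise SD (MAD of first differences / √2). The decay `γ` is estimated per
component by log-linear regression of the autocovariance over lags 1–5
after removing a 201-frame running median (slow background drift otherwise
inflates long-lag autocovariance; much shorter median windows clip the
transients themselves and bias `γ` low). `γ` is clipped to (0.6, 0.98) and
can be overridden.

**Screening.** Components are scored by

* `snr` — a gamma distribution is fitted by method of moments to the
  positive residuals (raw − denoised), accommodating the skewed shot-like
  noise of dim tissue; with `p` the fitted survival probability of the
  denoised trace's peak, `snr = qnorm((1 − p)^T)` for a `T`-frame trace,
  clipped to [0, 100]. The `(1 − p)^T` factor converts the single-sample
  survival into the probability that *no* such peak occurs anywhere in the
  trace; without it the maximum of `T` noise samples (survival ≈ 1/T)
  would score ≈ `qnorm(1 − 1/T)` ≈ 3 and pure noise would pass. This
  definition is the package's interpretation of a gamma-null SNR; it is
  exposed so alternatives can be swapped in.
* `rvalue` — Pearson correlation, inside the mask's bounding box, between
  the mask footprint and the movie averaged over the component's
  most-active frames (top decile of the denoised trace, minimum 5 frames).

Decisions follow the rejection-first rule: reject if `snr < 0.5` *or*
`rvalue < 0.1` regardless of the other metric; otherwise accept if
`snr > 1.2` *or* `rvalue > 0.85`; otherwise undecided.

# ΔF/F

Two variants, matching the two acquisition styles the package supports:

* **Moving-percentile (CNMF-style)**: denoised traces are detrended by the
  8th percentile in 500-frame moving windows; the baseline `F0` is the
  detrending trend plus the 8th moving percentile of the background
  component restricted to the cell's mask; ΔF/F is the detrended trace
  divided by `F0` (unitless). Windows are centered and truncated at the
  edges (a causal mode is available); percentiles use linear interpolation
  between order statistics. A non-positive baseline raises an error rather
  than producing infinities.
* **Simple (background-subtraction)**: `F` = raw ROI trace minus a
  background trace (e.g. a blood-vessel region); `F0` = mean of `F` over
  the contiguous ~2 s window of minimum variance (a reproducible stand-in
  for manually chosen inactive portions); ΔF/F = (F − F0)/F0 × 100, in
  percent.

Both variants are invariant to a global gain change of the movie.

# Cross-session matching

Masks from session A are mapped into session B's frame by a piecewise-rigid
shift field (per-patch windowed cross-correlation of the
brightness-corrected mean projections, bilinearly interpolated between
patch centers; a 1×1 grid reduces exactly to the rigid estimate, and
`rigid_shift_field()` covers known/manual shifts). Matching solves the
linear sum assignment problem on a cost of `1 − IoU`, with pairs whose
centroids are more than 10 px apart pinned to cost 1, and keeps pairs with
cost < 0.8 (equivalently IoU > 0.2). The `1 − IoU` reading is a design
decision: the quoted thresholds are consistent with it, and it is the only
monotone transform that makes a *minimizing* assignment sensible on [0, 1];
it is configurable. The solver is a shortest-augmenting-path implementation
with dual potentials, validated against an exhaustive-permutation oracle;
rectangular matrices are handled natively and ties resolve by row order.

# Trial-aligned activity

Trials are aligned at the choice time (entry into a maze arm). The window
(default 4 s pre-choice) is cut into fixed bins (default 0.5 s; neither is
stated for the original maps, so both are parameters), frames are averaged
within bins, and trials averaged per cell. Timeout trials have no choice
time and are excluded with a count. Per-cell activity is min–max normalized
to 0–1 and cells are sorted by peak bin (ties by index); zero-range cells
normalize to all-zero rows and sort last. For two-session comparisons,
matched cells appear in both maps in session-A peak order; session-unique
cells are sorted within their own session.

# Histology quantification

Sections are quantified by (i) bilinear line profiles of fixed length over
the expressing region, (ii) particle counts — binarize at a threshold
(Otsu's method by default, standing in for manual thresholding, with an
override), split touching cells by a watershed on the distance transform,
drop objects under the minimum area (5 px² for Iba1-class, 10 px² for
GFAP-class stains; `area ≥ min` kept), and count — and (iii) the
expression index, count/area × 10,000, averaged over four sections per
animal. Watershed parameters default to tolerance 0.5 with a 2 px
neighborhood: a 3 px neighborhood merges touching same-size disks whose
centers are ~1.6 radii apart, which the pipeline must resolve. Per-cell
multichannel co-expression uses Pearson correlation of z-scored
intensities across cells.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the
conditions under which the pipeline's guarantees are demonstrated.

* **Fields** (`generate_field()`): somata placed uniformly with a minimum
  pairwise separation (rejection sampling, bounded retries) near 3 planes
  spaced 30 μm; functional brightness 80–200 a.u.; radii 3–5 μm. Footprints
  are isotropic 2-D Gaussians (σ = radius/2) truncated at 2.5σ; axial
  defocus attenuates brightness by `exp(−(Δz/σ_z)²)` and inflates σ by
  `√(1 + (Δz/σ_z)²)` with `σ_z = 12 μm` — a convenience model, not an
  optical PSF.
* **Structural channel**: a separate population of structural-only nuclei
  (radius 2–3 μm) scattered *continuously* in depth, extending 40 μm beyond
  the outer planes. This is deliberate: normalized correlation is invariant
  to uniform dimming, so if structural content only sat at the imaging
  planes the axial correlation profile would be nearly flat; and if nuclei
  stopped at the probed range the profile would fall off asymmetrically
  and bias the Gaussian center. Continuous-depth nuclei make image content
  turn over symmetrically with Z, which is what the axial estimator relies
  on — as it does in real tissue.
* **Sessions** (`simulate_session_truth()` + `render_session()`): sparse
  Bernoulli spikes with amplitudes 0.5–1.5× the resting level, AR(1) decay
  γ = 0.85 per volume at 10.4 vol/s; a rank-1 global background (smooth
  spatial profile × slow two-sinusoid trace); gamma-distributed shot-like
  noise (shape 2) plus Gaussian read noise — the skewed noise that makes a
  gamma-null SNR meaningful. Rendering is a pure function of (field, truth):
  identical seeds give bit-identical movies and TIFF payloads.
* **Behavior** (`simulate_behavior()`): a parameterized agent runs the
  T-maze (219 cm stem, 37 cm arm, 5.7 cm/s initiation threshold, 120 s
  timeout, 1–1.5 s ITI plus 8 s after errors, memory-trial cues uniform in
  8.5–153.8 cm). The side-bias rule is a documented stand-in:
  `P(right cue) = clip(0.5 + k·(acc_L − acc_R over trailing 40 trials),
  0.2, 0.8)`, `k = 0.75` — it presents the failed side more often, and
  makes no claim about the original scheduling algorithm.
* **Histology** (`render_histology()`): non-touching disks of specified
  area inside an ROI polygon over a noisy background, with the true count
  retained.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: optical PSF structure and depth-dependent
scattering, brain motion within a session (movies are motion-free; the
piecewise-rigid machinery is exercised on cross-day mapping only), neuropil
contamination and overlapping somata, photobleaching, indicator
nonlinearity, and real behavioral statistics.

# Problem sizes and validated guarantees

The test-suite and acceptance-script runs use desk-scale versions of the
study geometry, chosen as the package's own validation conditions:

* Alignment: 20 fields of 160×160 μm (128×128 px at 1.25 μm/px, a scaled
  stand-in for the original 583×862 μm field), 40 somata + 140 nuclei,
  8 frames per Z position, true drifts uniform in ±15 μm per axis. The
  closed loop must converge (each shift < 5 μm) within 3 iterations, with
  final XY error ≤ 1 px and Z error ≤ 2.5 μm (half the Z step). Nucleus
  count matters here: sparser structural content makes the axial profile
  lumpy and the center estimate noisier.
* Z-fit robustness: 200 noisy 13-point profiles (correlation noise
  SD 0.02), center recovered within 2.5 μm in ≥ 95%.
* Matching: 20 session pairs, 45 cells at ≥ 15 px separation, 20% turnover,
  (8, −5) px drift, 10 px gate, cost < 0.8 — perfect precision and recall
  on persistent cells fully visible in both sessions (border-clipped cells
  are excluded from the benchmark: a half-visible mask cannot reach
  IoU > 0.2 with its partner).
* ΔF/F fidelity: 20 single-plane sessions (64×64 px, 1200 frames, 8 cells)
  with one planted transient of known amplitude per cell; the full
  detect → extract → deconvolve → detrend → baseline → divide chain must
  recover amplitudes within 10% of the ground-truth expectation (resting
  fluorescence, background light and noise offset all computed from the
  generator's truth).
* Deconvolution: exact λ = 0 inversion to 1e−8; assignment equal to the
  brute-force optimum on 100 random matrices up to 7×7; particle counts
  exact on 20 sections; screening decision table and rejection dominance on
  a 10⁴-point grid; planted pre-choice latencies recovered in the correct
  bins.

# Known limitations

* The seeded-mask extraction deliberately replaces constrained nonnegative
  matrix factorization: footprints are not refined, overlapping somata are
  not demixed, and the background is exactly rank-1.
* The SNR formula and the active-frame rule for the r-value are
  interpretations of under-specified upstream conventions; both have
  configuration hooks.
* The axial estimator inherits the literal two-step reading: only the top
  plane enters the XY and Z correlations. Using all planes would likely be
  more robust but is not what the procedure describes.
* Within-session motion correction is out of scope; movies are assumed
  motion-corrected (the simplified piecewise-rigid mapping is used for
  cross-day mask transfer only).
* Histology indices are reported per px², as no physical pixel size is
  defined for the synthetic sections.

# A compact end-to-end example

```{r example, eval = FALSE}
field <- generate_field(40, fov_um = c(160, 160), n_nuclei = 140, seed = 1)
reference <- render_structural_stack(field, frames_per_z = 8, seed = 2)
drift <- c(9, -7, 11)  # unknown in real life
stack_now <- function(pos) render_structural_stack(
  field, frames_per_z = 8, shift_um = drift - pos, seed = 3)
alignment <- align_iterative(stack_now, reference)
alignment
```
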