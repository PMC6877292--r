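---
title: "Quantifying blood-brain barrier permeability from two-photon time-lapse imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blood-brain barrier permeability from two-photon time-lapse imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbflux)
```

# The measurement problem

In vivo two-photon imaging of the cortical microvasculature after an
intravenous bolus of a fluorescent tracer gives a time series of image
volumes in which two processes are visible in one detection channel: the
tracer circulating in the blood (clearing over tens of minutes) and the
tracer that has crossed the blood-brain barrier (BBB) into the parenchyma,
where it accumulates.  `bbbflux` quantifies two transport routes:

* **Paracellular leak** of free small-molecule dyes, scored as the **area
  under the curve (AUC)** of the relative parenchymal fluorescence increase
  over a 30-min window after injection, with a sequential-tracer
  **decoupling correction** when several dyes share the channel.
* **Transcytosis** of a fluorophore-albumin conjugate, scored as the
  cumulative **vesicle surface density** — distinct wall puncta per
  100 µm² of vessel surface (`pi * d * L`) — resolved by microvessel
  category (pial arteriole/venule, penetrating arteriole, ascending venule,
  post-capillary venule, capillary).

Because the animal imaging data underlying such experiments are not
reproducible at a desk, the package ships a synthetic-data generator with
known ground truth; every stage of the analysis is tested against it.

# The two-compartment tracer model

The simulator (and the leak-rate estimator used for validation) adopts the
simplest kinetic model consistent with a bolus injection followed by
mono-exponential blood clearance.  For a tracer injected at $t_0$ with
blood amplitude $C_0$, clearance rate $\lambda$ (per min), and paracellular
leak rate $k$ (per min):

$$B(t) = C_0 e^{-\lambda (t - t_0)}, \qquad
  P(t) = k \int_{t_0}^{t} B(s)\,ds =
  \frac{k C_0}{\lambda}\left(1 - e^{-\lambda (t - t_0)}\right),$$

with $P(t) = k C_0 (t - t_0)$ in the $\lambda \to 0$ limit.  Fluorescence
is additive across tracers sharing the channel; a constant autofluorescence
offset is added everywhere; and noise is applied last — Poisson at
`gain * expectation` rescaled by `1/gain`, plus Gaussian read noise
(defaults `gain = 1`, `sigma = 2`, typical of photon-limited imaging).
Stacks are written as 16-bit TIFF.  The clearance rates are deliberately
pre-plateau over a 30-min window ($\lambda$ of order 0.02–0.05 per min for
the default dyes), so the parenchymal signal keeps rising without
saturating, as observed for small free dyes in vivo.  Per-dye blood
half-lives are not tabulated anywhere authoritative; the defaults are
order-of-magnitude choices (smaller dyes clear faster than a 10-kDa
dextran) and are plainly exposed in `groundTruth()`.

# The paracellular pipeline

1. **Maximum intensity projection** of each Z-stack (`maxProject()`).
2. **Vessel segmentation** on the first frame of the first tracer window
   (`segmentVasculature()`): a global Otsu threshold computed on 256 bins
   between the frame minimum and maximum — hence exactly invariant to
   constant offsets — followed by morphological closing (3-px disc) and
   removal of components under 20 px.
3. **ROI placement** (`placeParenchymalRois()`, `placeBloodRois()`):
   square parenchymal ROIs (default ten of 8 × 8 px, pooled into one
   trace) placed uniformly at random with rejection against the vessel
   mask dilated by 3 px, keeping the perivascular halo out; blood ROIs
   must lie entirely inside the mask.  The source protocol did not state
   ROI count, size, or whether ROIs were pooled; pooling into one
   pixel-weighted mean is this package's documented choice.
4. **Background subtraction** (`subtractBackground()`): the constant
   autofluorescence level, estimated from pre-injection frames when the
   recording has them, otherwise supplied.
5. **Sequential-tracer decoupling** (`decoupleSequential()`): dyes are
   injected consecutively at ~30-min spacing without waiting for
   clearance, so later windows contain earlier dyes' signals.  Fluorescence
   additivity lets us subtract, from each later trace, the extrapolated
   exponential fit of every earlier (already corrected) trace.  Parenchymal
   traces use a saturating-growth model $a + b(1 - e^{-c t})$: its
   extrapolation is non-decreasing and bounded by $a + b$, a conservative
   bound on the largest contribution a preceding tracer can make.  Blood
   traces use the analogous decay model.  Negative corrected values are
   retained, so over-correction stays measurable.  The correction is
   asymmetric by construction: earlier tracers are never corrected by later
   ones.
6. **Relative change and AUC** (`relativeChange()`, `computeAuc()`): each
   corrected window is expressed as $(F_t - F_0)/F_0$ against its own
   baseline frame and integrated trapezoidally on the native 1-min grid
   over the 30-min window; the score is dimensionless fluorescence × min,
   reported in "min".

## The relative-change denominator

After full background subtraction, a corrected parenchymal trace is
proportional to $k$, and a ratio of it to its own baseline would cancel
$k$ entirely.  What an observer actually normalizes by is the *measured*
baseline fluorescence of the window — parenchymal signal plus the
autofluorescence background.  `analyzeParacellular()` therefore subtracts
the background for fitting and decoupling (where constant offsets would
corrupt the exponential fits) and then restores it in the denominator when
converting to relative units.  This keeps AUC strictly increasing in the
leak rate and the normalization stable under noise.  The alternative
ordering (relative conversion before any correction) is exposed as
`relativeFirst = TRUE`, without endorsement.

## Exponential fits

`fitExponential()` uses Levenberg-Marquardt nonlinear least squares
(`minpack.lm`), initialized at `a` = first value, `b` = last − first,
`c` = 1/window-length, with `c` bounded to [0, 10] per min.  On noiseless
model data the parameters are recovered to better than $10^{-4}$ relative
error.  Constant traces return the degenerate fit $a$ = value, $b = 0$,
$c = 0$.  If the optimizer fails, a linear fallback is reported with
$c = 0$ and $b$ = slope × window length; such fits carry `fallback = TRUE`
and evaluate as $a + b\,(t - t_s)/L$.

## Validation oracle: the leak rate

`estimateLeakRate()` inverts the kinetic model directly:
$\hat k = \arg\min_k \lVert P(t) - k \int_0^t B(s) ds \rVert$, a one-line
least squares on the common time grid, with the unobserved head of the
blood integral (between injection and the first frame) reconstructed from
the decay fit.  The study design never reports $k$ — it is this package's
recovery oracle tying the pipeline back to the simulator's ground truth.

# The transcytosis pipeline

Conjugate sessions are simulated at sub-micrometre pixel size (0.755 µm,
matching high-magnification acquisition) with a slowly clearing blood-pool
conjugate and wall puncta accumulating as a Poisson process: per segment,
the cumulative event count at time $t$ is Poisson with mean
`rate * (area/100) * t`, events persist (densities do not saturate within
a 2-h session), and each event renders as a compact Gaussian punctum.
Because a cylindrical wall projects onto the vessel's full 2-D silhouette,
punctum positions are drawn uniformly over the projected footprint, not
just its outline.

Detection (`detectVesicles()`) automates what was originally manual
counting:

* work on the **change image** relative to the session's first
  (pre-accumulation) frame, with the global blood-pool drift (conjugate
  clearance) removed inside the mask — static luminal signal cancels
  exactly;
* restrict to the **wall band**: the vessel silhouette plus a 2-px margin,
  which keeps parenchymal uptake (e.g. by macrophages) out of the counts;
* threshold at **median + 3 MAD** of the band's vascular pixels (gain
  doubling rescales the threshold with the data, so counts are
  scale-invariant), with a one-detector-count floor so sub-quantization
  changes are never treated as signal;
* split merged blobs by **watershed** with a tolerance equal to the
  threshold prominence; size-filter components by their **half-max
  radius** (0.25–1.5 µm), which is threshold-independent;
* **veto** any candidate that is not also a local blob in the *current*
  frame relative to the vessel's own level — a deficit in the single
  baseline frame would otherwise masquerade as a persistent punctum;
* localize by the intensity-weighted centroid.

Punctum identity across timepoints uses nearest-neighbour linking within
1 µm; unlinked reappearances count as new puncta, and a track must be seen
in at least two frames to count (one-off noise blips do not persist;
genuine puncta do).  `densityKinetics()` then reports, per vessel and
timepoint, the cumulative distinct-punctum count per 100 µm² of
`pi * d * L` surface; `rateRecovery()` fits the per-category
density-vs-time slope through the origin, which estimates the configured
event rate regardless of vessel size.

Vessel categories come from a deterministic decision table
(`classifyVessel()`) on diameter, orientation and an arterial/venous flag
that must be supplied — morphology alone cannot decide it: capillary
< 6 µm; post-capillary venule 6–10 µm venous; penetrating arteriole /
ascending venule 10–25 µm through-plane; pial arteriole 25–60 µm and pial
venule 25–100 µm in-plane; anything else is `"unclassified"`, never
silently dropped.

# The statistical layer

`compareTwoGroups()` reproduces the study's gate: a per-group omnibus
(skewness + kurtosis) normality test — the D'Agostino-Pearson $K^2$
statistic, validated against an independent implementation — at
$\alpha = 0.05$; Welch's two-tailed t-test when every group passes,
otherwise the Mann-Whitney test with midranks.  Groups under $n = 8$
default to non-normal with a note.  Morphometry tables (electron-microscopy
ultrastructure measures) are log-transformed and tested by one-way ANOVA
with Tukey's multiple-comparison test (`compareMorphometry()`); the log
transform makes the test invariant to multiplicative rescaling.  All
reported errors are SEM.  No multiple-testing correction is applied across
tracers or vessel categories beyond Tukey, matching the original analysis.
For vessel-level comparisons the vessel is the default experimental unit
(group sizes are quoted as vessels across mice).

The morphometry generator draws log-normal values (positive support)
parameterized by arithmetic mean and coefficient of variation; group means
for endothelial thickness (0.071 / 0.078 / 0.070 µm for wild-type,
knockout, and agonist-rescued animals) and endothelial cell area encode
the reported effects, junctional measures are identical across groups, and
dispersions reflect the reported SEMs at n ≈ 104 vessels.

# Synthetic data: what it emulates, and what it does not

The generator emulates the statistical structure the analysis relies on —
compartment kinetics, channel additivity, constant autofluorescence,
photon-limited noise, Poisson vesicle accumulation, the microvascular
taxonomy with realistic diameters (capillaries < 6 µm), and 16-bit
acquisition.  It deliberately omits optical realism: no point-spread
function, depth attenuation, motion, bleaching, or hemodynamic
fluctuations.  Passing tests therefore demonstrate that the *analysis*
recovers known truth from data satisfying its assumptions; they cannot
certify performance on data with motion artifacts or scattering, and the
absolute group values of the original animal study are not desk-
reproducible — only its qualitative signature (direction of effects) is
asserted.

# Numerical and design notes

* **Problem sizes.**  Analyses are validated on compact grids chosen so a
  full session simulates in seconds: paracellular sessions at
  4 × 96 × 96 voxels per frame (3 µm pixels) and conjugate sessions at
  8 × 256 × 256 (0.755 µm pixels); larger grids are supported.  The
  vesicle validation uses a uniform event rate of 0.003 per 100 µm² per
  min — about 0.36 per 100 µm² over a 2-h session, the scale of the
  reported knockout arteriole densities — so 20-seed aggregates contain
  hundreds of events per category.
* **Projection bias.**  The maximum projection of a noisy stack is an
  order statistic: its expectation exceeds the plane expectation by an
  amount that grows with the signal's variance.  Group contrasts and
  decoupling ratios are insensitive to it (both arms share the bias), but
  absolute parameter recovery is not; the leak-rate recovery validation
  therefore runs on single-plane recordings, and the bias is documented
  here as a limitation of max-projected quantification in general.
* **Inter-vessel clearance.**  Segments are disjoint in the projected view
  (not merely in 3-D), with ~3 µm of lateral clearance in the
  vesicle-session geometry, so every punctum is attributable to a unique
  vessel — mirroring the hand-selected, clearly separated vessels used for
  manual counting.
* **Determinism.**  Every stochastic step takes a seed and restores the
  caller's RNG state; identical configuration + seed gives bit-identical
  stacks, tables and reports.
* **Degenerate inputs** fail loudly and informatively: constant frames
  (segmentation), insufficient vessel-free area (ROI placement), all-zero
  blood traces (leak estimation), non-positive values (log ANOVA), windows
  not covered by a trace (AUC).
* **Interface.**  The package is used from R; the exported functions plus
  `scripts/acceptance.R` are the command surface.  All exchange formats
  are plain text or TIFF: T-Z-Y-X 16-bit stacks with JSON metadata
  sidecars, integer label volumes, trace CSVs, ROI JSON (0-based
  row-major), schedules in JSON or YAML, morphometry CSV, and a
  deterministic `report.json`.

# Known limitations

Paracellular leak is not resolved per vessel category (free small dyes
diffuse too fast for that attribution, and the package does not attempt
it).  Transcytosis detection assumes puncta brighter than the local wall
signal and at the configured size scale; dim or diffraction-sized vesicles
under heavy noise will be undercounted, and two puncta closer than the
1 µm linking radius are fundamentally one count — the same limit manual
counting faces.  The decoupling correction is a bounded-extrapolation
heuristic: it is exact when the earlier tracer's parenchymal kinetics
really are saturating-exponential, and conservative otherwise.
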