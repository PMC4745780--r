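---
title: "Methods: automated tracking and morphometry of organoid/CAF co-cultures"
author: "organotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated tracking and morphometry of organoid/CAF co-cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organotrack)
```

# What the pipeline measures

Three-dimensional co-cultures of tumor organoids and cancer-associated
fibroblasts (CAFs) embedded in extracellular matrix are imaged over days
to weeks with a two-channel live-cell system (phase contrast plus green
fluorescence, one frame per hour) and, at end point, by confocal
microscopy. The biology of interest lives in slow morphological change:
fibroblast cohorts spread, branch and move; organoids grow, lose their
round epithelial phenotype and extrude invasive appendages. organotrack
turns those image sequences into quantitative per-well and per-object
measurements:

* **stabilization** — removal of frame-to-frame camera jitter;
* **fibroblast segmentation** — per-frame cohort masks, area and growth
  rate;
* **motion** — dense optical-flow motility of the masked CAF compartment;
* **shape** — branching of each cohort via convexity defects;
* **tumor segmentation** — organoid masks and growth curves from the
  phase-contrast channel;
* **MRF confocal segmentation** — three-label (background / cell shadow /
  in-focus cells) Markov-random-field labeling of confocal projections;
* **morphometrics** — per-organoid parameters (Area, Roundness, FiltRound,
  Density, AppNumber, MaxApp, MedApp, CellNumber) with group statistics.

Because no public raw imaging data accompany this platform, every stage
is validated against synthetic phantoms with exact, code-level ground
truth (the `generate_*` family). This vignette records the models, the
parameters that matter, the numerical conventions, and the design
decisions that were genuinely open.

# Stabilization

Sequential capture introduces small global displacements of the field of
view. A translation-only motion model is assumed: two frames $f$ and $g$
related by $g(\mathbf{x}) = f(\mathbf{x} - \Delta)$ have Fourier
transforms satisfying $G(u) = e^{-2\pi i u\cdot\Delta} F(u)$, so the
normalized cross-power spectrum

$$ T(u) = \frac{F(u)\,G^*(u)}{|F(u)|\,|G(u)|} = e^{2\pi i u\cdot\Delta} $$

inverse-transforms to a delta at $\Delta$ (phase correlation). The
implementation floors $|F||G|$ at machine epsilon, optionally applies a
Hann window after mean subtraction, and refines the peak to sub-pixel
precision by separable quadratic interpolation. Cumulative shifts are
compensated against the first frame and the output is cropped to the
rectangle covered by every compensated frame; out-of-field pixels are
never padded.

Decisions worth recording:

* **Blur-robust mode.** Heavily defocused movies defeat the plain
  normalized spectrum, which whitens into noise. `method = "blur_robust"`
  runs the identical correlation on gradient-magnitude images. On
  phantoms where every frame is blurred ($\sigma = 3$) the standard
  estimator fails by several pixels while the gradient variant recovers
  integer jitter exactly; on a one-sided blur both stay within 1 px.
* **Channel.** Shifts are estimated on the phase-contrast channel by
  default and the same compensation is applied to the fluorescence
  channel (`apply_stabilization()`). On co-culture phantoms the
  fluorescence channel is dominated by the bright moving cohort and phase
  correlation then locks onto object motion instead of camera jitter.
* **Windowing.** The Hann window is the default for real sequences, whose
  borders are not periodic. Phantom jitter is applied by circular shift,
  for which the un-windowed estimator is the exact oracle; tests
  therefore disable the window, as the configuration allows.

# Filtering

The fluorescence channel suffers from impulsive noise, defocus and
granular autofluorescent background. The filter cascade is a 5×5 median
followed by non-local means (NLM) with patch 7×7, search window 31×31 and
weight decay $h = 15$ — all config-exposed. NLM weights are
$w(p,q) = \exp(-\overline{\|P_p - P_q\|^2}/h^2)$ on mean squared patch
differences; the shipped implementation computes, per search offset, a
box sum of the squared difference image over a mirror-padded buffer,
which is numerically identical to the direct patch-by-patch formula (a
unit test asserts equality to 1e-10) but two orders of magnitude faster.

All windowed filters in the package use **mirror-reflection borders**;
this convention is fixed package-wide so that the exhaustive per-pixel
oracles in the test suite are well defined. The tumor channel gets the
intensive cascade: two NLM passes plus joint spatial/range mean-shift
filtering (defaults: spatial radius 10 px, range radius 10 intensity
units — values chosen once as reasonable for 8-bit-scale intensities).

# Fibroblast segmentation

Cohorts are low-contrast and their intensity drifts over time, so a
global histogram threshold (Otsu-style) fails. Instead each pixel is
compared against a local threshold

$$ T(x,y) = \Big(\sum_{i,j} f(x-i,\,y-j)\, w(i,j)\Big) + \kappa ,$$

the Gaussian-weighted mean of its $(2k+1)\times(2k+1)$ block
($w \propto e^{-(i^2+j^2)/2\sigma^2}$, normalized to sum 1, $\sigma =
(2k+1)/6$ by default) offset by a constant $\kappa$ (default 2, block
half-width $k = 25$). A pixel is foreground only when it exceeds its
neighborhood mean by more than $\kappa$: the sign convention is chosen so
that a positive $\kappa$ suppresses flat background, a constant image
yields no foreground, and raising $\kappa$ never adds foreground pixels —
the only orientation under which local adaptive thresholding works as a
fluorescent-object detector.

Two post-steps follow: **hole filling** (4-connected enclosed background
is converted to foreground — objects larger than the threshold block
otherwise hollow out, because their interior sits at the local mean) and
**small-region removal** (8-connected components below `min_area = 50` px
are deleted; the value is a package default, chosen once). Foreground
components, their Moore-traced closed contours and pixel-count areas form
the `CohortRegion` list; growth is the total foreground area per frame
normalized to the first frame, so every growth series starts at exactly 1.

Connectivity is fixed at 8 for foreground and 4 for background (the
proper digital-topology dual), and ties at the threshold go to
background.

# Motion

Motility is measured by Farnebäck dense optical flow, not by per-cell
tracking: individual CAFs cannot be resolved inside cohorts, whereas
dense flow needs no detections. Each pixel neighborhood is approximated
by a quadric $f_1(\mathbf{x}) = \mathbf{x}^TA_1\mathbf{x} +
\mathbf{b}_1^T\mathbf{x} + c_1$ under a Gaussian applicability. A pure
translation $\mathbf{d}$ gives $A_2 = A_1$, $\mathbf{b}_2 = \mathbf{b}_1
- 2A_1\mathbf{d}$, hence $\mathbf{d} = -\tfrac12 A_1^{-1}(\mathbf{b}_2 -
\mathbf{b}_1)$. The per-pixel normal equations are averaged over a 15-px
window, solved with a ridge guard for near-singular $A$, median-filtered
(5×5) to suppress occlusion-boundary outliers, and iterated three times
per level over a 3-level image pyramid. The window, pyramid and
polynomial parameters (poly half-width 5, applicability $\sigma = 1.1$)
are package defaults: only the algorithm itself, not its parameters, is
prescribed by the platform.

The **mean motion per frame** is defined as the mean displacement
magnitude over mask-foreground pixels — the only reading of the
motility normalization that yields a per-frame quantity in pixels. An
important subtlety surfaced during validation: when a cohort *grows*
while it moves, its boundary material genuinely travels outward at
$r\big((1+g)^{1/2}-1\big)$ px/frame, so the mean motion of a growing,
translating phantom exceeds the imposed translation — correctly. The
companion summary `mean_velocity_per_frame()` (the masked mean flow
*vector*) cancels isotropic expansion and recovers the net translation;
the test suite checks the magnitude curve against the phantom's true
material speed and the vector mean against the imposed velocity.

# Branching

Each cohort's contour is compared with its convex hull (`grDevices`
Andrew-monotone hull). For every pair of hull vertices consecutive along
the contour, the intermediate contour run is examined; the point farthest
from the hull chord, and its Euclidean point-to-chord distance (the
defect *depth*), define one convexity defect. Defects deeper than
`depth_threshold = 5` px count as extensions (branches); the threshold
default is a package choice, fixed once. Depth — not the area between
contour and hull — is used as the extension size, matching the
"farthest point distance" definition; the star phantom with analytic
notch depth $r_{out}\cos(\pi/n) - r_{in}$ validates depths to ±1 px on
rasterized masks.

# Tumor segmentation

The phase-contrast channel has low SNR and background clutter, so the
intensive denoise cascade precedes the same adaptive threshold, followed
by morphological smoothing (closing then opening with a 3-px-radius
disc; element and order fixed by decision), hole filling and small-region
removal. The raw result also detects fibroblast cohorts: because the
channels are registered, the fibroblast mask from the matched
fluorescence frame is subtracted, with contact pixels always assigned to
the fibroblast compartment. The count of removed pixels is kept as
`excluded_fibro_pixels`. Identical fixed parameters apply across a whole
sequence, so per-frame organoid areas form a comparable growth curve.

# MRF confocal segmentation

Confocal stacks are reduced to maximum-intensity projections, scaled to
8-bit, and passed through a local entropy filter (disc radius 5, Shannon
entropy in bits of the 256-bin histogram). A three-component Gaussian
mixture is fitted to the filtered values by EM with k-means++
initialization and five restarts (best log-likelihood kept, variances
floored at $10^{-3}$ with a warning on degeneracy); components sorted by
mean map to *background*, *cell shadow* and *in-focus cells*. Labels
minimize

$$ E(x) = \sum_i \theta_{i;l}\,\mathbb{1}\{x_i = l\}
        + \sum_{(i,j)} \theta_{ij;lk}\,\mathbb{1}\{x_i = l, x_j = k\} $$

with unaries $\theta_{i;l} = -\log f_l(z_i)$ (densities floored at
$10^{-12}$) and contrast-sensitive Potts pairwise terms
$\theta_{ij;lk} = \lambda_0 + \lambda_1 \exp(-\tfrac12\beta\|z_i -
z_j\|^2)$ for $l \ne k$ on a 4-neighbor grid. Defaults $\lambda_0 = 0.5$,
$\lambda_1 = 2$, $\beta = 0.05$ (on 8-bit intensities) were set once by
inspecting unary-potential quantiles — `unary_quantiles()` reproduces
that workflow for new data. Conventions: the mixture is fitted on
entropy-filtered values (switchable to raw via `mrf$unary_on`), while the
pairwise contrast always uses the 8-bit raw intensities; both choices are
coupled and documented here because the two images live on different
scales.

Minimization is by α-expansion: each move is an exact s–t min cut
(igraph max-flow backend; the pairwise term is a non-negative-weighted
Potts metric, so every binary subproblem is submodular). Expansion
descent reaches a move-optimal labeling that can still be a local
optimum of the move neighborhood — exhaustive enumeration on 3×3
instances exposed one such case — so the solver multi-starts from the
maximum-likelihood labeling and the three constant labelings, keeping the
lowest energy; with that strategy all 50 random tiny instances in the
suite attain the global minimum. The energy is asserted non-increasing
across moves. In the $\lambda_0 = \lambda_1 = 0$ limit the output equals
per-pixel maximum likelihood exactly. A 512×512 image segments in ~12 s
on one CPU. Per-channel in-focus labels are overlaid (none / first /
second / both) to display tumor–CAF co-localization; volumetric
(voxel-graph) segmentation is intentionally out of scope since the
upstream workflow itself operates on maximum projections.

# Organoid morphometrics

Parameter formulas are re-specified concretely here (the platform's
original high-content analyzer is not reproduced bit-for-bit):

* `Area` — object pixel count.
* `Roundness` — $4\pi A / P^2$, clamped to $(0, 1]$. The perimeter is the
  Freeman chain length of the traced contour with Kulpa's correction
  (×0.9481), without which a rasterized disc would read ~10% low.
* `FiltRound` — Roundness of the morphologically opened "body"
  (disc radius 4), i.e. after appendage removal.
* `Density` — mean intensity of the matched (red) channel over the
  object.
* `AppNumber` / `MaxApp` / `MedApp` — appendages are the 8-connected
  parts of the object outside the dilated body; each must cover at least
  5 px, and its length is the farthest Euclidean distance of its pixels
  from the body (equal to the protrusion length for straight appendages,
  a slight underestimate for curved ones).
* `CellNumber` — `Area / mean_cell_area` with a calibration default of
  250 px²/cell; explicitly an estimate, since no counting rule exists at
  this resolution.

Group screens use two-sided Mann–Whitney U tests (exact where possible)
or Welch t-tests against the control, Bonferroni-corrected across all
comparisons in the call; effect directions come from median (U) or mean
(t) ratios. Fold-change heatmaps are $\log_2$ of group-over-control
medians with the aligned adjusted-p matrix. Growth curves are normalized
pointwise to the vehicle control in percent (control flat at 100%, its
final point 100% by construction); the inhibition at the final time point
is $100(1 - \text{treated}/\text{control})$. Display smoothing of time
series is a centered 5-frame moving average, with raw curves always
retained.

# The phantom generator

`generate_cohort_sequence()` emulates the statistical structure the
analysis assumes, not the biology: a star-shaped bright cohort (area
growing geometrically, translating at a fixed velocity, carrying its own
granular internal texture, since real cells have substructure and a
texture-free interior would make dense flow ill-posed) over a static
low-frequency multiplicative background field (the granular ECM), round
organoid discs in the phase channel, per-frame integer circular jitter,
and additive Gaussian noise. Ground truth — jitter, drawn pixel-count
areas, centroids, per-frame object masks — is exact by construction, and
everything is bit-reproducible from the seed. `generate_star_contour()`,
`generate_mrf_image()` and `generate_organoid_field()` supply analytic
notch depths, known label maps and known appendage counts/lengths for
the shape, MRF and morphometry stages.

Study-condition choices made once for the end-to-end validation: 30
frames (hourly capture over ~a day of a fast phase), 10%/frame area
growth with 2 px/frame motion and ±3 px jitter on a 256×256 canvas with
noise σ=5 — a canvas large enough that the initial cohort is not
boundary-limited, at Incucyte-like scale. Passing phantom tests shows
the *estimators* are correct under these structural assumptions; it does
not certify performance on real data with focus drift, bleaching, or
non-rigid deformation, none of which the phantoms model.

# Numerical conventions and limitations

* Coordinates are row-major, origin top-left, 0-based in all reported
  contours and shifts; x is the column, y the row.
* All windowed operations use mirror-reflection borders; window sizes
  must be odd and are validated on config load.
* Tie-breaks: threshold ties go to background; mixture components tie-
  break by the first-restart best log-likelihood; `max.col` ties in ML
  labeling take the first label.
* The adaptive threshold cannot segment objects larger than its block
  without the hole-filling step; with it, only true enclosed holes are
  altered.
* Stabilization assumes pure translation — rotation, rolling shutter and
  non-rigid drift are out of scope.
* Mean-shift and NLM parameters are not auto-tuned from noise estimates;
  `h` is a plain scalar (default 15).
* Collagen-only cultures are known to segment poorly (noise and
  granularity); the tumor module accepts them but the platform's own
  recommendation is a Matrigel/collagen mixture.

# Problem sizes used in validation

The test suite and the acceptance script run, per invocation: 20
six-frame 128×128 jitter phantoms; 50 random 32×32 threshold fixtures;
translation phantoms at 128×128; 50 exhaustive 3×3 MRF instances plus
96×96 and 512×512 phantom segmentations; a 3,000-sample mixture
recovery; 1,000 null replicates for test calibration; and one 30-frame
256×256 end-to-end co-culture phantom. These sizes were chosen so the
whole validation stays comfortably within a desktop-minute budget while
every estimator is still exercised at realistic scale.
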