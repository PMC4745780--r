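# organotrack

Automated tracking and morphometry of tumor organoid / fibroblast 3D
co-cultures from live-cell time-lapse and confocal microscopy.

Prostate-cancer organoids grown in extracellular matrix together with
cancer-associated fibroblasts (CAFs) change shape slowly and subtly:
fibroblast cohorts spread, branch and migrate; organoids grow, lose
their round epithelial phenotype and push out invasive appendages.
organotrack quantifies those dynamics from standard two-channel
live-cell imaging (phase contrast + green fluorescence, one frame/hour)
and from end-point confocal projections, for screening how compounds or
matrix composition alter the tumor–stroma interplay. Its intended users
are imaging scientists and computational biologists running 3D
co-culture drug screens.

## What is inside

| stage | method |
|---|---|
| Video stabilization | phase correlation: `T(u) = F·G*/(|F||G|)` peaks at the inter-frame translation; cumulative compensation + common-field crop; gradient-magnitude variant for defocused movies |
| Denoising | 5×5 median + non-local means (patch 7, search 31, h = 15); tumor channel: 2× NLM + mean-shift filtering |
| CAF segmentation | local adaptive threshold `p > Σ f·w + κ` with a normalized Gaussian block kernel (k = 25, κ = 2), hole filling, small-region removal |
| Motility | Farnebäck dense optical flow `d = −½A₁⁻¹(b₂−b₁)`, pyramidal, masked mean displacement magnitude per frame |
| Branching | convex hull + convexity defects of each cohort contour; defects deeper than 5 px count as extensions |
| Organoid segmentation | intensive denoise + adaptive threshold + morphological smoothing, masked by the fibroblast segmentation (registered channels) |
| Confocal MRF | 3-label energy `E(x) = Σ −log f_l(z_i) + Σ_{l≠k} [λ₀ + λ₁ exp(−½β‖z_i−z_j‖²)]` minimized by multi-start α-expansion graph cuts; per-channel overlays for co-localization |
| Morphometrics | per-organoid Area, Roundness (4πA/P²), FiltRound, Density, AppNumber, MaxApp, MedApp, CellNumber; Mann–Whitney U / Welch t vs control with Bonferroni correction; growth normalization to vehicle control |
| Phantoms | synthetic co-cultures, stars, 3-label images and organoid fields with exact ground truth (jitter, areas, branch counts, labels, appendage lengths) |

## Worked example

```r
library(organotrack)

# simulate a jittery, growing, moving co-culture (ground truth known)
sim <- generate_cohort_sequence(
  n_frames = 12, jitter_amplitude = 3, growth_per_frame = 0.08,
  n_branches = 5, noise_sigma = 5, seed = 42,
  width = 192, height = 192, velocity = c(1, 0), n_organoids = 2)

# stabilize on the phase channel, carry the fluorescence channel along
stab  <- stabilize_sequence(sim$phase, subpixel = FALSE, window = "none")
fluor <- apply_stabilization(sim$fluor, stab)
phase <- apply_stabilization(sim$phase, stab)
head(stab$shifts, 3)
#>   frame dx dy      peak
#> 1     2 -3  0 0.1969284
#> 2     3  4 -3 0.2097538
#> 3     4 -4  4 0.2171908

# fibroblast cohorts: masks, growth rate, branching
cfg    <- default_config()
masks  <- segment_fibroblasts(fluor, cfg)
growth <- growth_rate_series(fibroblast_area_series(masks))
round(growth, 3)
#>  [1] 1.000 1.080 1.164 1.259 1.362 1.470 1.588 1.721 1.852 2.005 2.163 2.343

branching <- branching_series(masks, depth_threshold = 5)
branching$mean_extensions
#>  [1] 5 5 5 5 5 5 5 5 5 5 5 5

# CAF motility from dense optical flow (px/frame)
motility <- motion_series(fluor, masks, cfg)
round(motility, 2)
#>  [1] 1.23 1.17 1.25 1.25 1.25 1.26 1.28 1.23 1.35 1.34 1.29

# organoid compartment, never overlapping the fibroblast masks
tumor <- tumor_area_series(phase, masks, cfg)
tumor$area
#>  [1] 2322 2315 2330 2318 2321 2321 2320 2317 2323 2332 2325 2319
```

The estimated shifts reproduce the phantom's known jitter exactly; the
growth series tracks the prescribed 8%/frame geometric law (1.08¹¹ ≈
2.34); every frame reports the five branches the star cohort was drawn
with; the motility sits slightly above the imposed 1 px/frame because a
growing cohort's boundary genuinely moves outward as well; and the
organoid area stays flat at the drawn disc area with zero overlap
between the tumor and fibroblast masks.

A command-line front end wrapping the same functions ships in
`inst/cli/organotrack` (subcommands `simulate`, `stabilize`,
`segment-fibro`, `flow`, `branch`, `segment-tumor`, `mrf`, `morpho`,
`stats`).

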