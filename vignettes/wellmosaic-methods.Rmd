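---
title: "Methods: synthetic well mosaics and region-coupled quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic well mosaics and region-coupled quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(wellmosaic)
```

## The assay wellmosaic models

In vessel-on-a-dish coculture models of intimal hyperplasia (IH),
endothelial cells (ECs) are seeded on a layer of cell-tracker-labeled
smooth muscle cells (SMCs) in 6-well plates and swirled on an orbital
shaker. Whole wells are imaged as stitched fluorescence mosaics and the
biology is read out regionally:

* the EC layer decomposes into confluent cobblestone **islands**,
  cord-like **networks** of elongated cells, and bare **gaps**;
* SMCs under EC defects proliferate and pile into 2–3-cell-thick
  **corrugated structures**, visible as elevated cell-tracker intensity;
* labeled plasma **fibronectin** is incorporated into ECM fibers only
  where the endothelium is defected;
* the orbital flow is pulsatile and near-laminar at the well **periphery**
  and disturbed in the **center**, so every statistic is reported per
  radial zone, split at the middle of the radial position.

wellmosaic implements this entire quantification chain — well fitting,
zoning, EC texture classification, nucleus detection with
ERG1 (EC identity) and ki-67 (proliferation) markers, island-normalized
SMC intensity, radial profiles, ANOVA/Tukey group comparisons, and a
closed-form orbital wall-shear-stress (WSS) estimate — together with a
synthetic scene generator that renders mosaics with exact ground truth, so
the whole pipeline is testable end to end.

## Synthetic scenes

`generate_scene()` renders six registered channels (EC = VE-cadherin
membrane + ERG1 nuclei, SMC cell tracker, fibronectin, DAPI, ki-67, ERG1)
inside a circular well on a square canvas.

**Scale.** Scenes use a scaled-down well: default pixel size 4 µm and well
radius 480 px (≈1.9 mm) on a 1024² canvas. A full 35 mm well at this
canvas would make 30 µm cells sub-pixel; shrinking the well rather than
the cells keeps single-cell texture resolvable while preserving the
center/periphery geometry. All statistics are area fractions, ratios or
rates, so they do not depend on the absolute well size.

**Region geometry with exact targets.** Island regions are the top
quantile of a long-wavelength Gaussian random field, selected per zone by
order statistics so ground-truth area fractions match the configured
targets to within one pixel. Blobs smaller than a minimum confluent-patch
size (`min_island_px`, default 600 px ≈ 12 cells) are removed and the
selection trimmed back skin-first to the exact count: confluent islands
are by definition multi-cell patches. Network cords follow level-set
contours of a second random field, dilated to a bounded half-width
(default 5 px ≈ 1–2 cell diameters); additional levels are added — with a
minimum separation between centerlines and a clearance around islands —
until each zone can meet its target, then the band is trimmed
pixel-exactly. When targets demand denser networks than comfortably
separated cords allow (static low-density cocultures), later passes pack
cords into a braided mesh. Remaining in-well pixels are gaps.

**Textures.** Island cobblestone is the watershed tessellation of a
smoothed noise field at the cell scale; membranes (tessellation borders)
are bright, interiors carry weak junctional signal. Under shear, the
peripheral field is generated on a polar grid with anisotropic smoothing,
elongating cells tangentially (axis ratio 2.5 by default) — the flow
alignment readout. Island and network mean brightness are deliberately
comparable: the classes differ by texture, not gain, as in the real
staining. Corrugations are ridged noise profiles confined to gap/network
regions, tangentially aligned in the sheared periphery, multiplying the
SMC baseline by `corrugation_multiplier` (default 2.5, the 2–3-cell
multilayer). Fibronectin fibers are thin anisotropic streaks restricted
to defected regions with intensity tied to local SMC intensity.

**Nuclei.** All nuclei come from one jittered-grid point process at the
combined EC+SMC density, spatially thinned to the local density and then
assigned an identity by the local rate ratio. A single hard-core process
(minimum separation ≈ 0.56 grid spacings) keeps every pair of nuclei
resolvable in the DAPI projection; a pure Poisson process at realistic
density would place ~30 % of nuclei closer than any peak detector can
separate, which is a property of the z-projection, not of the detector.
Consequently the generator does not add extra nuclei inside corrugated
multilayers — the multilayer is carried by the cell-tracker intensity
channel, which is how the assay itself quantifies layering.
Proliferation flags are Bernoulli draws from per-(zone × class) rates;
ERG1 is rendered only on EC nuclei and ki-67 only on flagged nuclei.

**Noise.** Per-tile multiplicative gain on a square grid emulates the
rectangular stitching pattern of mosaic acquisition, then Poisson shot
noise (expected photons per unit intensity, default 200) and additive
Gaussian read noise. Ground truth is fixed before any noise and is
invariant under global gain.

**Model presets** encode the three coculture models and the shear/static
contrast: quiescent (island ≈ 0.8, no corrugations, SMC proliferation
5 %), IH low density (islands 0.30 / networks 0.20 under shear,
0.15 / 0.35 static; SMC proliferation 5 % under islands vs 25 / 30 % in
networks/gaps; corrugations on), high density (confluent periphery,
small central gaps where proliferation is elevated), plus both
monocultures. Effect sizes follow the qualitative patterns of the assay
and are deliberately large so pipeline recovery is unambiguous; they are
fixture defaults, not estimates of the biological magnitudes.

**What the generator does not emulate:** 3-D structure and z-stacks,
photobleaching and temporal drift, optical vignetting within tiles,
cell-shape heterogeneity beyond elongation, immune cells and platelets,
and nucleus crowding inside multilayers (see above). Passing tests
therefore demonstrate that the quantification machinery is correct and
well-calibrated on images with this statistical structure — not that it
would segment any particular real microscope's output without
recalibration (`calibrate_params()` exists for exactly that).

## Texture classification

`binarize_ec()` smooths the EC channel (σ = 1 px), thresholds it (Otsu on
in-well intensities over range-anchored histogram bins, making the mask
exactly invariant under constant offsets), then applies morphological
closing (radius 2 px), size-limited hole filling (≤ 80 px, the dark
cobblestone interiors) and small-object removal.

`classify_regions()` separates islands from networks by **thickness**:
EC regions surviving a morphological opening of radius
`island_core_radius_px` (default 8 px) are island bodies — the opening
removes everything thinner than ~2 cell diameters without spilling onto
attached cords. Two guards follow: a local-coverage floor
(support-normalized sliding-window density ≥ `island_density_min`,
default 0.35 in a 31 px window) and an elongation veto (island components
with axis ratio ≥ 4 are cords seen at high coverage). Components smaller
than `min_object_px` merge into their surrounding class. The result is a
partition: every in-well pixel is island, network or gap. Ties at the
density floor go to island, the denser phase by definition.

The defaults were chosen by grid calibration against synthetic ground
truth (`calibrate_params()` reproduces the procedure); the classifier is
deliberately transparent — two interpretable features rather than a
learned texture model — so its failure modes are auditable.

`alignment_order()` estimates local orientation from the smoothed
structure tensor of the EC signal and reports
`mean(cos 2Δθ)` between the texture orientation and the tangential flow
direction over island pixels per zone (1 = tangentially aligned,
0 = isotropic, negative = radial). Pixels in the lowest quartile of
gradient energy carry no orientation and are excluded; zones without
usable island pixels are reported missing. The counter-clockwise tangent
convention is arbitrary but unobservable through the unsigned angle.

## Region-coupled statistics

* `coverage_fractions()` — per-zone class fractions (they sum to 1 by
  construction) plus total EC coverage; optional annular-sector ROIs
  (default 8 per zone) expose local variance the way repeated ROI
  measurements do.
* `detect_nuclei()` — DAPI local maxima (σ = 0.6 px smoothing, 3×3
  non-maximum suppression, Otsu floor); ERG1/ki-67 identity from mean
  intensity in a 2 px disk (threshold 0.2).
* `proliferation_by_region()` — % ki-67⁺ among SMC (ERG1⁻) nuclei per
  (zone × class), assigned by centroid pixel. Cells with fewer than
  `n_min = 20` SMC nuclei are reported missing, never 0: small-count
  percentages are noise, and the assay itself only reports regions with
  enough cells.
* `smc_layering_index()` — background-subtracted (median of outside-well
  pixels; no darkfield reference exists) mean cell-tracker intensity per
  class, normalized by the island mean *of the same zone*, so the island
  index is exactly 1 and the statistic is gain-free. Zone-wise rather
  than well-wise normalization keeps the island-≡-1 convention exact in
  both zones; with zone-uniform staining the two normalizers coincide.
* `radial_profiles()` — equal-width annular bins from rim to center;
  SMC/Fn means are min-max rescaled to 0–255 across the profile (the
  display convention of such plots), while the Fn/SMC ratio uses raw
  background-subtracted values — mixing the rescaled values into the
  ratio would destroy gain invariance. The ratio is undefined where SMC
  falls below a floor, and empty bins yield missing rows.
* `compare_groups()` — one-way ANOVA + Tukey HSD via `aov()` and
  `TukeyHSD()`, with broom-style `tidy()`/`glance()`. Star cutpoints
  default to the assay's caption convention (**** < 0.001, *** < 0.01,
  ** < 0.1, * < 0.5) and are configurable; zero within-group variance is
  flagged degenerate and exact-zero p-values print as "< 1e-6".

Total EC coverage is defined as islands + networks (not the binarized EC
area); the two differ only by segmentation error, and the label-map
definition keeps coverage consistent with the class fractions.

## Orbital shear

`stokes_wss()` evaluates the standard Stokes-second-problem estimate of
the peak wall shear stress under an orbitally swirled layer,

$$\tau = r_{orb}\sqrt{\rho\,\mu\,\omega^3},\qquad \omega = 2\pi\,\mathrm{rpm}/60,$$

with defaults 135 rpm, 9.5 mm orbit, ρ = 1000 kg m⁻³ and
μ = 7.8 × 10⁻⁴ Pa s (DMEM-like medium at 37 °C; media viscosities are
rarely reported, so μ is exposed as a parameter). This is a closed-form
stand-in for full free-surface CFD: `zone_shear_summary()` therefore
reports the published simulation-derived windows for a 6-well plate at
135 rpm (periphery 0.4–1.2 Pa, pulsatile-laminar; center 0.3–0.8 Pa,
disturbed) as fixed annotations, plus a consistency flag telling whether
the analytical value falls inside the peripheral window. The analytical
number is a cycle-peak wall value and should not be conflated with the
CFD time-mean; the module keeps both visible instead of merging them.
`rpm_to_beat_equivalent()` maps rotation frequency one-to-one onto a
heart-rate scale with configurable resting/exercise bands (defaults:
< 100 bpm resting, 100–190 bpm exercise).

```{r shear}
zone_shear_summary(shear_model())
```

## Numerical and design choices

* **Determinism.** Every scene is generated under `withr::with_seed()`
  from the config seed; the pipeline routes all randomness through one
  seed, and repeated runs write byte-identical CSVs (no timestamps in
  outputs; metadata headers carry the package version and a config hash).
* **Zone tie-break.** Pixels at exactly `split_fraction × R` belong to
  the periphery — one deterministic rule rather than a measure-zero
  ambiguity.
* **Coordinates.** Matrices are indexed `[y, x]` with the origin at the
  top-left pixel center `(1, 1)` (R's 1-based convention); nucleus
  coordinates are continuous pixel units in the same frame.
* **Nucleus region assignment** uses the centroid pixel, not the nuclear
  area majority: point statistics stay exact and deterministic.
* **Degenerate inputs.** Constant images binarize to empty masks (not
  errors); zones without island pixels fall back to zone-mean
  normalization with a flag; missing optional channels (Fn, ki-67, ERG1)
  propagate as missing results, not failures.

## Problem sizes used in the test battery

The shipped tests run the full pipeline at the generator's default scene
size (1024² canvas, radius 480 px) for the five-seed segmentation
recovery, an 880² scene for proliferation recovery (≥ 2000 SMC nuclei per
region class), and 480² fixtures for the six-model directional battery —
sizes at which each check's discriminating quantity (Jaccard indices,
binomial tolerances, directional contrasts) is well inside its noise
floor.

## Known limitations

* The texture classifier assumes cords thinner than ~2
  `island_core_radius_px` and islands thicker; tissues with intermediate
  morphology (very wide cords, perforated monolayers) blur the island /
  network boundary and should be recalibrated per dataset.
* The WSS estimate is a flat-wall boundary-layer formula; it carries no
  radial gradient, free-surface sloshing or secondary flow, which is why
  the zone windows are quoted rather than derived.
* 2-D projections cannot count nuclei inside true multilayers; layering
  is an intensity ratio, not a cell count.
* The generator's noise model (tile gain, shot noise, read noise) omits
  within-tile vignetting and focus variation across large mosaics.
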