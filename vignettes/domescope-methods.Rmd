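---
title: "Quantifying dome formation and epithelial organization in confocal z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dome formation and epithelial organization in confocal z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domescope)
```

## The measurement problem

Intestinal epithelial models built from Caco-2 enterocytes co-cultured with
mucus-producing HT29-MTX-E12 goblet cells differentiate over ~3 weeks on
permeable Transwell inserts. Two morphological signatures of successful
differentiation are *domes* — blister-like elevations of the polarized
monolayer produced by active basolateral fluid transport — and the vertical
organization of the tissue: how much of the field is cell-covered at each
height above the membrane, how cohesive the covered patches are, and how
round versus elongated they appear. Confocal z-stacks (a WGA/mucus channel
marking cellular presence and the apical mucus layer, plus a nuclei
channel) sample this organization as a series of optical sections at fixed
axial spacing, conventionally 2 µm, indexed from the membrane upward so
that section *i* lies at height *i·z_step*.

`domescope` turns such stacks into per-section coverage, object and
eccentricity profiles, a height-map reconstruction of the tissue top with
geometric dome detection and per-angle-view visibility counts, and
condition comparisons by exact Mann–Whitney tests. Closed-form calculators
for orbital shear stress, blank-corrected TEER, apparent permeability
(P_app) and flux AUC cover the accompanying barrier-physiology readouts.
A synthetic phantom generator with analytic ground truth makes every stage
testable without imaging data.

## Segmentation model

Each section is binarized by the chain: stack-level percentile
normalization → weighted grayscale projection → optional gamma enhancement
→ Gaussian pre-smoothing → local-mean adaptive thresholding combined with
a global intensity floor → mask hygiene. The tunables live in
`segmentation_config()`:

* `clip_percentiles` (default 1–99): robust normalization to a 0–1 range.
  The percentiles are computed **over the whole stack volume**, not per
  section. Per-section normalization stretches the detector noise of
  sections above the tissue top to full range, turning noise into
  foreground; volume-level percentiles leave empty sections dim.
* `channel_weights` (default mucus 1, nuclei 0): coverage is defined on
  the WGA/mucus channel, which marks cellular presence; the nuclei channel
  is kept for QC overlays only.
* `enhance_gamma` (default 1): a logged, parameterized gamma transform
  replaces interactive enhancement of weak signal, so that runs are
  reproducible; `γ < 1` brightens dim regions without reordering pixels.
* `smooth_sigma` (default 2 px): with noise sd around 0.05 on a 0–1 scale,
  an offset of 0.02 is well below the noise; smoothing reduces pixel noise
  by ~an order of magnitude so the offset discriminates structure.
* `block_size` 51 px, `offset` 0.02: a pixel is foreground when it exceeds
  the mean of its 51×51 window plus 0.02. The local rule is invariant to
  adding a constant to the image and tolerates the smooth illumination
  gradients of tiled mosaics.
* `floor_method` (default `"otsu"`): local-mean thresholding is a contrast
  detector — deep inside a covered region wider than the window, the
  window saturates and nothing exceeds its own mean, so a near-confluent
  monolayer would be detected only along its boundaries. A pixel is
  therefore also foreground when it exceeds Otsu's threshold of the
  normalized volume. The floor recovers sheet interiors; the adaptive rule
  still captures locally contrasted structure that a global threshold
  misses under illumination gradients.
* `min_object_px` 64, `fill_holes` FALSE, `connectivity` 8: speck removal
  is the noise guard; hole filling is off by default because, with the
  intensity floor, sheet interiors are detected directly and filling would
  erase genuine enclosed gaps in the monolayer.

Sections corrupted by glass-slide grid artifacts are excluded before
profiling. `flag_artifact_sections()` scans row/column mean profiles for a
sharp excursion (a thin line lifts its own profile bin far above bins two
pixels away). A section is flagged only when the excursion exceeds an
absolute floor (0.1) *and* 25 robust standard deviations of the profile's
own second differences; measured on phantoms, genuine texture — including
sections holding only a few bright dome caps — stays below ~20 robust sds
while a full-width 2 px line sits above ~80. Manual exclusion lists are
honored verbatim, and excluded sections carry missing values (never zero)
through all downstream profiles.

## Morphometry

Coverage is the fraction of foreground pixels per section. Contiguous
objects are connected components (8-connectivity by default; EBImage's
4-connected labeler is extended to 8-connectivity by bridging diagonal
contacts on a doubled grid). Each object is scored by pixel area and by
the eccentricity of the ellipse matching its second central moments: with
semi-axes *a ≥ b*, *e = √(1 − (b/a)²)*, 0 for a circle and →1 for a line;
this moments-based fit is deterministic and equivalent to the
foci-over-major-axis definition. Per-section eccentricity profiles are
aggregated over objects by the mean (default) or median — the choice is
exposed because either is defensible. Cross-replicate averages are flagged
`full` when every replicate contributes a non-missing value at that
section and `partial` otherwise; both are emitted.

## Height map and dome detection

The tissue top is `height(y,x) = z_step · (1 + highest foreground section
index)`, zero where nothing was detected; it depends only on the masks, so
it inherits their intensity invariances. The map is block-mean resampled
to a 128×128 grid (the working resolution for surface work; the map mean
is conserved). The display z-scale of 0.1 is cosmetic and never enters
measurements.

Dome detection replaces multi-angle visual counting of rendered surface
plots with an explicit geometric criterion:

1. **Gap bridging.** A grayscale closing (disk radius 8 px at grid 128)
   bridges sub-cellular gaps in the monolayer. Without it every gap pulls
   the baseline to the membrane and narrow monolayer ridges masquerade as
   prominences.
2. **Baseline.** The local monolayer level is the running median over a
   51×51 window (`baseline_radius_px = 25`). The median tracks the
   monolayer top as long as neither gaps nor dome footprints occupy half
   the window, and — unlike the classic rolling-disk opening, which is
   retained as `baseline_method = "opening"` — it neither collapses at
   unclosed gaps nor requires a structuring element large enough to bridge
   adjacent domes. All filters run on reflect-padded maps; truncated
   border windows otherwise under-fill with membrane-level zeros and fake
   prominence along the edge.
3. **Candidates.** Connected regions rising ≥ `min_prominence_um` (4 µm,
   two axial steps) above baseline with footprint ≥ `min_area_px` (25 px)
   become domes. A dome is an elevation *of* the epithelial sheet, so two
   island filters apply: the median baseline under a candidate must reach
   one axial step (`min_baseline_um`, rejects plateaus on bare membrane)
   and half the map's typical tissue level (`min_baseline_frac`, rejects
   tissue patches in sparsely covered pockets whose local baseline sits
   far below the monolayer). Caps whose elevated regions merge are
   reported as one dome with the combined footprint (fusion semantics);
   `exclude_border` optionally drops footprints cut by the field edge.
4. **Views.** From each of four azimuths a dome is *visible* when part of
   its footprint rises ≥ the prominence threshold above both the baseline
   and the running maximum of the terrain in front of it (the dome's own
   footprint is flattened while computing its occluders). The mean visible
   count over views reproduces the "average number of domes per angle
   view" readout; it equals the total count exactly when nothing occludes.

Per-dome area and height above baseline are computed and emitted even
though they are extensions beyond the per-view counts.

## Statistics

Per section, replicate coverage values of two conditions are compared with
a Mann–Whitney U test: U = #(xᵢ > yⱼ) + ½·ties, and for n₁+n₂ ≤ 12 the
p-value is exact by full enumeration of all group labelings (ties handled
via midranks; the permutation distribution of U is symmetric about
n₁n₂/2, and the two-sided p is the mass at least as far from the center as
observed). Larger samples use the tie-corrected normal approximation with
continuity correction. Raw p-values are reported alongside Holm-adjusted
ones (adjusted across sections).

The overall across-sections test collapses each replicate's profile to its
area under the coverage-versus-height curve (trapezoidal rule) and applies
the same test to the per-replicate AUCs. This keeps replicates — not
sections — as the independent units; pooling sections would
pseudo-replicate. Note the exact floor: with 3 replicates per group the
smallest attainable two-sided p is 0.1, with 4 it is ≈0.029, so overall
significance at 0.05 requires n ≥ 4.

## Barrier physiology

* Orbital shear: τ_max = a·√(ρη(2πf)³) with a the orbital radius; defaults
  ρ = 1000 kg/m³ and η = 9.5×10⁻⁴ Pa·s describe culture medium at 37 °C.
  At a 25 mm orbit and 55 rpm this gives 0.17 Pa (1.7 dynes/cm²).
* P_app = K·Vr/A (cm/s) with Vr = 1.5 mL and A = 1.12 cm² defaults.
  Receiver samples withdrawn and replaced with buffer dilute later
  measurements; concentrations are corrected by cumulative mass accounting
  (C_corr(t_k) = C(t_k) + (Vs/Vr)·Σ_{j<k} C(t_j)) before fitting K as the
  least-squares slope over the steady-state window (by default the final
  two-thirds of time points). Omitting the correction biases K low by a
  deterministic, simulation-checkable amount; `simulate_receiver_series()`
  provides the forward model (20-minute sampling over 3 h by default).
* TEER = (measured − blank) × area, in Ω·cm²; negative values are returned
  with a warning rather than silently clipped.
* `flux_auc()` is the trapezoidal rule; `dilution_nominal()` the nominal
  concentration after an n-fold dilution.

## The phantom: what it emulates, and what it does not

`phantom_spec()`/`generate_phantom()` build a two-channel stack of a flat
monolayer (thickness 14 µm by default, matching near-confluent coverage
through the first ~14 µm above the membrane) carrying spherical-cap domes,
with exact per-section ground-truth masks. The lateral monolayer pattern
is a Gaussian random field (correlation scale 16 px, a cell-cluster scale)
thresholded to exactly the target coverage, dome footprints always
included. The mucus channel is 0.4 through the cell body with a 1.0 shell
at the local top surface — a shell-only channel would make per-section
coverage unmeasurable, and WGA in practice marks cellular presence as well
as the apical mucus. Nuclei are isotropic Gaussian blobs (σ = 3 px) inside
the cell body. Noise is additive Gaussian, clipped at zero. The default
canvas is 512×512 px with 28 sections at 2 µm (heights 0–54 µm).

Deliberately not emulated: optical PSF and axial blur, Poisson photon
statistics, photobleaching, tile seams, mucus heterogeneity, or real cell
morphology. Passing the phantom-based checks therefore demonstrates that
the geometry pipeline is correct and noise-robust at the stated levels; it
does not by itself validate performance on real stacks, whose contrast
statistics differ.

Analytic oracles: below the monolayer top, coverage equals
`base_coverage` exactly (up to one-pixel rounding of the target count);
above it each cap of radius r and height H contributes a disk of radius
r·√(1 − (h/H)²), so analytic and mask-counted coverage agree within the
boundary quantization bound of ~2πr pixels per dome.

## Validation problem sizes

The test-suite and acceptance-script checks run at sizes chosen to
exercise the defaults while staying desk-scale: segmentation IoU against
ground truth on 20 phantoms at the default 512×512×28 with noise sd 0.05
(pooled IoU per phantom); coverage-vs-analytic fidelity at 0.02 absolute
per section; dome count/height recovery on 50 phantoms at 384×384×16 with
2–5 well-separated caps (radius 22–38 px, heights 8–14 µm, edge gaps
≥ 45 px), exact counts and apex heights within one axial step; Mann–Whitney
enumeration against a pair-counting permutation oracle on 100 random tied
datasets (n₁+n₂ ≤ 10); K recovery within 1% median relative error over 100
simulated permeability assays; and detection power for coverage 0.8 vs 0.5
with 4 replicates per group on 160×160×16 phantoms over 20 seeds. The
null size of the overall test is exercised at n = 3, where the exact
two-sided floor (0.1) makes false positives at the 0.05 level structurally
impossible.

## Known limitations

* Segmentation accuracy is boundary-limited: expect a 1–2 px misclassified
  band around object boundaries (smoothing plus thresholding), which
  dominates the error for small footprints in high sections.
* The dome/island distinction relies on `min_baseline_um`; tissue plateaus
  in very sparsely covered surroundings are ambiguous and can be counted
  either way depending on the baseline window.
* Heights are quantized to the axial step; cap heights are recovered at
  ±1 z-step at best.
* The Otsu floor assumes a roughly bimodal volume histogram (background
  vs tissue). Stacks without meaningful foreground, or with strong
  per-tile gain differences, should disable it (`floor_method = "none"`)
  and rely on the purely local rule.
* `per_section_comparison()` requires aligned section grids and at least
  two replicates per condition; the overall AUC test needs ≥ 2 non-missing
  sections per replicate.
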