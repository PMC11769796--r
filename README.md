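# domescope

Quantitative analysis of epithelial dome formation and 3-D tissue
organization in confocal z-stacks of intestinal co-cultures (e.g.
Caco-2/HT29-MTX-E12 on Transwell inserts), plus the closed-form
barrier-physiology calculators that accompany such experiments.

Differentiating intestinal epithelia organize vertically: a near-confluent
monolayer forms over the first ~14 µm above the membrane, mucus
accumulates at the apical surface, and active fluid transport lifts parts
of the sheet into blister-like *domes*. `domescope` measures this
organization from two-channel stacks (mucus/WGA + nuclei) acquired as
optical sections at fixed axial spacing:

* **Per-section morphometry** — adaptive binarization of each section
  (local-mean rule with a global Otsu floor), then coverage fraction,
  contiguous-object counts, and moments-based eccentricity
  (`e = sqrt(1 − (b/a)²)`, 0 = circle, →1 = line) per section.
* **Height-map dome analysis** — top-surface reconstruction
  (`height = z_step · (1 + top foreground section)`), block-mean
  resampling to a 128-grid, dome detection as connected regions rising
  ≥ 4 µm above a running-median monolayer baseline, and per-angle-view
  visibility counts with explicit occlusion geometry (mean domes per view
  over 4 azimuths).
* **Statistics** — Mann–Whitney U per section (exact by full enumeration
  for n₁+n₂ ≤ 12, ties included; tie-corrected normal approximation
  otherwise), Holm adjustment across sections, and an overall
  across-sections test on per-replicate profile AUCs.
* **Barrier physiology** — orbital shear stress
  `τ = a·sqrt(ρη(2πf)³)`, blank-corrected area-normalized TEER,
  apparent permeability `P_app = K·Vr/A` with sampling-replacement
  correction of the receiver series, and trapezoidal flux AUC.
* **Synthetic phantoms** — domed-monolayer stacks with exact ground truth
  (analytic spherical-cap coverage, per-section masks), used throughout
  the test suite; `self_test()` runs the whole pipeline on them.

## Worked example

```r
library(domescope)

# a synthetic two-channel stack: 80% covered monolayer + 3 domes
spec <- phantom_spec(seed = 42,
                     domes = random_domes(phantom_spec(), 3, seed = 42))
ph    <- generate_phantom(spec)
masks <- segment_stack(ph$stack, segmentation_config(smooth_sigma = 1))

prof <- coverage_profile(masks, z_step = spec$z_step)
head(prof[, c("section", "height_um", "coverage")], 8)
#>   section height_um   coverage
#> 1       0         0 0.79821396
#> 2       1         2 0.79827881
#> 3       2         4 0.79824448
#> 4       3         6 0.79831314
#> 5       4         8 0.79820251
#> 6       5        10 0.79820251
#> 7       6        12 0.81161118
#> 8       7        14 0.07078934
```

Coverage sits at the generated 80% through the monolayer (sections 0–6,
heights 0–12 µm) and drops to the dome cross-sections above it. Dome
detection on the reconstructed surface:

```r
hm <- resample_grid(height_map(masks, spec$z_step), 128)
dd <- detect_domes(hm)
dd[, c("dome_id", "area_px", "max_height_um", "eccentricity")]
#>   dome_id area_px max_height_um eccentricity
#> 1       1     327            10    0.1770927
#> 2       2     455            16    0.2137167
#> 3       3     323            10    0.5867521
count_per_angle_view(hm, dd)$average_per_view
#> [1] 2.75
spec$domes$cap_height_um          # planted cap heights, for comparison
#> [1] 14.643581  9.077333  8.939899
```

All three planted domes are recovered with apex heights within one 2 µm
section of the planted caps (height quantization rounds to the section
grid); the per-view average of 2.75 < 3 reflects one dome partly occluded
along one azimuth. Barrier physiology:

```r
orbital_shear_stress(orbital_diameter_m = 0.025, rotations_per_s = 55/60)
#> [1] 0.1684065       # Pa; 1.7 dynes/cm2
papp(K = 1e-6, Vr_ml = 1.5, A_cm2 = 1.12)$papp_cm_per_s
#> [1] 1.339286e-06    # cm/s
teer(900, 100, area_cm2 = 1.12)
#> [1] 896             # ohm cm2
```

`analyze()` (or the thin CLI wrapper in `inst/cli/domescope.R`) runs the
full pipeline over a set of stacks or phantom specs and writes
`coverage.csv`, `objects.csv`, `domes.csv`, `stats.csv` and a
`manifest.json` with the config hash and seed; reruns are byte-identical.

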