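# lungkin

Diaphragm weakness is the main driver of respiratory failure in
neuromuscular disease, but spirometry only sees the combined output of
all respiratory muscles — a failing diaphragm can hide behind
compensating chest-wall muscles. Time-resolved 3D imaging of a breathing
maneuver lets the two be separated: the lung surface regions resting on
the diaphragm and on the rib cage can be tracked independently, and the
volume each one displaces attributed to its muscle group.

`lungkin` implements that measurement chain for R. Given a binary lung
segmentation at full expiration and a displacement provider mapping
reference positions to each of the `T` frames of the maneuver (in
practice, the output of a groupwise B-spline registration), it

* extracts a watertight triangle surface mesh of the lung
  (`extract_mesh`),
* partitions it into costal, medial and diaphragmatic regions with a
  curvature watershed, convex-hull proximity and an anatomically seeded
  random walker (`partition_lung_surface`), solving the combinatorial
  Dirichlet problem `L_U x = -B s` on the weighted mesh graph with
  boundary-emphasising weights `w_ij = exp(-d_ij^2)`,
  `d_ij = w1‖p_i-p_j‖ + w2‖n_i-n_j‖ + w3 f(κ_ij)`,
  `f(κ) = 5κ (κ≥0), |κ| (κ<0)`,
* tracks the mesh through the maneuver (`propagate_mesh`) and computes
  the feature set that separates diaphragm from chest-wall action:
  volumes and size ratios B1–B6, region-wise swept volumes A1–A3
  (per-triangle prism volumes that telescope exactly to `V(t)-V(t+1)`
  over a closed surface), diaphragm excursion A4–A5, dome orientation
  A6–A7, and unfolded 2D excursion maps (`extract_features`,
  `excursion_map`),
* ships a synthetic dynamic lung phantom with analytic ground truth
  (`stock_phantom`, `generate_phantom`, `truth_labels`) against which
  the whole chain is validated, plus measurement-agreement metrics
  (`ase`, `mare`) and group-comparison statistics (`group_stats`).

Mask preprocessing utilities (Otsu thresholding, an iterative
bias-correction masking driver with pluggable corrector, physical-space
morphology, Dice overlap) round out the pipeline front end.

## Worked example

Generate a control-like phantom (healthy-subject motion: 20 mm dome
descent, posterior-greater excursion, dome tilt relaxing 20° → 5°, 15%
chest contraction), partition its surface, and measure:

```r
library(lungkin)

spec    <- stock_phantom("control", rng_seed = 1)
ph      <- generate_phantom(spec, mask_frames = spec$T)
mesh    <- extract_mesh(ph$reference_mask, target_edge_mm = 3.5,
                        smooth_iterations = 40)
part    <- partition_lung_surface(mesh, rng_seed = 1)
tracked <- propagate_mesh(mesh, ph$field, spec$T)
feats   <- extract_features(tracked, part, lung = "right")
round(feats$features[c("B1", "B3", "B4", "B5", "B6",
                       "A3", "A4_mm", "A5_mm", "A6_deg", "A7_deg")], 3)
#>     B1     B3     B4     B5     B6     A3  A4_mm  A5_mm A6_deg A7_deg
#>  0.858  1.494  1.183  1.150  1.029  0.155 24.304  2.996 25.074 -16.083
```

Reading the output: the phantom exhales from 1.28 L to a residual
volume (B1) of 0.86 L, a volume ratio (B3) of 1.49; the cranio-caudal
size change (B4 = 1.18) exceeds the antero-posterior one (B5 = 1.15),
so B6 > 1 — the diaphragm-dominated pattern of a healthy subject. The
diaphragm's mean cranial excursion (A4) is 24.3 mm with the posterior
half moving 3.0 mm more than the anterior (A5 > 0), and the dome
flattens from a 25.1° backward tilt by 16.1° during exhalation
(A6, A7). These are full-pipeline values, measured on the
automatically partitioned diaphragm label; measured against the
phantom's analytic labels instead (the decomposition `ph$truth` and
`truth_labels` provide), A4 lands within 0.1% of the analytic
area-weighted mean and A6/A7 within a degree of the nominal 20°/−15°
schedule — the difference is the partition's boundary behaviour at the
costophrenic rim, not the kinematics. A patient-like phantom
(`stock_phantom("patient")`) flips the signatures: B6 < 1,
A3 ≈ 0.05, A5 ≤ 0.

Per-triangle labels and excursion maps can be exported for external
rendering:

```r
write_ply(mesh, "labeled.ply",
          labels = as.integer(factor(part$label)))
write_excursion_map(excursion_map(tracked, part), "map.csv")
```

A thin command-line front end over the same functions is installed at
`inst/cli/lungkin.R` (subcommands `phantom`, `partition`, `features`,
`unfold`, `evaluate`).

## Method vignette

`vignettes/diaphragm-mechanics.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, the
phantom's design (including which features of real data it does and
does not emulate), numerical choices, and known limitations.
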