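# plaquemetry

Volumetric and planimetric quantification of de-novo dental plaque from
sequential intraoral scans.

## What problem this solves, and for whom

Dental-research groups that run plaque accumulation or plaque-control
studies usually score biofilm with ordinal clinical indices (e.g. the
Turesky modification of the Quigley-Hein Plaque Index, TMQHPlI) or with
2D planimetry of disclosed-plaque images. Both measure *coverage*, not
*amount*: a micrometre-thin stained film and a thick mature deposit count
the same. When the same tooth surfaces are captured with an intraoral
scanner before (T0, clean) and after (T4, plaque-bearing) a no-hygiene
period, the deposit itself becomes measurable: superimpose the two
surface meshes rigidly, and de-novo plaque is the positive deviation of
T4 from T0.

`plaquemetry` implements that digital workflow and the comparison
statistics around it:

* **Mesh I/O** — PLY / STL / OBJ (ASCII and binary), ROI definitions as
  JSON (vertex masks or closed boundary polylines flood-filled on the
  surface), TMQHPlI site-score CSVs.
* **Registration** — principal-axes pre-alignment, then robust trimmed
  point-to-plane ICP per ROI pair with a one-sided, noise-calibrated
  refinement that exploits the fact that plaque only pushes the surface
  outwards.
* **Volumetry** — the signed per-vertex thickness field
  d (mm, positive = deposit) with area weights a (mm²), and from it

  ```
  VPI  = Σ_v a_v · d_v   over vertices with d_v ≥ 0.01 mm      [mm³]
  AVPI = VPI / Σ_v a_v                                          [mm³/mm²]
  ```

* **Maps** — deterministic orthographic colour / categorized / Boolean
  thickness maps; the Boolean 0.01 mm map read planimetrically gives
  PLANIvolmap (%).
* **Disclosed planimetry** — trainable random-forest pixel segmentation
  of two-tone (pink new / purple mature) disclosed-plaque images into
  PLANItot, PLANIdark, PLANIlight = PLANItot − PLANIdark and the
  relative fractions.
* **Clinical index** — TMQHPlI site-score aggregation per surface.
* **Statistics** — Shapiro-Wilk; Friedman + Wilcoxon/Bonferroni across
  the four planimetric measures; Spearman and Passing-Bablok (on
  z-scores) matrices; ROC of VPI against dichotomized coverage
  (10/25/50%); Fisher-z sample-size; a two-segment growth-regime model
  of volume vs coverage.
* **Simulator** — synthetic crown surfaces with a known analytic plaque
  layer, scanner noise, pose offsets, two-tone images and TMQHPlI-like
  scores, used as ground truth for every other module.

## Worked example

Simulate one tooth surface with a known plaque layer, push it through
the measurement chain, and compare with the analytic truth:

```r
library(plaquemetry)
spec   <- syntheticSpec(edge_length = 0.15, seed = 42)
crown  <- makeCrown(spec)          # clean baseline surface (T0)
plaque <- addPlaque(crown, spec)   # 4-day plaque layer with known truth
scan   <- corruptScan(plaque$mesh_t4, noise_sd = 0.005,
                      rotation_deg = 3, translation_mm = 1, seed = 7)

fit <- bestFitROI(scan$mesh, crown$mesh,
                  init = preAlign(scan$mesh, crown$mesh))
fit
#> AlignmentReport: mean |d| = 0.00388 mm (SD 0.00284), inliers 82%, 48 iteration(s)

field <- signedDistanceField(crown$mesh,
                             applyTransform(fit@transform, scan$mesh))
computeVPI(field)
#> VolumetricIndices: VPI 0.7267 mm^3, AVPI 0.00786 mm^3/mm^2, area 92.475 mm^2, covered 19.8%

plaque$truth$true_volume           # analytic ground truth
#> [1] 0.7169436
```

The residual of the superimposition (0.0039 mm) sits at the scanner-noise
floor — the same order as the 0.0099 mm repeated-scan calibration
reported for this workflow — and the measured volume lands within ~1.4%
of the analytic truth. The Boolean coverage map and its planimetric
reading:

```r
bmap <- renderThicknessMap(field, crown$mesh,
                           projectionSpec(mesh = crown$mesh,
                                          pixel_size = 0.05),
                           mode = "boolean")
planiVolmap(bmap)                  # % of ROI pixels with >= 0.01 mm plaque
#> [1] 17.52727

sampleSizeCorrelation(0.66, alpha = 0.05, beta = 0.2)
#> [1] 15
```

A complete simulated study (meshes, images, scores on disk, then
measurement and cohort statistics):

```r
simulateStudy("study", n_subjects = 4, teeth_per_subject = 4, seed = 1)
res <- runStudy("study", runConfig(seed = 1))
res$records            # one row per surface: VPI, AVPI, PLANI*, TMQHPlI
res$stats$friedman     # comparison of the four planimetric measures
```

A thin command-line front end over the same functions lives in
`inst/scripts/plaquemetry-cli.R` (`simulate`, `run`, `measure`,
`stats` verbs).

## Documentation

The methods vignette (`vignettes/plaquemetry-methods.Rmd`) describes the
model, the registration robustness scheme, all numerical conventions and
tolerances, what the simulator does and does not emulate, and known
limitations. Function-level documentation is in the roxygen comments in
`R/`.
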