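---
title: "Quantifying de-novo dental plaque from sequential intraoral scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying de-novo dental plaque from sequential intraoral scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquemetry)
```

## The measurement problem

Clinical plaque scoring (ordinal indices such as the Turesky modification
of the Quigley-Hein index, TMQHPlI) and 2D planimetry of disclosed-plaque
images both describe how much of a tooth surface is *covered* by plaque.
Neither measures how much plaque is *there*: a film a few micrometres
thick and a mature deposit a fifth of a millimetre thick count the same.
Sequential intraoral scans offer a third route. If a clean baseline
surface (T0) and a plaque-bearing follow-up of the same surface (T4, after
some days without oral hygiene) are superimposed rigidly, de-novo plaque
appears as a positive deviation of the T4 surface from T0, and its volume
can be integrated directly.

`plaquemetry` implements this volumetric workflow end to end, together
with the planimetric and clinical measures it is compared against:

1. **Superimposition.** Coarse pre-alignment of whole models (centroid +
   principal axes, with the four proper sign choices disambiguated by
   nearest-surface RMS distance), then a robust best fit of each buccal
   region of interest (ROI) pair.
2. **Thickness field.** For each T0 ROI vertex the signed distance to the
   nearest point of the superimposed T4 surface, signed by the outward T0
   vertex normal, with barycentric (one-third incident-triangle) area
   weights.
3. **Indices.** The Volumetric Plaque Index
   $\mathrm{VPI} = \sum_v a_v d_v \,[d_v \ge \delta]$ (mm³) over the
   detection limit $\delta = 0.01$ mm, and the area-adjusted
   $\mathrm{AVPI} = \mathrm{VPI} / \sum_v a_v$ (mm³/mm²). A Boolean map
   (plaque present where $d \ge 0.01$ mm) is rendered in a canonical
   orthographic projection and read planimetrically as PLANIvolmap.
4. **Disclosed planimetry.** Two-tone disclosed-plaque images are
   segmented by a trainable random-forest pixel classifier into
   non-plaque, light/pink (new) and dark/purple (mature) plaque, giving
   PLANItot, PLANIdark and PLANIlight = PLANItot − PLANIdark.
5. **Statistics.** The full method-comparison plan: Shapiro-Wilk,
   Friedman with Wilcoxon/Bonferroni post hocs across the four
   planimetric measures, Spearman and Passing-Bablok (on z-scores)
   matrices, ROC of VPI against dichotomized coverage, and a two-segment
   growth-regime model of volume against coverage.

## Registration

The best fit is a trimmed point-to-plane iterative closest point (ICP)
procedure with symmetric correspondences (moved T4 vertices against the
T0 surface and T0 vertices against the moved surface), capped at 1 mm.
Point-to-plane linearization converges quickly on smooth enamel-like
geometry; the cap rejects gross mismatches.

Robustness to plaque is the central difficulty: at alignment time the
plaque extent is unknown, but the deposit is *one-sided* — it can only
push the T4 surface outwards. Three mechanisms exploit this:

* **Fraction trimming** (default 0.6 of correspondences kept, by
  smallest distance) suppresses the thickest deposits during the main
  iteration.
* **One-sided refinement.** After the trimmed phase, scanner noise is
  estimated from the *negative* residual tail (deposits never produce
  negative residuals), robustly as $\hat\sigma =
  \mathrm{median}(-r^-)/0.6745$, and the fit is re-solved keeping only
  residuals within $\pm 2.5\hat\sigma$. The band is symmetric because an
  asymmetric band would re-centre the least-squares fit with a bias; the
  noise estimate is forced monotone non-increasing across passes because
  residual misalignment can only inflate it, and letting it grow feeds
  back into an ever wider band.
* **A second basin.** When plaque covers a share of the surface close to
  the trim fraction, the trimmed phase can settle on a plaque-anchored
  minimum. A low-trim (0.25) run from the initial pose locks onto the
  dense clean-point cluster instead; between the two refined candidates
  the one with the *sharper lower residual tail* (5th-to-25th percentile
  spread) is kept, since a clean-anchored fit concentrates its noise-only
  tail and a plaque-anchored one smears it.

With scanner noise of SD 0.005 mm per scan, two noise-only scans of the
same surface align with a mean absolute ROI distance of roughly
0.005-0.01 mm, the same order as the published repeated-scan calibration
of this workflow (0.0099 mm). That noise floor, not the mesh resolution,
limits how small a volume difference the method can resolve: a residual
alignment bias of $b$ mm adds roughly $b \times$ (covered area) mm³ to
the VPI, which is why per-surface volumetric errors in the noisy
end-to-end pipeline are a few percent while the registration-free
volumetry is well under 1%.

## Numerical choices

* Field sampled on T0 vertices: the area normalizer of AVPI is then
  plaque-independent and comparable across timepoints.
* Negative deviations (abrasion, noise) are clamped out of the VPI —
  the index quantifies deposit. `computeVPI(..., signed_volume = TRUE)`
  subtracts them instead, for sensitivity analysis.
* Vertices whose nearest T4 point is farther than 1 mm are missing data;
  more than 20% missing aborts the surface (bad scan coverage should
  fail loudly rather than truncate silently).
* Mesh cleanup merges vertices within 1e-6 mm and drops zero-area faces;
  the tolerance sits three orders of magnitude below the 0.01 mm
  detection limit, so cleanup cannot create apparent plaque.
* ICP stops when the trimmed mean absolute distance changes by less than
  1e-6 mm (or 100 iterations, flagged non-converged); the refinement
  pass stops on a transform increment below the same tolerance.
* The orthographic projection is deterministic: view along the
  area-weighted mean outward ROI normal, up vector from the
  occluso-gingival axis, 0.02 mm/px default. Viewer screenshots are not
  reproducible; a canonical projection is. Because 2D planimetry of a
  curved surface is inherently foreshortened (a flat patch tilted 60°
  projects to half its area), the package reports both the projected
  PLANIvolmap and the area-weighted 3D coverage (`surfaceCoverage`).
* Rounding of mean TMQHPlI scores to whole scores is half-up
  (`roundHalfUp`); the convention is exposed rather than buried.
* Friedman p-values use the exact within-block permutation null whenever
  the permutation count $(k!)^n \le 2\times10^5$, because the chi-square
  approximation deviates from the exact null by up to ~0.13 at the block
  counts where this package is typically exercised; the chi-square
  approximation (used by mainstream clinical statistics software, and
  therefore by `studyStatistics`) remains available via `p.method`.
* Wilcoxon signed-rank tests drop zero differences and use the exact
  null for up to 25 non-zero differences without ties, the normal
  approximation with continuity correction otherwise. Bonferroni
  multiplies by the number of pairwise tests actually performed (6 for
  the four planimetric measures).
* Passing-Bablok follows the 1983 shifted-median construction: 0/0
  slopes and slopes of exactly −1 excluded, offset K = number of slopes
  below −1, binomial-quantile rank confidence intervals, intercept as
  the median of $y - bx$. Variables are marginally standardized to
  z-scores first (the indices live on different scales); the raw-scale
  fit is available with `use_zscores = FALSE`.
* ROC dichotomization interprets the cut points as absolute coverage
  thresholds (10%, 25%, 50% of the surface); an empirical percentile
  split is available via `percentile_split = TRUE`, since either reading
  of a "10:90%" dichotomization is defensible.
* The growth-regime model fits a continuous two-segment linear function
  of volume against total coverage by grid search over the data
  quantiles with least squares within segments, and separately reports
  the linear fits of volume on dark and on light coverage. If no
  breakpoint improves the residual sum of squares by more than 1% over a
  single line the single line is returned, flagged. Whether the
  published ~32.5% regime change was derived by segmented regression or
  by intersecting the dark/light linear fits is not documented anywhere;
  both routes are implemented and neither is claimed to be *the*
  original computation.
* Surfaces are analysed as independent observations (matching the
  published analysis, which acknowledges the resulting variance
  underestimation); a subject-level bootstrap for the breakpoint is
  available but off by default.

## The synthetic test bed

Real cohorts of this kind involve manual ROI delineation and scanner
hardware, so the package ships a simulator that generates the full study
with known ground truth. Its defaults *are* the study conditions and are
not tuned per analysis:

* **Crown patches.** Smooth superellipsoid-profile buccal patches about
  8 × 10 mm (area within the plausible 50-150 mm² premolar/incisor
  range), with a gingival-cervical bulge and slight mesiodistal skew, as
  real buccal surfaces have — the asymmetry also makes the principal
  axes of a patch unambiguous for pre-alignment. Meshed on a parameter
  grid at a 0.1 mm target edge by default.
* **Plaque layer.** A smooth random coverage field (40 cosine waves,
  wavelengths 4-8 mm) biased towards the gingival margin, thresholded to
  hit a target *volumetric* coverage (area with thickness ≥ 0.01 mm) and
  offset along the analytic surface normals. Thickness rises from a
  0.015 mm floor (a detectable deposit has finite height; colonies are
  not arbitrarily thin films) through a smooth ~1.2 mm-wide taper to a
  local maximum of ~0.15 mm, stronger near the gingiva. Gentle lateral
  slopes matter: the nearest-surface distance under-reads a slanted
  offset by a factor $1/\sqrt{1+|\nabla t|^2}$, so a generator with
  knife-edge margins would make the measurement look biased when the
  geometry, not the code, is at fault.
* **Volumetric vs stained coverage.** In the emulated study conditions
  volumetric coverage averages ~19% of the surface (beta-distributed,
  rarely above 45%), while the disclosing dye stains a region ~2.4 times
  wider — thin films far below what the scanner can reconstruct. The
  stained film therefore exists only in the rendered two-tone image and
  the TMQHPlI scores, never in the T4 geometry. This reproduces
  mechanistically the well-known gap between disclosed-plaque planimetry
  (~46% mean coverage) and Boolean volumetric maps (~19%), a factor of
  about 2.47.
* **Ground truth** is always computed by fine-grid quadrature of the
  analytic thickness field on the parametric surface (800² points by
  default), never by the volumetry module, so volume recovery is checked
  against an independent oracle.
* **Scans** add Gaussian displacement along normals (SD 0.005 mm) and a
  rigid pose offset (3°, 1 mm); **two-tone images** colour the stained
  region pink, its thickest `maturity_fraction` (the dark/mature
  sub-region, ~50%) purple, on pale enamel, with additive pixel noise
  (SD 0.02); **TMQHPlI site scores** derive from true stained and dark
  coverage through the Turesky band definitions (0 none; 1 flecks; 2
  band ≤ 1 mm; 3 up to one third; 4 one to two thirds; 5 beyond) with
  ±1 ordinal examiner noise at probability 0.1.

What the simulator does *not* emulate — colour-calibration drift of
scanner textures, specular highlights, saliva, scan stitching artefacts,
calculus, true biofilm growth dynamics — bounds what passing tests mean:
they validate the geometry, the segmentation machinery and the
statistical chain, not performance on arbitrary clinical imagery.

## Problem sizes used in the shipped checks

The automated checks run the simulator at mesh edges of 0.1 mm where the
quantity under test is resolution-sensitive (volume recovery: 20 seeded
crowns, every surface within 2% of analytic truth) and 0.15-0.3 mm
elsewhere; segmentation trains on two rendered images and evaluates on a
held-out third (per-class intersection-over-union ≥ 0.90); the
growth-regime recovery simulates cohorts of 150 surfaces; the end-to-end
determinism check runs a 2-subject study twice and compares output bytes.
`scripts/acceptance.R` recomputes the same headline quantities from
scratch under a caller-supplied seed.

## Known limitations

* Extreme volumetric coverage (beyond roughly 60-70% of a surface)
  leaves too little clean geometry to anchor any rigid fit; surfaces in
  that regime carry a visible inward bias. The published study's
  volumetric coverage tops out around 43%, comfortably inside the safe
  regime.
* The thickness field is single-valued along T0 normals; overhanging
  deposits and interproximal plaque wrapping around the contact point
  are out of scope, as is non-rigid change (eruption, abrasion).
* Volumetric resolution is bounded by scanner noise through the
  registration, at roughly the published 0.01 mm calibration; claims
  below ~10 µm mean thickness difference per surface are not supported.
* The pixel classifier is trained per study; no pretrained model is
  shipped, and its IoU on synthetic dyes does not transfer to
  uncalibrated clinical photographs.
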