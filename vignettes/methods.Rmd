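---
title: "Knowledge-based proton planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based proton planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

protonKBP implements a knowledge-based planning (KBP) loop for
intensity-modulated proton therapy (IMPT): a library of treatment plans is
parameterized into geometric and dosimetric features, a per-organ
regression learns how achievable organ-at-risk (OAR) dose-volume
histograms (DVHs) depend on patient geometry, and the learned model
predicts DVH bands for new cases, from which optimization objectives are
placed automatically. This vignette documents the models, the tunable
parameters and the numerical choices, and states plainly what the
synthetic test bed does and does not demonstrate.

## The geometry-based expected dose (GED)

The geometric feature at the heart of the model is a surrogate per-voxel
dose computed from the target prescriptions and the beam arrangement
alone, using a simplified spread-out Bragg peak (SOBP) picture. For each
beam field and each target level (boost `PTV_B`, transition `PTV_O`,
elective `PTV_E` of the simultaneous-integrated-boost prescription), every
ray through the grid is classified against the target:

* voxels inside the target interval receive the level prescription
  $D_p$;
* voxels upstream at distance $d$ from the target entry receive an entry
  dose $D_p\,r(L)\,\max(0,\,1 - d/d_e)$, where $L$ is the target length
  along the ray. The entry ratio $r(L) = a_0 + a_1 L/(L + L_0)$ is
  monotone increasing and bounded by 1, reflecting that longer modulated
  targets deposit a higher proximal plateau;
* voxels downstream at distance $d$ past the distal edge receive
  $D_p\,e^{-d/s}$, a sharp exponential fall-off.

If a ray crosses a non-convex target more than once, the disjoint
crossings are treated as separate sub-targets and a voxel between them
takes the maximum of the proximal sub-target's fall-off and the distal
sub-target's entry dose — strictly less than $D_p$, which is exactly the
dose-sparing opportunity a gap offers a proton beam.

Fields of one level are combined by voxelwise *mean* (keeping the GED on
the prescription scale, so target voxels still carry $D_p$ after
combination), levels by voxelwise *maximum*. The total is grey-dilated
and convolved with a 3-D Gaussian to emulate the lateral penumbra.

Defaults (all configurable through `gedParams()`):

| parameter | default | unit | role |
|---|---|---|---|
| `a0`, `a1`, `L0_mm` | 0.6, 0.4, 50 | —, —, mm | entry ratio $r(L)$ |
| `entry_decay_mm` | 150 | mm | linear taper of entry dose |
| `falloff_s_mm` | 4 | mm | distal exponential scale |
| `dilation_mm` | 4 | mm | grey dilation radius |
| `sigma_mm` | 4 | mm | Gaussian penumbra sigma |
| `tau_in_Gy`, `tau_out_Gy` | 5% of lowest prescription | Gy | partition thresholds |

Only the *dependencies* of a proton GED are physically dictated (target
length, distance, fall-off steepness, a dilation-plus-Gaussian penumbra);
the functional forms and constants above are the package's own choices,
selected to be monotone, bounded and qualitatively SOBP-like, and every
model archive records the values used. No claim is made that they equal
any commercial implementation; all checks on the GED are property-based
(closed-form agreement on slab geometries, monotonicity, the sub-target
inequality).

Every OAR is partitioned against the smoothed GED into a target-overlap
region, an in-field region (GED at or above threshold, no overlap) and an
out-of-field region. Voxels between the two thresholds (when they differ)
join the in-field region, the conservative side, so that borderline voxels
are modelled rather than averaged; with the default single threshold the
band is empty.

## Model extraction and training

For each library case the in-field GED DVH and the achieved in-field dose
DVH are sampled as dose-at-volume on a fixed 100-point volume grid, doses
normalized to the highest prescription (70 Gy). Principal-component
analysis parameterizes each curve family; the component count is the
smallest explaining 95% of variance, capped at 5. The regression maps the
geometric features — GED-DVH PC scores plus OAR volume, target-overlap
fraction, union-target volume and out-of-field fraction — to the achieved
dose PC scores. Features are standardized; the estimator is least squares
with a small ridge penalty on the slopes whose weight is selected per OAR
by the analytic leave-one-out error of the dose-PC1 regression (the
plain-OLS solution is in the candidate set and wins whenever it
generalizes best; an ill-conditioned design simply never selects it). The
reported $R^2$ is that of the dose-PC1 regression, the component the
regression plots pair with geometric score 1.

The low-modulation regions are not regressed: their library mean DVH
± one SD forms the prediction band directly. One refinement matters under
a simultaneous-integrated-boost prescription: the overlap band is kept
*per target level* (overlap with `PTV_B`, `PTV_O` and `PTV_E` averaged
separately, then mixed by the prospective case's level-specific overlap
fractions). A single pooled overlap band systematically biased
predictions for midline swallowing structures, whose overlap composition
varies strongly from case to case while the overlap dose tracks the
overlapped level's prescription.

Prediction reconstructs the in-field median curve from the predicted
scores; the band is the reconstruction at ±1 residual SD (configurable
multiplier). Region curves are merged into a full-OAR DVH by pooling
dose-at-volume samples weighted by region volume fractions and rebuilding
the weighted survival curve — which is monotone by construction, so no
isotonic projection step is needed. Scalar features outside the training
min/max range raise geometric-outlier flags; flagged predictions are
extrapolations and are reported as such, never suppressed.

Outlier curation (`curateOutliers()`) flags training points with
|studentized residual| > 3 or leverage > 3(p+1)/n in the dose-PC1
regression. Flagging is diagnostic only: removal means retraining on a
reduced library, a deliberate user action, mirroring the practice of
restrained, plot-driven curation.

## The toy dose engine

Clinical proton optimizers and dose algorithms are proprietary; the
package ships a declared, simple engine whose role is to produce
*DVH-realistic* plans, not clinical dose accuracy:

* **Spots.** Lateral Gaussian pencil beams, in-air sigma 3.9 mm at the
  isocenter, spot spacing 0.425 × the in-air FWHM; energy layers 5 mm
  apart in depth, each a mini-SOBP (flat top of one layer spacing,
  constant entry plateau 0.3, distal fall-off scale shared with the GED).
  Lateral sigma grows linearly with layer range (0.015 mm/mm) as a
  scattering surrogate. Per-field margins: 2 mm proximal, 3 mm distal,
  5 mm lateral. A 57-mm water-equivalent range-shifter offset is carried
  in the nominal-range bookkeeping; the phantom itself is
  water-equivalent.
* **Optimization.** Dose is linear in the non-negative spot weights
  (multi-field optimization: all fields jointly). Objectives are weighted
  quadratic penalties — two-sided for target uniformity (with under-dose
  weighted 4× so the coverage aims of 95% of prescription to 99%/98% of
  `PTV_B`/`PTV_E` are reachable), one-sided for mean-dose, maximum-point
  and upper dose-volume objectives; dose-volume objectives use the
  standard per-iteration voxel selection (the hottest allowed fraction is
  exempt). The solver is projected gradient descent with a Jacobi
  (column-norm) preconditioner and a backtracking line search, so the
  accepted objective sequence is non-increasing and the run is
  deterministic. Sparing objectives act on the OAR cropped from the
  target union, standard practice to avoid fighting target coverage in
  overlap regions.
* **Manual-plan emulation.** Interactive planning is emulated as
  objective re-weighting rounds: a target-only optimization, then two
  rounds in which every modelled OAR receives a mean-dose objective at
  0.75 × its currently achieved mean. A per-case planner-skill factor,
  uniform on [0.6, 1], scales the OAR priorities and is the deliberate
  source of library variability — the inter-planner spread that
  knowledge-based models exist to learn. A continue-optimization step
  (target priorities × 6, warm start) runs whenever the coverage aims are
  missed, mirroring its clinical use in most cases.
* **Knowledge-based plans** optimize against three upper dose-volume
  objectives per OAR placed on the lower prediction boundary at the
  10/50/85% volume anchors (offset 0 by default), with OAR priorities
  mirrored from the manual plan's skill factor, then the same
  continue-optimization policy, and are finally normalized to the manual
  plan's mean boost-PTV dose before any comparison.

## The phantom cohort

`generateCohort()` emulates a head-and-neck cohort: an elliptical
water-equivalent body; an irregular superellipsoid boost volume with
angular boundary noise; the transition shell constructed *exactly* as the
5-mm dilation of the boost minus the boost, clipped to the body; an
elongated elective envelope including an inferior nodal-like extension;
paired parotid/submandibular analogs placed laterally; midline oral
cavity, pharyngeal-constrictor, larynx, cricopharynx and
upper-esophageal-sphincter analogs; cord and brainstem analogs for the
fixed maximum-dose objectives. OAR volumes are truncated normals matched to reported head-and-neck
population statistics (mean ± SD clipped to min–max, e.g. parotid
27.6 ± 8.9 cm³ on 12.3–46 cm³; see `defaultOARMenu()`). Gantry
angles are drawn from the standard three-field ranges (35–55°, 180°,
305–330°). A per-OAR proximity factor (uniform on [0, 0.35], recorded in
the manifest) pulls structures toward the boost to produce variable PTV
overlap; clinical anatomies constrain overlap only loosely, so the
overlap distribution is a documented generator choice.
Everything is deterministic given `(seed, index)`.

What the phantoms do **not** emulate: CT intensities and tissue
heterogeneity (range uncertainty is out of scope), realistic cervical
anatomy beyond topology, inter-observer contouring variation, and
non-coplanar or case-adapted beam arrangements. Consequently, passing the
end-to-end study analog shows that the pipeline is *internally*
consistent — geometry drives achievable dose, the model recovers the
relationship, and the resulting plans match their predictions — not that
the specific accuracy numbers transfer to clinical data.

## Numerical choices and degenerate inputs

* Ray casting quantizes voxel centres into rays at the in-plane
  resolution after rotating into the beam frame; depths are quantized to
  the same step, which makes the engine exactly reproducible by a scalar
  1-D implementation on axis-aligned geometries (tested to 1e-9).
* DVH curves use 0.05-Gy bins with linear interpolation; metric error is
  below one bin. Region curves for modelling use exact empirical
  quantiles instead of bins.
* The transition target `PTV_O` is stored explicitly by the generator and
  carries an interpolated prescription of 62.125 Gy (the 70/54.25
  midpoint; the source prescription for the transition region is not
  stated). Its uniform objective gets low priority — it exists to shape
  the gradient, not to be homogeneous.
* PCA of a zero-variance curve family returns a single component with
  all scores zero. Regressions with constant features survive via the
  ridge candidate. Empty in-field regions route an OAR to the
  low-modulation path; an OAR entirely inside a target is pure overlap.
* Laterality ties (equal overlap) fall back to centroid distance; a pair
  identical in both criteria is an error rather than an arbitrary label.
* Optimizer determinism: fixed iteration budgets, no stochastic steps;
  the only randomness in the study is the seeded phantom sampling and the
  seeded planner skill.

## Problem sizes

The study analog uses 50 library + 10 evaluation phantoms on a 4-mm
isotropic grid (≈ 40,000 voxels per case, ≈ 6,000–12,000 spots per
case), the sizes at which the full pipeline — GED, influence matrices,
four optimizations per evaluation case, training and prediction — runs
comfortably on a single desktop core. A clinical-scale deployment would
use the 2.5-mm grid default of `VoxelGrid` and denser energy layers; all
algorithms are resolution-independent.

## Known limitations

Non-robust optimization only (worst-case or probabilistic robustness is
out of scope); physical dose only, constant RBE 1.1 implied; no
leaf-transmission region (protons have none); point dose-volume
objectives rather than full-curve line objectives; no automatic priority
learning; the GED constants and the manual-planning emulation are
declared stand-ins, evaluated by their properties, not by equivalence to
any commercial system.
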