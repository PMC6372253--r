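# protonKBP

Knowledge-based treatment planning for intensity-modulated proton therapy
(IMPT), in R.

Treatment planning for head-and-neck IMPT is slow and planner-dependent:
how much parotid or swallowing-muscle sparing is *achievable* for a given
anatomy is not obvious, so plan quality varies. Knowledge-based planning
(KBP) attacks this by learning, from a library of previous plans, how
achievable organ-at-risk (OAR) dose-volume histograms (DVHs) depend on
patient geometry, then using the learned model to predict a DVH range for
a new patient and to place optimization objectives automatically.

protonKBP implements the full loop with a proton-specific geometric
feature and a simplified pencil-beam dose engine, plus a seeded generator
of head-and-neck-like phantom cohorts so that every stage is testable
without clinical data. It is aimed at medical-physics researchers who
want an open, end-to-end testbed for KBP methodology.

## The model

**Geometry-based expected dose (GED).** For each beam field and each
target level of the simultaneous-integrated-boost prescription
(70 / 62.125 / 54.25 Gy to boost / transition / elective PTV in 35
fractions), every voxel receives a surrogate dose from a simplified
spread-out-Bragg-peak picture: the prescription $D_p$ inside the target;
an entry dose $D_p\,r(L)\,(1 - d/d_e)_+$ upstream (larger for longer
target chords $L$, fading with distance $d$); a distal fall-off
$D_p e^{-d/s}$ downstream. Disjoint crossings of a non-convex target act
as separate sub-targets, which lowers the expected dose in the gap.
Fields are averaged, levels combined by maximum, and the total is dilated
and Gaussian-blurred into a penumbra.

**Model.** Each OAR is partitioned into target-overlap, in-field and
out-of-field regions. In-field GED DVHs and achieved DVHs are
parameterized by principal components; a per-OAR regression (standardized
features, leave-one-out-selected ridge) maps geometric features — GED-DVH
PC scores, OAR volume, overlap fraction, target volume, out-of-field
fraction — to achieved-DVH PC scores. Low-modulation regions use their
library mean DVH ± SD (the overlap band kept per target level).
Prediction yields a lower/median/upper DVH band per OAR; upper
dose-volume objectives are placed on the lower boundary at the 10/50/85%
volume anchors, a plan is optimized (projected gradient,
multi-field spot-weight optimization), continued if target coverage aims
(V95 ≥ 99%/98% for boost/elective) are missed, and normalized to the
manual plan's mean boost-PTV dose for comparison.

Endpoints follow standard plan-quality metrics: homogeneity index
HI = 100·(D2% − D98%)/D50%, V95, mean OAR dose (plus combined salivary
`comp_sal` and swallowing `comp_swal` composites), maximum dose for cord
and brainstem analogs, and predicted-vs-achieved mean dose with
geometric-outlier flags for cases outside the training feature ranges.

## Worked example

```r
library(protonKBP)

spec <- cohortSpec(n_cases = 1, seed = 42)    # head-and-neck phantom spec
case <- generateCase(spec, 0)$case
case
#> PlanCase 'phantom_000'
#> VoxelGrid: 41 x 37 x 29 voxels, spacing 4 x 4 x 4 mm
#>   targets: PTV_B (70 Gy), PTV_O (62.12 Gy), PTV_E (54.25 Gy)
#>   OARs: 15 | fields: 36.02061/180/313.8467 deg | 35 fractions

ged <- computeGED(case)                        # proton GED, all fields/levels
partitionOAR(caseOAR(case, "parotid_left"), ged, case)
#> OARPartition 'parotid_left': overlap 0.0%, in-field 60.2%, out-of-field 39.8%

plan <- makeManualPlan(case, seed = 42)        # library-style plan
plan
#> PlanResult (manual): 13091 spots, V95_B 100.0%, V95_E 97.5%, aims NOT met

dvhB <- computeDVH(plan@dose, caseTargets(case)$PTV_B)
sprintf("PTV_B: mean %.2f Gy, HI %.2f%%",
        meanDose(plan@dose, caseTargets(case)$PTV_B), homogeneityIndex(dvhB))
#> "PTV_B: mean 70.43 Gy, HI 9.16%"
meanDose(plan@dose, caseOAR(case, "parotid_right"))
#> 2.80  # Gy, contralateral parotid
```

The boost target receives its 70 Gy prescription homogeneously (HI ~9%)
while the contralateral parotid analog is spared to under 3 Gy mean dose;
the elective V95 of 97.5% sits just below the 98% aim, which is what the
continue-optimization phase inside the study pipeline then escalates.

The full study — generate 50 library + 10 evaluation phantoms, build
manual plans, train, predict, place objectives, optimize knowledge-based
plans, normalize, evaluate — is one call:

```r
res <- runStudy(seed = 1)
res$accuracy$summary     # predicted vs achieved mean dose per OAR
res$comparison$summary   # KBP vs manual HI/V95/mean-dose deltas
res$diagnostics$r2_table # per-OAR regression R^2
```

A thin command-line front end with per-stage subcommands
(`generate-cohort`, `ged`, `plan`, `train`, `predict`, `make-objectives`,
`run-study`) is installed at `inst/cli/protonkbp.R`.

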