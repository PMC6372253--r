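makeInfl <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- caseInfluence(miniCase())
        cache
    }
})

test_that("spot grid follows the spacing rule and dose is linear in weights", {
    case <- miniCase()
    infl <- makeInfl()
    # lateral spot spacing = 0.425 x in-air FWHM
    us <- sort(unique(infl@spots$u_mm[infl@spots$field == 1]))
    fwhm <- 2 * sqrt(2 * log(2)) * 3.9
    expect_equal(min(diff(us)), 0.425 * fwhm, tolerance = 1e-9)
    # linearity / superposition
    set.seed(1)
    w1 <- runif(ncol(infl@A)); w2 <- runif(ncol(infl@A))
    d1 <- influenceDose <- as.numeric(infl@A %*% w1)
    d2 <- as.numeric(infl@A %*% w2)
    d12 <- as.numeric(infl@A %*% (w1 + w2))
    expect_equal(d12, d1 + d2, tolerance = 1e-9)
    # doubling one spot weight doubles exactly its contribution
    j <- which.max(Matrix::colSums(infl@A))
    wj <- numeric(ncol(infl@A)); wj[j] <- 1
    dj <- as.numeric(infl@A %*% wj)
    w3 <- w1; w3[j] <- w3[j] + 1
    expect_equal(as.numeric(infl@A %*% w3), d1 + dj, tolerance = 1e-9)
})

test_that("single-spot profiles match the closed forms", {
    # a deep-seated small target in a water box, single posterior field
    dims <- c(21L, 40L, 21L)
    grid <- voxelGrid(dims, 2)
    tgt <- boxMask(dims, c(10, 12), c(18, 22), c(10, 12))
    body <- array(TRUE, dims)
    case <- planCase("probe", grid,
        list(targetLevel(rtStructure("PTV_B", tgt, "target"), 70)),
        oars = list(rtStructure("body", body)),
        fields = list(beamField(0, rtStructure("PTV_COMP", tgt, "target"))))
    params <- engineParams()
    infl <- buildInfluence(case, case@fields[[1]], params,
                           voxels = which(array(TRUE, dims)))
    # central spot of a mid-range layer
    sp <- infl@spots
    cand <- which(abs(sp$u_mm) < 1 & abs(sp$z_mm) < 1)
    j <- cand[which.min(abs(sp$range_mm[cand] -
                            stats::median(sp$range_mm[cand])))]
    dj <- array(as.numeric(infl@A[, j]), dims)
    # depth profile along the voxel column nearest the spot axis: the
    # constant lateral factor at the column offset times the closed form
    ys <- axisCoords(grid, 2)
    onaxis <- dj[11, , 11]
    depth <- ys + 40
    latfac <- exp(-(sp$u_mm[j]^2 + sp$z_mm[j]^2) / (2 * sp$sigma_mm[j]^2))
    expected <- latfac * sobpDepthProfile(depth, sp$range_mm[j], params)
    nz <- expected > 1e-2
    expect_equal(onaxis[nz], expected[nz], tolerance = 1e-9)
    # lateral profile at the peak depth is Gaussian with the layer sigma:
    # quadratic log fit (with a linear term for the spot offset) recovers
    # the configured sigma exactly
    iy <- which.min(abs(depth - sp$range_mm[j]))
    lat <- dj[, iy, 11]
    xs <- axisCoords(grid, 1)
    keep <- lat > 1e-2
    fit <- lm(log(lat[keep]) ~ xs[keep] + I(xs[keep]^2))
    expect_equal(as.numeric(-1 / (2 * coef(fit)[3])), sp$sigma_mm[j]^2,
                 tolerance = 1e-6)
    expect_lt(mean(residuals(fit)^2), 1e-12)
})

test_that("optimizer descends monotonically and covers a bare target", {
    case <- miniCase(two_oars = FALSE)
    infl <- caseInfluence(case)
    plan <- optimizePlan(infl, case, targetObjectives(case),
                         iterations = 80)
    lg <- plan@convergence
    expect_true(all(diff(lg) <= 1e-9))
    full <- continueOptimization(plan, infl, case)
    expect_gte(full@metrics$v95_b, 99)
    # deterministic re-run
    plan2 <- optimizePlan(infl, case, targetObjectives(case),
                          iterations = 80)
    expect_identical(plan@spot_weights, plan2@spot_weights)
})

test_that("zero-priority OAR objectives reproduce the pure target fit", {
    case <- miniCase()
    infl <- makeInfl()
    tObj <- targetObjectives(case, serial_max_Gy = c())
    withZero <- rbind(tObj,
        objRow("parotid_left", "mean_dose", 5, 0),
        objRow("oral_cavity", "upper_dose_volume", 10, 0,
                     volume_percent = 50))
    p1 <- optimizePlan(infl, case, objectiveSet(tObj), iterations = 40)
    p2 <- optimizePlan(infl, case, objectiveSet(withZero), iterations = 40)
    expect_equal(p1@spot_weights, p2@spot_weights, tolerance = 1e-12)
})

test_that("an OAR mean-dose objective never worsens that OAR", {
    case <- miniCase()
    infl <- makeInfl()
    tObj <- targetObjectives(case)
    base <- optimizePlan(infl, case, objectiveSet(tObj), iterations = 50)
    m0 <- meanDose(base@dose, caseOAR(case, "oral_cavity"))
    spar <- rbind(tObj, objRow("oral_cavity", "mean_dose", 0, 30))
    trad <- optimizePlan(infl, case, objectiveSet(spar), iterations = 50)
    m1 <- meanDose(trad@dose, caseOAR(case, "oral_cavity"))
    expect_lte(m1, m0 + 1e-9)
})

test_that("continue-optimization escalates but is a no-op when aims are met", {
    case <- miniCase()
    infl <- makeInfl()
    # under-iterated plan with heavy OAR pull misses the aims
    obj <- rbind(targetObjectives(case),
                 objRow("oral_cavity", "mean_dose", 0, 500))
    weak <- optimizePlan(infl, case, objectiveSet(obj), iterations = 4)
    cont <- continueOptimization(weak, infl, case)
    expect_gte(cont@metrics$v95_b, weak@metrics$v95_b)
    # factor 1 with forced run equals a plain warm-start re-run
    c1 <- continueOptimization(weak, infl, case, factor = 1,
                               iterations = 10, only_if_needed = FALSE)
    c2 <- optimizePlan(infl, case, objectiveSet(obj), iterations = 10,
                       w0 = weak@spot_weights)
    expect_equal(c1@spot_weights, c2@spot_weights, tolerance = 1e-12)
    # a converged plan is returned unchanged
    good <- optimizePlan(infl, case, targetObjectives(case),
                         iterations = 80)
    if (good@converged)
        expect_identical(continueOptimization(good, infl, case), good)
})

test_that("normalization is exact, idempotent and preserves HI", {
    case <- miniCase()
    infl <- makeInfl()
    plan <- optimizePlan(infl, case, targetObjectives(case),
                         iterations = 40)
    ptvB <- caseTargets(case)$PTV_B
    hi0 <- homogeneityIndex(computeDVH(plan@dose, ptvB))
    norm <- normalizeToMean(plan, ptvB, 70)
    expect_equal(meanDose(norm@dose, ptvB), 70, tolerance = 1e-9)
    norm2 <- normalizeToMean(norm, ptvB, 70)
    expect_equal(norm2@dose@values, norm@dose@values, tolerance = 1e-12)
    hi1 <- homogeneityIndex(computeDVH(norm@dose, ptvB))
    expect_equal(hi1, hi0, tolerance = 0.02)
    # scale arithmetic
    cur <- meanDose(plan@dose, ptvB)
    expect_equal(norm@meta$normalization, 70 / cur, tolerance = 1e-12)
    expect_error(normalizeToMean(plan, ptvB, -1))
})

test_that("manual plans are deterministic and skill scales OAR effort", {
    case <- miniCase()
    infl <- makeInfl()
    p1 <- makeManualPlan(case, infl, seed = 3)
    p2 <- makeManualPlan(case, infl, seed = 3)
    expect_identical(p1@spot_weights, p2@spot_weights)
    expect_identical(p1@meta$skill, p2@meta$skill)
    # zero skill disables OAR objectives entirely
    cfg <- manualConfig()
    cfg$skill_range <- c(0, 0)
    p0 <- makeManualPlan(case, infl, config = cfg, seed = 3)
    oarRows <- p0@meta$objectives$kind == "mean_dose"
    expect_true(all(p0@meta$objectives$priority[oarRows] == 0))
})
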