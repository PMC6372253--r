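test_that("ray tracing finds the expected target intervals", {
    case <- slabCase()
    mask <- caseTargets(case)$PTV_B@mask
    # convex target: exactly one interval per ray
    iv <- traceRayIntervals(mask, case@grid, 0, c(0, 0, 0))
    expect_identical(nrow(iv), 1L)
    expect_equal(unname(iv[1, "exit_depth"] - iv[1, "entry_depth"]), 10 * 2)
    # ray missing the target entirely
    hs <- horseshoeCase()
    m2 <- caseTargets(hs$case)$PTV_B@mask
    miss <- traceRayIntervals(m2, hs$case@grid, 90, c(0, 0, -24))
    expect_identical(nrow(miss), 0L)
    # horseshoe crossed through the gap: two disjoint intervals
    two <- traceRayIntervals(m2, hs$case@grid, 90, c(0, -4, 0))
    expect_identical(nrow(two), 2L)
    expect_lt(two[1, "exit_depth"], two[2, "entry_depth"])
})

test_that("slab-field GED matches the 1-D scalar reference to 1e-9", {
    case <- slabCase()
    params <- gedParams(tau_in_Gy = 2.7125, tau_out_Gy = 2.7125)
    vol <- fieldLevelGED(case, case@fields[[1]], case@targets[[1]], params)
    # independent scalar route: the slab spans y-voxels 16..25 (2 mm
    # spacing), the beam travels +y, depth = y coordinate
    grid <- case@grid
    ys <- axisCoords(grid, 2)
    entry <- ys[16] - 1; exit <- ys[25] + 1
    expected <- gedProfile1D(ys, cbind(entry, exit), 70, params)
    for (ix in c(1, 6, 11)) for (iz in c(1, 3, 5))
        expect_equal(vol[ix, , iz], expected, tolerance = 1e-9)
    # target voxels receive exactly the prescription before smoothing
    expect_true(all(vol[caseTargets(case)$PTV_B@mask] == 70))
    # distal fall-off: closed form at a chosen distance
    d <- ys[30] - exit
    expect_equal(vol[3, 30, 2], 70 * exp(-d / params@falloff_s_mm),
                 tolerance = 1e-9)
})

test_that("entry dose grows with target length and decays with distance", {
    params <- gedParams()
    rL <- function(L) params@a0 + params@a1 * L / (L + params@L0_mm)
    iv <- function(L) cbind(100, 100 + L)
    # at fixed upstream distance, longer targets give more entry dose
    e1 <- gedProfile1D(50, iv(20), 70, params)
    e2 <- gedProfile1D(50, iv(80), 70, params)
    expect_lt(e1, e2)
    expect_equal(e1, 70 * rL(20) * (1 - 50 / 150), tolerance = 1e-12)
    # decreasing in upstream distance, floored at zero
    dists <- seq(0, 200, by = 10)
    ent <- gedProfile1D(100 - dists, iv(30), 70, params)
    expect_true(all(diff(ent) <= 1e-12))
    expect_equal(gedProfile1D(-100, iv(30), 70, params), 0)
    # distal fall-off strictly decreasing
    dis <- gedProfile1D(130 + dists[-1], iv(30), 70, params)
    expect_true(all(diff(dis) < 0))
})

test_that("sub-target splitting lowers the gap dose and never raises any", {
    hs <- horseshoeCase()
    case <- hs$case
    params <- gedParams(tau_in_Gy = 3.5, tau_out_Gy = 3.5)
    split <- fieldLevelGED(case, case@fields[[1]], case@targets[[1]],
                           params, split_subtargets = TRUE)
    merged <- fieldLevelGED(case, case@fields[[1]], case@targets[[1]],
                            params, split_subtargets = FALSE)
    expect_true(all(split <= merged + 1e-12))
    expect_true(all(split[hs$gap] < 70))
    expect_true(all(split[hs$gap] < merged[hs$gap] - 1e-9))
    # target voxels unaffected by the mode
    tm <- caseTargets(case)$PTV_B@mask
    expect_true(all(split[tm] == 70) && all(merged[tm] == 70))
})

test_that("field/level combination and smoothing behave as specified", {
    case <- miniCase(two_oars = FALSE)
    params <- resolveGEDParams(gedParams(), case)
    pfl <- lapply(case@fields, function(f)
        lapply(case@targets, function(tl)
            fieldLevelGED(case, f, tl, params)))
    # identity when dilation and sigma are zero
    p0 <- resolveGEDParams(gedParams(dilation_mm = 0, sigma_mm = 0), case)
    res0 <- combineAndSmooth(pfl, p0, case@grid)
    expect_identical(res0@total_smoothed, res0@total_raw)
    # two identical fields average to the single-field result
    pf2 <- list(pfl[[1]], pfl[[1]])
    res2 <- combineAndSmooth(pf2, p0, case@grid)
    res1 <- combineAndSmooth(list(pfl[[1]]), p0, case@grid)
    expect_equal(res2@total_raw, res1@total_raw, tolerance = 1e-12)
    # raw GED is bounded by the boost prescription and exact on each level
    res <- combineAndSmooth(pfl, params, case@grid)
    expect_lte(max(res@total_raw), 70 + 1e-9)
    expect_true(all(res@total_raw[caseTargets(case)$PTV_B@mask] == 70))
    # smoothing preserves the global max within 5% and stays non-negative
    expect_gte(max(res@total_smoothed), 0.95 * max(res@total_raw))
    expect_true(all(res@total_smoothed >= 0))
})

test_that("a point source blurs to the sampled Gaussian kernel", {
    grid <- voxelGrid(c(15, 15, 15), 4)
    raw <- array(0, grid@dims)
    raw[8, 8, 8] <- 100
    sm <- gaussianBlur3D(raw, 4, grid@spacing)
    # direct convolution oracle at interior voxels
    k <- dnorm(-3:3, sd = 1); k <- k / sum(k)
    for (off in list(c(0, 0, 0), c(1, 0, 0), c(2, -1, 0), c(1, 1, 3))) {
        expected <- 100 * prod(k[abs(off) + 4])
        got <- sm[8 + off[1], 8 + off[2], 8 + off[3]]
        expect_equal(got, expected, tolerance = 1e-12)
    }
})

test_that("OAR partitions are disjoint, covering, and edge cases resolve", {
    case <- miniCase()
    ged <- computeGED(case)
    for (nm in c("parotid_left", "oral_cavity")) {
        part <- partitionOAR(case@oars[[nm]], ged, case)
        tot <- part@overlap + part@in_field + part@out_of_field
        expect_true(all(tot[case@oars[[nm]]@mask] == 1L))
        expect_true(all(tot[!case@oars[[nm]]@mask] == 0L))
        expect_equal(sum(part@fractions), 1, tolerance = 1e-9)
    }
    # OAR fully inside a target: pure overlap
    inside <- rtStructure("inside", caseTargets(case)$PTV_B@mask)
    pi1 <- partitionOAR(inside, ged, case)
    expect_equal(unname(pi1@fractions["overlap"]), 1)
    # OAR in a zero-GED corner: pure out-of-field
    far <- array(FALSE, case@grid@dims)
    far[1:2, 1:2, 1:2] <- TRUE
    pf <- partitionOAR(rtStructure("far", far), ged, case)
    expect_equal(unname(pf@fractions["out_of_field"]), 1)
    expect_error(partitionOAR(rtStructure("e", far & FALSE), ged, case),
                 "empty")
})
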