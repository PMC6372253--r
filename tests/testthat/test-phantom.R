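test_that("case generation is deterministic and seeds differ", {
    spec <- cohortSpec(2, seed = 11)
    a <- generateCase(spec, 0)
    b <- generateCase(spec, 0)
    expect_identical(a$case@targets[[1]]@structure@mask,
                     b$case@targets[[1]]@structure@mask)
    expect_identical(a$params, b$params)
    other <- generateCase(cohortSpec(2, seed = 12), 0)
    expect_false(identical(a$case@targets[[1]]@structure@mask,
                           other$case@targets[[1]]@structure@mask))
    expect_error(cohortSpec(0), "n_cases")
})

test_that("the transition shell is exactly the 5-mm dilation of the boost", {
    case <- generateCase(cohortSpec(1, seed = 5), 0)$case
    tg <- caseTargets(case)
    grid <- case@grid
    body <- caseBodyMask(case)
    # brute-force distance oracle on the boost bounding region
    bIdx <- which(tg$PTV_B@mask, arr.ind = TRUE) - 1L
    bW <- indexToWorld(grid, bIdx)
    near <- binaryDilate3D(tg$PTV_B@mask, 10, grid@spacing)
    cand <- which(near & !tg$PTV_B@mask, arr.ind = TRUE) - 1L
    cW <- indexToWorld(grid, cand)
    d2 <- outer(rowSums(cW^2), rep(1, nrow(bW))) +
          outer(rep(1, nrow(cW)), rowSums(bW^2)) - 2 * cW %*% t(bW)
    minD <- sqrt(pmax(0, apply(d2, 1, min)))
    inShell <- minD <= 5 + 1e-9 & body[near & !tg$PTV_B@mask]
    got <- tg$PTV_O@mask[near & !tg$PTV_B@mask]
    expect_identical(unname(got), unname(inShell))
    # shell voxels live nowhere else
    expect_identical(sum(tg$PTV_O@mask), sum(got))
    # target levels pairwise disjoint
    expect_lte(max(tg$PTV_B@mask + tg$PTV_O@mask + tg$PTV_E@mask), 1L)
})

test_that("cohort sampling respects the volume menu and pairs laterality", {
    spec <- cohortSpec(50, seed = 2)
    cohort <- generateCohort(spec)
    man <- cohort$manifest
    expect_identical(nrow(man), 50L)
    menu <- defaultOARMenu()
    for (i in seq_len(nrow(menu))) {
        nm <- menu$name[i]
        cols <- if (menu$paired[i])
            paste0(nm, c("_left", "_right"), "_cm3") else paste0(nm, "_cm3")
        for (cl in cols) {
            v <- man[[cl]]
            expect_true(all(v >= menu$min[i] & v <= menu$max[i]),
                label = sprintf("%s sampled volumes in range", cl))
            expect_true(mean(v) >= menu$min[i] && mean(v) <= menu$max[i])
        }
    }
    # realized mask volumes track the sampled ones for a mid-size OAR
    case <- cohort$cases[[3]]
    real <- volumeCm3(caseOAR(case, "parotid_left"), case@grid)
    expect_equal(real, man$parotid_left_cm3[3], tolerance = 0.25 * real)
    # exactly one ipsilateral member per pair
    for (case in cohort$cases[1:5]) {
        for (nm in c("parotid", "submandibular")) {
            lat <- c(caseOAR(case, paste0(nm, "_left"))@laterality,
                     caseOAR(case, paste0(nm, "_right"))@laterality)
            expect_identical(sort(lat), c("contralateral", "ipsilateral"))
        }
    }
    # gantry angles inside the standard ranges
    expect_true(all(man$gantry_1 >= 35 & man$gantry_1 <= 55))
    expect_true(all(man$gantry_2 == 180))
    expect_true(all(man$gantry_3 >= 305 & man$gantry_3 <= 330))
})

test_that("u-shape cases carve an anterior gap through the elective volume", {
    spec <- cohortSpec(1, seed = 3, u_shape = TRUE)
    case <- generateCase(spec, 0)$case
    tu <- targetUnion(case)
    co <- which(tu, arr.ind = TRUE) - 1L
    w <- indexToWorld(case@grid, co)
    gap <- abs(w[, 1]) < 9 & w[, 2] < 8
    expect_identical(sum(gap), 0L)
})
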