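test_that("uniform dose gives a step DVH with all Dv equal", {
    grid <- voxelGrid(c(6, 6, 3), 4)
    dvh <- computeDVH(uniformDose(grid, 54.25), array(TRUE, grid@dims))
    expect_equal(dvh@volume_fraction[1], 1)
    expect_equal(doseAtVolume(dvh, 2), 54.25, tolerance = 0.05)
    expect_equal(doseAtVolume(dvh, 50), 54.25, tolerance = 0.05)
    expect_equal(doseAtVolume(dvh, 98), 54.25, tolerance = 0.05)
    expect_equal(volumeAtDose(dvh, 54.2), 100)
    expect_equal(volumeAtDose(dvh, 54.3), 0)
    expect_equal(volumeAtDose(dvh, 0), 100)
})

test_that("linear dose ramp reproduces analytic quantiles", {
    n <- 70000
    grid <- voxelGrid(c(100, 100, 7), 2)
    vals <- array(seq(0, 70, length.out = n), grid@dims)
    dvh <- computeDVH(new("DoseGrid", values = vals, grid = grid),
                      array(TRUE, grid@dims))
    expect_equal(volumeAtDose(dvh, 35), 50, tolerance = 0.2)
    expect_equal(doseAtVolume(dvh, 50), 35, tolerance = 0.1)
    expect_equal(doseAtVolume(dvh, 98), 0.02 * 70, tolerance = 0.1)
})

test_that("binned DVH metrics agree with a sort-based oracle", {
    set.seed(42)
    for (rep in 1:25) {
        grid <- voxelGrid(c(12, 10, 6), 4)
        mask <- array(runif(prod(grid@dims)) < 0.4, grid@dims)
        if (!any(mask)) next
        vals <- array(70 * rbeta(prod(grid@dims), 2, 1.5), grid@dims)
        dose <- new("DoseGrid", values = vals, grid = grid)
        dvh <- computeDVH(dose, mask)
        dv <- sort(vals[mask], decreasing = TRUE)
        oracle_dav <- function(v) dv[max(1L, ceiling(v / 100 * length(dv)))]
        oracle_vad <- function(d) 100 * mean(dv >= d)
        for (v in c(2, 50, 98))
            expect_equal(doseAtVolume(dvh, v), oracle_dav(v),
                         tolerance = 0.1)
        for (d in c(10, 35, 0.95 * 70))
            expect_equal(volumeAtDose(dvh, d), oracle_vad(d),
                         tolerance = 100 / sum(mask) + 0.1)
        # mean dose from the voxels equals the DVH integral within a bin
        expect_equal(meanDose(dose, mask),
            sum(dvh@volume_fraction) * 0.05 - 0.05 / 2, tolerance = 0.06)
    }
})

test_that("dose/volume lookups are mutual inverses and ordered", {
    set.seed(7)
    grid <- voxelGrid(c(10, 10, 5), 4)
    vals <- array(runif(prod(grid@dims), 0, 70), grid@dims)
    dvh <- computeDVH(new("DoseGrid", values = vals, grid = grid),
                      array(TRUE, grid@dims))
    for (v in c(5, 20, 50, 80, 95)) {
        d <- doseAtVolume(dvh, v)
        expect_equal(volumeAtDose(dvh, d), v, tolerance = 0.5)
    }
    d2 <- doseAtVolume(dvh, 2); d50 <- doseAtVolume(dvh, 50)
    d98 <- doseAtVolume(dvh, 98)
    expect_true(d98 <= d50 && d50 <= d2)
    expect_error(doseAtVolume(dvh, 0), "v_percent")
    expect_error(doseAtVolume(dvh, 101), "v_percent")
})

test_that("mean and max point dose handle hot spots", {
    grid <- voxelGrid(c(5, 5, 2), 4)
    vals <- array(0, grid@dims)
    vals[3, 3, 1] <- 80
    dose <- new("DoseGrid", values = vals, grid = grid)
    mask <- array(TRUE, grid@dims)
    expect_equal(maxPointDose(dose, mask), 80)
    expect_equal(meanDose(dose, mask), 80 / prod(grid@dims))
    expect_error(meanDose(dose, array(FALSE, grid@dims)), "empty")
})
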