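test_that("curve PCA is orthonormal, exact for low rank, degenerate-safe", {
    set.seed(9)
    p <- 60
    base <- matrix(rnorm(2 * p), 2, p)
    scores <- matrix(rnorm(40), 20, 2)
    curves <- sweep(scores %*% base, 2, seq_len(p) / p, `+`)
    pca <- fitPCA(curves, n_components = 2)
    expect_equal(crossprod(pca$rotation), diag(2), tolerance = 1e-9,
                 ignore_attr = TRUE)
    recon <- sweep(pca$scores %*% t(pca$rotation), 2, pca$mean, `+`)
    expect_lt(max(abs(recon - curves)), 1e-9)
    expect_equal(pca$var_explained, 1, tolerance = 1e-12)
    # identical curves: all scores zero
    same <- matrix(rep(curves[1, ], 5), 5, byrow = TRUE)
    expect_equal(max(abs(fitPCA(same)$scores)), 0, tolerance = 1e-9)
    expect_error(fitPCA(curves, n_components = 25), "n_curves")
})

test_that("a perfectly linear library trains to R-squared one", {
    lib <- synthLibrary(30, beta = 2, noise_sd = 0)
    model <- trainSynth(lib)
    om <- model@models$oar
    expect_equal(om@r_squared, 1, tolerance = 1e-6)
    expect_lt(max(om@residual_sd), 1e-6)
    expect_identical(om@n_train, 30L)
})

test_that("shuffled dosimetry gives a near-zero R-squared", {
    lib <- synthLibrary(50, beta = 2, noise_sd = 0.2, seed = 4,
                        shuffle = TRUE)
    model <- trainSynth(lib)
    expect_lt(model@models$oar@r_squared, 0.15)
})

test_that("training skips OARs matched below the minimum", {
    lib <- synthLibrary(8)
    expect_warning(m <- trainModel(NULL, NULL,
        config = kbpConfig(min_train = 20), features = lib$features),
        "skipped")
    expect_length(m@models, 0L)
})

test_that("outlier curation flags spiked points and only those", {
    lib <- synthLibrary(40, beta = 2, noise_sd = 0.3, seed = 6)
    clean <- trainSynth(lib)
    expect_identical(nrow(curateOutliers(clean)), 0L)
    # corrupt one library DVH: doubled dose curve
    bad <- lib
    bad$features$case07$oar$dose_curve <-
        2 * bad$features$case07$oar$dose_curve
    spiked <- trainSynth(bad)
    flags <- curateOutliers(spiked)
    expect_true("case07" %in% flags$case_id[flags$reason == "residual"])
    # infinite thresholds flag nothing
    expect_identical(nrow(curateOutliers(spiked, resid_threshold = Inf,
                                         lev_factor = Inf)), 0L)
})

# Hand-built single-OAR model against which prediction mechanics are exact.
handModel <- function(case, residual_sd = 0, vol_range = c(0.1, 1000)) {
    p <- 100L
    unitg <- rep(1 / sqrt(p), p)
    om <- new("OARModel", oar_name = "parotid_left",
        dose_pca = list(mean = seq(0.5, 0.1, length.out = p),
                        rotation = matrix(unitg, ncol = 1), sdev = 1),
        geo_pca = list(mean = seq(0.6, 0.2, length.out = p),
                       rotation = matrix(unitg, ncol = 1), sdev = 1),
        coef = matrix(0, 6, 1,
            dimnames = list(c("Intercept", "geo_pc1",
                c("oar_volume_cm3", "overlap_fraction",
                "target_volume_cm3", "out_of_field_fraction")), NULL)),
        residual_sd = residual_sd, r_squared = 0.9, n_train = 10L,
        training_ranges = data.frame(
            feature = c("oar_volume_cm3", "overlap_fraction",
                "target_volume_cm3", "out_of_field_fraction"),
            min = c(vol_range[1], 0, 0, 0),
            max = c(vol_range[2], 1, 1e4, 1)),
        low_mod_bands = list(overlap = list(),
            out_of_field = list(mean = rep(0.02, p), sd = rep(0, p))),
        extras = list(center = rep(0, 5), scale = rep(1, 5),
                      ref_dose_Gy = 70))
    new("KBModel", models = list(parotid_left = om),
        ged_params = resolveGEDParams(gedParams(), case),
        config = kbpConfig(), provenance = list())
}

test_that("zero-residual models predict collapsed, valid DVH bands", {
    case <- miniCase()
    model <- handModel(case)
    bands <- suppressWarnings(predictBands(model, case))
    b <- bands$parotid_left
    expect_s4_class(b, "PredictionBand")
    expect_equal(b@lower@volume_fraction, b@upper@volume_fraction,
                 tolerance = 1e-12)
    expect_equal(b@lower@volume_fraction, b@median@volume_fraction,
                 tolerance = 1e-12)
    # valid cumulative DVH after region mixing
    expect_true(all(diff(b@median@volume_fraction) <= 1e-12))
    expect_true(all(b@median@volume_fraction >= 0 &
                    b@median@volume_fraction <= 1))
    expect_length(b@outlier_flags, 0L)
    # positive residual SD widens the band around the same median
    wide <- suppressWarnings(predictBands(handModel(case, residual_sd = 0.1),
                                          case))$parotid_left
    expect_true(all(wide@lower@volume_fraction <=
                    wide@upper@volume_fraction + 1e-12))
    expect_gt(doseAtVolume(wide@upper, 50) - doseAtVolume(wide@lower, 50),
              0)
})

test_that("scalar features outside the training ranges raise outlier flags", {
    case <- miniCase()
    model <- handModel(case, vol_range = c(0.1, 0.5))  # volumes above range
    bands <- suppressWarnings(predictBands(model, case))
    expect_true("oar_volume-out-of-range" %in%
                bands$parotid_left@outlier_flags)
})

test_that("model archives round-trip through save/load", {
    case <- miniCase()
    model <- handModel(case, residual_sd = 0.05)
    path <- withr::local_tempdir()
    saveModel(model, path)
    back <- loadModel(path)
    expect_identical(names(back@models), names(model@models))
    b1 <- suppressWarnings(predictBands(model, case))$parotid_left
    b2 <- suppressWarnings(predictBands(back, case))$parotid_left
    expect_equal(b1@median@volume_fraction, b2@median@volume_fraction,
                 tolerance = 1e-9)
    expect_equal(b1@mean_dose_Gy, b2@mean_dose_Gy, tolerance = 1e-9)
    om <- back@models$parotid_left
    expect_equal(om@coef, model@models$parotid_left@coef,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(om@r_squared, 0.9)
})
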