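evalFixture <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        case <- miniCase()
        infl <- caseInfluence(case)
        plan <- optimizePlan(infl, case, targetObjectives(case),
                             iterations = 40)
        cache <<- list(case = case, plan = plan)
        cache
    }
})

test_that("comparing a plan with itself is identically zero", {
    fx <- evalFixture()
    cases <- list(mini = fx$case)
    cmp <- comparePlans(list(mini = fx$plan), list(mini = fx$plan), cases)
    expect_equal(max(abs(unlist(cmp$per_case[, -1]))), 0, tolerance = 1e-9)
    expect_equal(max(abs(cmp$per_oar$delta_mean_Gy)), 0, tolerance = 1e-9)
    # bookkeeping: one row per case and modelled OAR; the mini fixture has
    # no serial structures
    expect_identical(nrow(cmp$per_oar), 2L)
    expect_null(cmp$serial_max)
})

test_that("pre-normalization scaling of the KBP does not change deltas", {
    fx <- evalFixture()
    cases <- list(mini = fx$case)
    scaled <- fx$plan
    scaled@spot_weights <- scaled@spot_weights * 1.01
    scaled@dose@values <- scaled@dose@values * 1.01
    cmp0 <- comparePlans(list(mini = fx$plan), list(mini = fx$plan), cases)
    cmp1 <- comparePlans(list(mini = fx$plan), list(mini = scaled), cases)
    expect_equal(cmp1$per_oar$delta_mean_Gy, cmp0$per_oar$delta_mean_Gy,
                 tolerance = 1e-9)
    expect_equal(unlist(cmp1$per_case[, -1]), unlist(cmp0$per_case[, -1]),
                 tolerance = 1e-6)
    expect_error(comparePlans(list(), list(mini = fx$plan), cases),
                 "counterpart")
})

test_that("accuracy counts respect thresholds and are monotone", {
    fx <- evalFixture()
    cases <- list(mini = fx$case)
    mkBand <- function(oar, mean_Gy) {
        edges <- seq(0, 70, by = 0.5)
        vf <- pmax(0, 1 - edges / 70)
        cv <- new("DVHCurve", dose_Gy = edges, volume_fraction = vf)
        new("PredictionBand", oar_name = oar, lower = cv, median = cv,
            upper = cv, mean_dose_Gy = mean_Gy, outlier_flags = character(0))
    }
    achieved <- vapply(c("parotid_left", "oral_cavity"), function(nm)
        meanDose(fx$plan@dose, caseOAR(fx$case, nm)), 0)
    exact <- list(mini = list(
        parotid_left = mkBand("parotid_left", achieved[["parotid_left"]]),
        oral_cavity = mkBand("oral_cavity", achieved[["oral_cavity"]])))
    acc <- predictedVsAchieved(exact, list(mini = fx$plan), cases)
    expect_equal(max(abs(acc$table$delta_Gy)), 0, tolerance = 1e-9)
    expect_identical(acc$summary$n_within, acc$summary$n_oars)
    # threshold zero counts only exact matches
    off <- exact
    off$mini$parotid_left@mean_dose_Gy <-
        off$mini$parotid_left@mean_dose_Gy + 1
    a0 <- predictedVsAchieved(off, list(mini = fx$plan), cases,
                              threshold_Gy = 1e-12)
    expect_identical(a0$summary$n_within, 1L)
    # monotone in the threshold
    counts <- vapply(c(0.5, 1.5, 5), function(th)
        predictedVsAchieved(off, list(mini = fx$plan), cases,
                            threshold_Gy = th)$summary$n_within, 0L)
    expect_true(all(diff(counts) >= 0))
    expect_error(predictedVsAchieved(off, list(other = fx$plan), cases),
                 "mismatch")
})

test_that("model diagnostics expose the fitted line and serialize", {
    lib <- list()
    set.seed(2)
    for (i in 1:20) {
        a <- rnorm(1)
        p <- 50
        lib[[sprintf("c%02d", i)]] <- list(oar = list(
            geo_curve = seq(1, 0, length.out = p) + a * sin(seq_len(p) / 8) / 5,
            dose_curve = seq(0.9, 0, length.out = p) +
                (3 * a) * sin(seq_len(p) / 8) / 5,
            overlap_curves = list(), overlap_by_level = c(PTV_B = 0),
            oof_curve = NULL,
            scalars = c(oar_volume_cm3 = runif(1, 25, 35),
                        overlap_fraction = runif(1, 0, 0.1),
                        target_volume_cm3 = runif(1, 140, 160),
                        out_of_field_fraction = runif(1, 0, 0.2)),
            fractions = c(overlap = 0, in_field = 1, out_of_field = 0),
            ref_dose_Gy = 70, low_mod_only = FALSE))
    }
    model <- trainModel(NULL, NULL, config = kbpConfig(min_train = 10),
                        features = lib)
    dg <- modelDiagnostics(model)
    expect_identical(nrow(dg$r2_table), 1L)
    expect_gt(dg$r2_table$r_squared, 0.99)
    # perfect linear relation: points on the fitted line
    expect_lt(max(abs(dg$scatter$residual)), 1e-6)
    # serialization round-trip
    f <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(dg, f, digits = NA, dataframe = "columns")
    back <- jsonlite::read_json(f, simplifyVector = TRUE)
    expect_equal(back$r2_table$r_squared, dg$r2_table$r_squared,
                 tolerance = 1e-12)
    expect_equal(back$scatter$dose_score1, dg$scatter$dose_score1,
                 tolerance = 1e-12)
})
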