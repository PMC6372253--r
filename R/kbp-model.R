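# Knowledge-based model: extraction (parameterize geometry and dosimetry of
# each library plan), training (per-OAR principal-component regression from
# geometric features to achieved-DVH components), diagnostics and
# prediction of DVH bands for new cases.

#' Model configuration
#'
#' @param n_volume_points fixed volume-fraction grid length for DVH
#'   sampling (dose-at-volume at the bin midpoints).
#' @param var_explained keep the smallest number of principal components
#'   explaining at least this variance fraction...
#' @param pc_cap ...capped at this many components.
#' @param min_train minimum matched cases for an OAR model.
#' @param band_sd half-width of the prediction band in residual SDs.
#' @param bin_width_Gy dose resolution of exported DVH curves.
#' @export
kbpConfig <- function(n_volume_points = 100L, var_explained = 0.95,
                      pc_cap = 5L, min_train = 20L, band_sd = 1,
                      bin_width_Gy = 0.05) {
    list(n_volume_points = as.integer(n_volume_points),
         var_explained = var_explained, pc_cap = as.integer(pc_cap),
         min_train = as.integer(min_train), band_sd = band_sd,
         bin_width_Gy = bin_width_Gy)
}

# Midpoint volume-percent grid used for all sampled DVH curves.
volumeGrid <- function(n) (seq_len(n) - 0.5) / n * 100

# Dose-at-volume samples of the voxel doses in a region (no binning: exact
# empirical quantiles, normalized by the reference dose).
sampleRegionCurve <- function(doses, n, ref) {
    q <- stats::quantile(doses, probs = 1 - volumeGrid(n) / 100,
                         names = FALSE, type = 4)
    q / ref
}

#' Extract geometric and dosimetric features of one case/plan pair
#'
#' For every modelled OAR: the in-field GED DVH and achieved in-field dose
#' DVH sampled as dose-at-volume on a fixed grid (normalized to the highest
#' prescription), the scalar features (OAR volume, target-overlap fraction,
#' union target volume, out-of-field fraction), and the low-modulation
#' region curves (target-overlap and out-of-field dose DVHs).
#'
#' @param case a [PlanCase-class].
#' @param plan_dose a [DoseGrid-class] (achieved dose) or `NULL` when only
#'   geometry is needed (prediction time).
#' @param ged a [GEDResult-class] for the case.
#' @param config a [kbpConfig()] list.
#' @return named list per OAR with elements `geo_curve`, `dose_curve`,
#'   `overlap_curves` (one per target level), `oof_curve` (each `NULL` when
#'   its region is empty), `scalars`, `fractions`, `overlap_by_level` and
#'   `ref_dose_Gy`. Overlap curves are kept per target level because under
#'   a simultaneous-integrated-boost prescription the overlap dose tracks
#'   the overlapped level's prescription.
#' @export
extractFeatures <- function(case, plan_dose, ged, config = kbpConfig()) {
    n <- config$n_volume_points
    ref <- max(casePrescriptions(case))
    tvol <- volumeCm3(targetUnion(case), case@grid)
    doseArr <- if (is.null(plan_dose)) NULL else plan_dose@values
    out <- list()
    for (nm in modelOARNames(case)) {
        oar <- case@oars[[nm]]
        part <- partitionOAR(oar, ged, case)
        fr <- part@fractions
        gedArr <- ged@total_smoothed
        nvox <- sum(oar@mask)
        ovCurves <- list(); ovFrac <- numeric(0)
        for (tl in case@targets) {
            tn <- tl@structure@name
            m <- part@overlap & tl@structure@mask
            ovFrac[tn] <- sum(m) / nvox
            ovCurves[[tn]] <- if (!is.null(doseArr) && any(m))
                sampleRegionCurve(doseArr[m], n, ref) else NULL
        }
        feat <- list(
            geo_curve = if (any(part@in_field))
                sampleRegionCurve(gedArr[part@in_field], n, ref) else NULL,
            dose_curve = if (!is.null(doseArr) && any(part@in_field))
                sampleRegionCurve(doseArr[part@in_field], n, ref) else NULL,
            overlap_curves = ovCurves,
            overlap_by_level = ovFrac,
            oof_curve = if (!is.null(doseArr) && any(part@out_of_field))
                sampleRegionCurve(doseArr[part@out_of_field], n, ref) else NULL,
            scalars = c(oar_volume_cm3 = volumeCm3(oar, case@grid),
                        overlap_fraction = unname(fr["overlap"]),
                        target_volume_cm3 = tvol,
                        out_of_field_fraction = unname(fr["out_of_field"])),
            fractions = fr,
            ref_dose_Gy = ref,
            low_mod_only = !any(part@in_field))
        out[[nm]] <- feat
    }
    out
}

#' Principal-component parameterization of a curve family
#'
#' Thin wrapper around [stats::prcomp()]: centers the sampled curves,
#' returns the mean curve, orthonormal component curves, their standard
#' deviations and the per-curve scores. The number of components is either
#' given or chosen as the smallest number explaining at least
#' `var_explained` of the variance, capped at `pc_cap`.
#'
#' @param curves numeric matrix, one row per sampled curve (>= 2 rows).
#' @param n_components fixed component count, or `NULL` to choose by
#'   explained variance.
#' @param var_explained,pc_cap see [kbpConfig()].
#' @return list with `mean`, `rotation` (p x k, orthonormal columns),
#'   `sdev` (k), `scores` (n x k), `var_explained`.
#' @export
fitPCA <- function(curves, n_components = NULL, var_explained = 0.95,
                   pc_cap = 5L) {
    curves <- as.matrix(curves)
    n <- nrow(curves)
    if (n < 2L) stop("need at least 2 curves")
    if (!is.null(n_components) && n_components > n - 1L)
        stop("n_components must be at most n_curves - 1")
    pc <- stats::prcomp(curves, center = TRUE, scale. = FALSE)
    tot <- sum(pc$sdev^2)
    if (tot < 1e-20) {
        k <- 1L
        rot <- matrix(0, ncol(curves), 1)
        rot[1, 1] <- 1
        return(list(mean = colMeans(curves), rotation = rot, sdev = 0,
                    scores = matrix(0, n, 1), var_explained = 1))
    }
    cum <- cumsum(pc$sdev^2) / tot
    k <- if (is.null(n_components))
        min(which(cum >= var_explained - 1e-12)[1], pc_cap, n - 1L)
    else as.integer(n_components)
    k <- max(1L, k)
    list(mean = colMeans(curves),
         rotation = pc$rotation[, seq_len(k), drop = FALSE],
         sdev = pc$sdev[seq_len(k)],
         scores = pc$x[, seq_len(k), drop = FALSE],
         var_explained = cum[k])
}

# Mean/SD band of a curve family (low-modulation regions).
curveBand <- function(curves) {
    if (is.null(curves) || nrow(curves) == 0L) return(NULL)
    s <- if (nrow(curves) > 1L) apply(curves, 2, stats::sd) else
        rep(0, ncol(curves))
    list(mean = colMeans(curves), sd = s, n = nrow(curves))
}

scalarFeatureNames <- c("oar_volume_cm3", "overlap_fraction",
                        "target_volume_cm3", "out_of_field_fraction")

#' Train a knowledge-based model from a plan library
#'
#' For every OAR matched in at least `min_train` library cases: fits a PCA
#' of the in-field GED DVHs and of the achieved in-field DVHs, then an
#' ordinary-least-squares regression (on standardized features; ridge
#' fallback when the design is ill-conditioned) from the geometric features
#' (GED-DVH PC scores plus scalar geometry) to the achieved-DVH PC scores.
#' Stores per-PC residual SDs, the R-squared of the dose-PC1 regression,
#' the scalar-feature training ranges (geometric-outlier detection), and
#' the mean +/- SD low-modulation bands.
#'
#' @param cases named list of [PlanCase-class] (the library).
#' @param plans named list of [PlanResult-class] aligned with `cases`.
#' @param ged_params a [GEDParams-class] snapshot.
#' @param config a [kbpConfig()] list.
#' @param features optional precomputed list of [extractFeatures()] results
#'   per case (avoids recomputing GED).
#' @param provenance optional list stored in the model (seed, manifest
#'   hash).
#' @return A [KBModel-class]; OARs with fewer matches are skipped with a
#'   warning.
#' @export
trainModel <- function(cases, plans, ged_params = gedParams(),
                       config = kbpConfig(), features = NULL,
                       provenance = list()) {
    if (is.null(features)) {
        features <- lapply(names(cases), function(id) {
            ged <- computeGED(cases[[id]], ged_params)
            extractFeatures(cases[[id]], plans[[id]]@dose, ged, config)
        })
        names(features) <- names(cases)
    }
    oarNames <- unique(unlist(lapply(features, names)))
    models <- list()
    for (nm in oarNames) {
        have <- Filter(function(id) {
            f <- features[[id]][[nm]]
            !is.null(f) && !is.null(f$dose_curve) && !is.null(f$geo_curve)
        }, names(features))
        if (length(have) < config$min_train) {
            warning(sprintf("OAR '%s' matched in only %d cases (min %d): skipped",
                nm, length(have), config$min_train))
            next
        }
        doseC <- do.call(rbind, lapply(have, function(id)
            features[[id]][[nm]]$dose_curve))
        geoC <- do.call(rbind, lapply(have, function(id)
            features[[id]][[nm]]$geo_curve))
        scal <- do.call(rbind, lapply(have, function(id)
            features[[id]][[nm]]$scalars))
        dosePCA <- fitPCA(doseC, var_explained = config$var_explained,
                          pc_cap = config$pc_cap)
        geoPCA <- fitPCA(geoC, var_explained = config$var_explained,
                         pc_cap = config$pc_cap)
        X <- cbind(geoPCA$scores, scal)
        colnames(X) <- c(paste0("geo_pc", seq_len(ncol(geoPCA$scores))),
                         scalarFeatureNames)
        ctr <- colMeans(X)
        scl <- apply(X, 2, stats::sd)
        scl[scl < 1e-12] <- 1
        Xs <- scale(X, center = ctr, scale = scl)
        Y <- dosePCA$scores
        D <- cbind(Intercept = 1, Xs)
        # least squares with a small ridge on the (standardized) slopes,
        # selected per OAR by analytic leave-one-out error of the dose-PC1
        # regression; guards against variance/extrapolation at library size
        # and covers ill-conditioned designs
        XtX0 <- crossprod(D)
        XtY <- crossprod(D, Y)
        lambdas <- c(0, 0.01, 0.03, 0.1, 0.3, 1) * nrow(D)
        looBest <- Inf; coef <- NULL; lamBest <- 0
        for (lam in lambdas) {
            XtX <- XtX0 + diag(c(0, rep(lam, ncol(Xs))))
            if (lam == 0 && kappa(XtX) > 1e8) next
            cf <- solve(XtX, XtY)
            H <- D %*% solve(XtX, t(D))
            h <- pmin(diag(H), 1 - 1e-6)
            r1 <- Y[, 1] - as.numeric(D %*% cf[, 1])
            loo <- mean((r1 / (1 - h))^2)
            if (loo < looBest) { looBest <- loo; coef <- cf; lamBest <- lam }
        }
        resid <- Y - D %*% coef
        p <- ncol(Xs)
        dfres <- max(1L, nrow(D) - p - 1L)
        residSD <- sqrt(colSums(resid^2) / dfres)
        ssTot <- sum((Y[, 1] - mean(Y[, 1]))^2)
        r2 <- if (ssTot < 1e-20) NA_real_ else 1 - sum(resid[, 1]^2) / ssTot
        ranges <- data.frame(feature = scalarFeatureNames,
            min = apply(scal, 2, min), max = apply(scal, 2, max))
        levelNames <- unique(unlist(lapply(have, function(id)
            names(features[[id]][[nm]]$overlap_curves))))
        ovlBands <- list()
        for (tn in levelNames) {
            cv <- do.call(rbind, Filter(Negate(is.null),
                lapply(have, function(id)
                    features[[id]][[nm]]$overlap_curves[[tn]])))
            ovlBands[[tn]] <- curveBand(cv)
        }
        oof <- do.call(rbind, Filter(Negate(is.null),
            lapply(have, function(id) features[[id]][[nm]]$oof_curve)))
        models[[nm]] <- new("OARModel", oar_name = nm, dose_pca = dosePCA,
            geo_pca = geoPCA, coef = as.matrix(coef),
            residual_sd = as.numeric(residSD),
            r_squared = max(0, min(1, r2)), n_train = length(have),
            training_ranges = ranges,
            low_mod_bands = list(overlap = ovlBands,
                                 out_of_field = curveBand(oof)),
            extras = list(ids = have, X = X, center = ctr, scale = scl,
                          ridge_lambda = lamBest,
                          dose_scores = Y, geo_scores = geoPCA$scores,
                          ref_dose_Gy = features[[have[1]]][[nm]]$ref_dose_Gy))
    }
    new("KBModel", models = models, ged_params = ged_params,
        config = config, provenance = provenance)
}

#' Flag training points that deviate from the population
#'
#' Computes studentized residuals and leverages of the dose-PC1 regression
#' of every OAR model and flags points with |studentized residual| >
#' `resid_threshold` or leverage > `lev_factor * (p+1)/n`. Flagging is a
#' diagnostic: removal is a user action (retrain on the reduced library),
#' never automatic.
#'
#' @param model a [KBModel-class].
#' @param resid_threshold studentized-residual threshold (default 3).
#' @param lev_factor leverage threshold factor (default 3).
#' @return data frame (oar, case_id, studentized_residual, leverage,
#'   reason), zero rows when nothing is flagged.
#' @export
curateOutliers <- function(model, resid_threshold = 3, lev_factor = 3) {
    rows <- list()
    for (om in model@models) {
        X <- scale(om@extras$X, om@extras$center, om@extras$scale)
        D <- cbind(1, X)
        n <- nrow(D); p <- ncol(D)
        H <- D %*% solve(crossprod(D) +
            diag(1e-10, p), t(D))
        h <- pmin(diag(H), 1 - 1e-9)
        y <- om@extras$dose_scores[, 1]
        res <- y - as.numeric(D %*% om@coef[, 1])
        s <- sqrt(sum(res^2) / max(1, n - p))
        tstud <- res / (s * sqrt(1 - h) + 1e-12)
        bad <- abs(tstud) > resid_threshold | h > lev_factor * p / n
        if (any(bad)) {
            rows[[length(rows) + 1L]] <- data.frame(
                oar = om@oar_name, case_id = om@extras$ids[bad],
                studentized_residual = tstud[bad], leverage = h[bad],
                reason = ifelse(abs(tstud[bad]) > resid_threshold,
                    "residual", "leverage"))
        }
    }
    if (!length(rows))
        return(data.frame(oar = character(0), case_id = character(0),
            studentized_residual = numeric(0), leverage = numeric(0),
            reason = character(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# Weighted empirical survival curve (cumulative DVH) from pooled region
# dose samples.
weightedSurvivalDVH <- function(samples, weights, bin_width_Gy = 0.05) {
    ord <- order(samples)
    s <- samples[ord]; w <- weights[ord]
    cw <- cumsum(w); tot <- cw[length(cw)]
    edges <- seq(0, max(s, 0) + bin_width_Gy, by = bin_width_Gy)
    idx <- findInterval(edges - 1e-12, s)
    frac <- (tot - c(0, cw)[idx + 1L]) / tot
    new("DVHCurve", dose_Gy = edges,
        volume_fraction = pmin(1, pmax(0, frac)))
}

#' Predict DVH bands for a new case
#'
#' Computes the case GED with the model's parameter snapshot, extracts the
#' geometric features, predicts the in-field DVH principal-component scores
#' per OAR and reconstructs the median curve; the band is the
#' reconstruction at +/- `band_sd` residual SDs. In-field, target-overlap
#' and out-of-field region curves are merged volume-weighted into a full
#' OAR DVH (low-modulation regions use their library mean +/- SD bands).
#' Scalar features outside the training ranges raise geometric-outlier
#' flags.
#'
#' @param model a [KBModel-class].
#' @param case a [PlanCase-class]; OAR names are matched to model OARs,
#'   unmatched ones are skipped with a warning.
#' @param ged optional precomputed [GEDResult-class] (must use the model's
#'   parameters).
#' @return named list of [PredictionBand-class].
#' @export
predictBands <- function(model, case, ged = NULL) {
    if (is.null(ged)) ged <- computeGED(case, model@ged_params)
    feats <- extractFeatures(case, NULL, ged, model@config)
    unmatched <- setdiff(names(feats), names(model@models))
    if (length(unmatched))
        warning(sprintf("no model for OAR(s): %s",
            paste(unmatched, collapse = ", ")))
    bands <- list()
    for (nm in intersect(names(feats), names(model@models))) {
        om <- model@models[[nm]]
        f <- feats[[nm]]
        ref <- f$ref_dose_Gy
        flags <- character(0)
        for (i in seq_len(nrow(om@training_ranges))) {
            fe <- om@training_ranges$feature[i]
            v <- f$scalars[[fe]]
            if (v < om@training_ranges$min[i] - 1e-9 ||
                v > om@training_ranges$max[i] + 1e-9)
                flags <- c(flags, paste0(sub("_cm3$|_fraction$", "", fe),
                                         "-out-of-range"))
        }
        n <- model@config$n_volume_points
        bsd <- model@config$band_sd
        regions <- list()  # per region: lower/median/upper sample vectors
        if (!is.null(f$geo_curve) && f$fractions[["in_field"]] > 0) {
            gs <- as.numeric((f$geo_curve - om@geo_pca$mean) %*%
                             om@geo_pca$rotation)
            x <- c(gs, f$scalars[scalarFeatureNames])
            xs <- (x - om@extras$center) / om@extras$scale
            yhat <- as.numeric(c(1, xs) %*% om@coef)
            med <- om@dose_pca$mean +
                as.numeric(om@dose_pca$rotation %*% yhat)
            hw <- as.numeric(abs(om@dose_pca$rotation) %*%
                             (bsd * om@residual_sd))
            regions$in_field <- list(lower = pmax(0, med - hw),
                median = pmax(0, med), upper = pmax(0, med + hw),
                frac = f$fractions[["in_field"]])
        }
        rx <- casePrescriptions(case)
        for (tn in names(f$overlap_by_level)) {
            frc <- f$overlap_by_level[[tn]]
            if (frc <= 0) next
            bd <- om@low_mod_bands$overlap[[tn]]
            if (!is.null(bd)) {
                regions[[paste0("overlap_", tn)]] <- list(
                    lower = pmax(0, bd$mean - bsd * bd$sd),
                    median = pmax(0, bd$mean),
                    upper = pmax(0, bd$mean + bsd * bd$sd), frac = frc)
            } else {
                # level overlap never seen in training: assume the
                # overlapped level prescription
                base <- rep(if (tn %in% names(rx)) rx[[tn]] / ref else 1, n)
                regions[[paste0("overlap_", tn)]] <- list(lower = base,
                    median = base, upper = base, frac = frc)
            }
        }
        frc <- f$fractions[["out_of_field"]]
        bd <- om@low_mod_bands$out_of_field
        if (frc > 0) {
            if (!is.null(bd)) {
                regions$out_of_field <- list(
                    lower = pmax(0, bd$mean - bsd * bd$sd),
                    median = pmax(0, bd$mean),
                    upper = pmax(0, bd$mean + bsd * bd$sd), frac = frc)
            } else {
                regions$out_of_field <- list(lower = rep(0, n),
                    median = rep(0, n), upper = rep(0, n), frac = frc)
            }
        }
        if (!length(regions)) next
        totFrac <- sum(vapply(regions, `[[`, 0, "frac"))
        pool <- function(which) {
            s <- unlist(lapply(regions, function(r) r[[which]] * ref))
            w <- unlist(lapply(regions, function(r)
                rep(r$frac / totFrac / n, n)))
            list(s = s, w = w)
        }
        lo <- pool("lower"); md <- pool("median"); up <- pool("upper")
        bw <- model@config$bin_width_Gy
        maxd <- max(up$s, 0) + bw
        mkCurve <- function(p) {
            cv <- weightedSurvivalDVH(p$s, p$w, bw)
            # extend all three curves onto a common edge grid
            edges <- seq(0, maxd, by = bw)
            vf <- c(cv@volume_fraction,
                    rep(0, length(edges) - length(cv@dose_Gy)))
            new("DVHCurve", dose_Gy = edges, volume_fraction = vf[seq_along(edges)])
        }
        bands[[nm]] <- new("PredictionBand", oar_name = nm,
            lower = mkCurve(lo), median = mkCurve(md), upper = mkCurve(up),
            mean_dose_Gy = sum(md$s * md$w) / sum(md$w),
            outlier_flags = flags)
    }
    bands
}

setMethod("show", "KBModel", function(object) {
    cat(sprintf("KBModel: %d OAR models\n", length(object@models)))
    for (om in object@models)
        cat(sprintf("  %-22s n=%2d  R2=%.2f  PCs(dose/geo)=%d/%d\n",
            om@oar_name, om@n_train, om@r_squared,
            ncol(om@dose_pca$rotation), ncol(om@geo_pca$rotation)))
})

setMethod("show", "PredictionBand", function(object) {
    cat(sprintf("PredictionBand '%s': predicted mean %.2f Gy%s\n",
        object@oar_name, object@mean_dose_Gy,
        if (length(object@outlier_flags))
            paste0(" [", paste(object@outlier_flags, collapse = ", "), "]")
        else ""))
})
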