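# Model archive: a directory with a `model.json` manifest (per-OAR
# training statistics, regression coefficients, scalar ranges, GED
# parameter snapshot) plus one CSV per OAR holding the curve data (PCA mean
# and component curves, low-modulation bands). All files are plain text.

gedParamsToList <- function(p) {
    list(a0 = p@a0, a1 = p@a1, L0_mm = p@L0_mm,
         entry_decay_mm = p@entry_decay_mm, falloff_s_mm = p@falloff_s_mm,
         dilation_mm = p@dilation_mm, sigma_mm = p@sigma_mm,
         tau_in_Gy = p@tau_in_Gy, tau_out_Gy = p@tau_out_Gy)
}

gedParamsFromList <- function(l) {
    gedParams(l$a0, l$a1, l$L0_mm, l$entry_decay_mm, l$falloff_s_mm,
              l$dilation_mm, l$sigma_mm,
              if (is.null(l$tau_in_Gy)) NA_real_ else l$tau_in_Gy,
              if (is.null(l$tau_out_Gy)) NA_real_ else l$tau_out_Gy)
}

#' Save a knowledge-based model archive
#'
#' @param model a [KBModel-class].
#' @param path directory to create.
#' @return `path`, invisibly.
#' @seealso [loadModel()]
#' @export
saveModel <- function(model, path) {
    if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
        stop(sprintf("cannot create model directory '%s'", path))
    manifest <- list(schema = "protonKBP-model/1",
        ged_params = gedParamsToList(model@ged_params),
        config = model@config, provenance = model@provenance,
        oars = lapply(model@models, function(om) list(
            oar_name = om@oar_name, n_train = om@n_train,
            r_squared = om@r_squared, residual_sd = om@residual_sd,
            coef = as.data.frame(om@coef),
            coef_rownames = rownames(om@coef),
            feature_center = om@extras$center,
            feature_scale = om@extras$scale,
            ref_dose_Gy = om@extras$ref_dose_Gy,
            dose_sdev = om@dose_pca$sdev, geo_sdev = om@geo_pca$sdev,
            training_ranges = om@training_ranges)))
    jsonlite::write_json(manifest, file.path(path, "model.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (om in model@models) {
        df <- data.frame(dose_mean = om@dose_pca$mean,
                         geo_mean = om@geo_pca$mean)
        for (k in seq_len(ncol(om@dose_pca$rotation)))
            df[[paste0("dose_pc", k)]] <- om@dose_pca$rotation[, k]
        for (k in seq_len(ncol(om@geo_pca$rotation)))
            df[[paste0("geo_pc", k)]] <- om@geo_pca$rotation[, k]
        for (tn in names(om@low_mod_bands$overlap)) {
            bd <- om@low_mod_bands$overlap[[tn]]
            df[[paste0("overlap_", tn, "_mean")]] <-
                if (is.null(bd)) NA_real_ else bd$mean
            df[[paste0("overlap_", tn, "_sd")]] <-
                if (is.null(bd)) NA_real_ else bd$sd
        }
        bd <- om@low_mod_bands$out_of_field
        df$out_of_field_mean <- if (is.null(bd)) NA_real_ else bd$mean
        df$out_of_field_sd <- if (is.null(bd)) NA_real_ else bd$sd
        utils::write.csv(df, file.path(path, paste0(om@oar_name, ".csv")),
                         row.names = FALSE)
    }
    invisible(path)
}

#' Load a knowledge-based model archive
#'
#' @param path directory written by [saveModel()].
#' @return A [KBModel-class]. Diagnostics-only extras (training feature
#'   matrices and scores) are not part of the archive, so
#'   [curateOutliers()] requires the in-memory model.
#' @export
loadModel <- function(path) {
    mf <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
    if (!identical(mf$schema, "protonKBP-model/1"))
        stop("unrecognized model archive schema")
    cfg <- mf$config
    cfg$n_volume_points <- as.integer(cfg$n_volume_points)
    models <- list()
    oars <- mf$oars
    for (nm in names(oars)) {
        o <- oars[[nm]]
        df <- utils::read.csv(file.path(path, paste0(nm, ".csv")))
        doseRot <- as.matrix(df[grep("^dose_pc", names(df))])
        geoRot <- as.matrix(df[grep("^geo_pc", names(df))])
        ovl <- list()
        for (cn in grep("^overlap_.*_mean$", names(df), value = TRUE)) {
            tn <- sub("^overlap_(.*)_mean$", "\\1", cn)
            if (all(is.na(df[[cn]]))) next
            ovl[[tn]] <- list(mean = df[[cn]],
                              sd = df[[paste0("overlap_", tn, "_sd")]])
        }
        bands <- list(overlap = ovl,
            out_of_field = if (all(is.na(df$out_of_field_mean))) NULL else
                list(mean = df$out_of_field_mean, sd = df$out_of_field_sd))
        coef <- as.matrix(o$coef)
        rownames(coef) <- o$coef_rownames
        models[[nm]] <- new("OARModel", oar_name = nm,
            dose_pca = list(mean = df$dose_mean, rotation = doseRot,
                            sdev = o$dose_sdev),
            geo_pca = list(mean = df$geo_mean, rotation = geoRot,
                           sdev = o$geo_sdev),
            coef = coef, residual_sd = o$residual_sd,
            r_squared = o$r_squared, n_train = as.integer(o$n_train),
            training_ranges = as.data.frame(o$training_ranges),
            low_mod_bands = bands,
            extras = list(center = unlist(o$feature_center),
                          scale = unlist(o$feature_scale),
                          ref_dose_Gy = o$ref_dose_Gy))
    }
    new("KBModel", models = models,
        ged_params = gedParamsFromList(mf$ged_params), config = cfg,
        provenance = as.list(mf$provenance))
}
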