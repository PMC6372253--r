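# Study endpoints: prediction accuracy (predicted vs achieved mean dose),
# knowledge-based vs manual plan comparison, and model-quality diagnostics.

#' Composite structure membership
#'
#' Default name lists of the combined salivary (`comp_sal`: parotid and
#' submandibular glands) and swallowing (`comp_swal`: pharyngeal
#' constrictors, larynx, cricopharynx, upper esophageal sphincter)
#' structures used for aggregate mean-dose reporting.
#' @export
compositeConfig <- function() {
    list(comp_sal = c("parotid_left", "parotid_right",
                      "submandibular_left", "submandibular_right"),
         comp_swal = c("pcm_superior", "pcm_medial", "pcm_inferior",
                       "larynx_upper", "larynx_lower", "cricopharynx",
                       "ues"))
}

# Mean dose over the union of member masks present in a case.
compositeMeanDose <- function(dose, case, members) {
    members <- intersect(members, names(case@oars))
    if (!length(members)) return(NA_real_)
    m <- Reduce(`|`, lapply(members, function(nm) case@oars[[nm]]@mask))
    meanDose(dose, m)
}

#' Predicted versus achieved mean dose
#'
#' Per evaluation case and OAR: mean dose implied by the median predicted
#' DVH, achieved mean dose of the knowledge-based plan, their difference
#' (achieved minus predicted) and any geometric-outlier flags; plus the
#' count of OARs with an absolute difference below a threshold.
#'
#' @param bands_by_case named list (case id) of [predictBands()] results.
#' @param plans_by_case named list (case id) of [PlanResult-class].
#' @param cases named list of [PlanCase-class].
#' @param threshold_Gy accuracy threshold (default 3 Gy).
#' @return list with `table` (one row per case/OAR) and `summary`
#'   (`n_oars`, `n_within`, `frac_within`, `mean_abs_delta_Gy`).
#' @export
predictedVsAchieved <- function(bands_by_case, plans_by_case, cases,
                                threshold_Gy = 3) {
    ids <- names(bands_by_case)
    if (!setequal(ids, names(plans_by_case)))
        stop("case mismatch between bands and plans")
    rows <- list()
    for (id in ids) {
        case <- cases[[id]]
        dose <- plans_by_case[[id]]@dose
        for (nm in names(bands_by_case[[id]])) {
            b <- bands_by_case[[id]][[nm]]
            ach <- meanDose(dose, case@oars[[nm]])
            rows[[length(rows) + 1L]] <- data.frame(case_id = id, oar = nm,
                predicted_mean_Gy = b@mean_dose_Gy,
                achieved_mean_Gy = ach,
                delta_Gy = ach - b@mean_dose_Gy,
                outlier = length(b@outlier_flags) > 0L,
                flags = paste(b@outlier_flags, collapse = ";"))
        }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(table = tab,
         summary = list(n_oars = nrow(tab),
             n_within = sum(abs(tab$delta_Gy) < threshold_Gy),
             frac_within = mean(abs(tab$delta_Gy) < threshold_Gy),
             mean_abs_delta_Gy = mean(abs(tab$delta_Gy)),
             threshold_Gy = threshold_Gy))
}

#' Compare knowledge-based plans with manual plans
#'
#' Each knowledge-based plan is first normalized to the mean boost-PTV dose
#' of its manual counterpart, then paired differences (KBP minus manual)
#' are reported: target homogeneity (HI) and V95 per level, mean dose per
#' OAR and composite, and maximum point dose for the serial structures.
#'
#' @param manual_plans,kbp_plans named lists of [PlanResult-class] keyed by
#'   case id (every KBP needs a manual counterpart).
#' @param cases named list of [PlanCase-class].
#' @param composites a [compositeConfig()] list.
#' @param serial names of serial structures compared by maximum dose.
#' @return list with `per_case` (HI/V95 deltas), `per_oar` (mean-dose
#'   deltas), `composites`, `serial_max` and `summary`.
#' @export
comparePlans <- function(manual_plans, kbp_plans, cases,
                         composites = compositeConfig(),
                         serial = serialStructureNames()) {
    ids <- names(kbp_plans)
    if (!all(ids %in% names(manual_plans)))
        stop("missing manual counterpart plan")
    perCase <- list(); perOAR <- list(); comp <- list(); ser <- list()
    for (id in ids) {
        case <- cases[[id]]
        ptvB <- caseTargets(case)$PTV_B
        man <- manual_plans[[id]]
        kbp <- normalizeToMean(kbp_plans[[id]], ptvB,
                               meanDose(man@dose, ptvB))
        rx <- casePrescriptions(case)
        tgt <- caseTargets(case)
        met <- function(plan) {
            dvhB <- computeDVH(plan@dose, tgt$PTV_B)
            dvhE <- computeDVH(plan@dose, tgt$PTV_E)
            c(hi_b = homogeneityIndex(dvhB), hi_e = homogeneityIndex(dvhE),
              v95_b = volumeAtDose(dvhB, 0.95 * rx[["PTV_B"]]),
              v95_e = volumeAtDose(dvhE, 0.95 * rx[["PTV_E"]]))
        }
        dm <- met(kbp) - met(man)
        perCase[[id]] <- data.frame(case_id = id, t(dm))
        for (nm in modelOARNames(case)) {
            perOAR[[paste(id, nm)]] <- data.frame(case_id = id, oar = nm,
                manual_mean_Gy = meanDose(man@dose, case@oars[[nm]]),
                kbp_mean_Gy = meanDose(kbp@dose, case@oars[[nm]]))
        }
        for (cn in names(composites)) {
            mm <- compositeMeanDose(man@dose, case, composites[[cn]])
            if (is.na(mm)) next  # no member structures in this case
            comp[[paste(id, cn)]] <- data.frame(case_id = id, composite = cn,
                manual_mean_Gy = mm,
                kbp_mean_Gy = compositeMeanDose(kbp@dose, case,
                    composites[[cn]]))
        }
        for (sn in intersect(serial, names(case@oars))) {
            ser[[paste(id, sn)]] <- data.frame(case_id = id, structure = sn,
                manual_max_Gy = maxPointDose(man@dose, case@oars[[sn]]),
                kbp_max_Gy = maxPointDose(kbp@dose, case@oars[[sn]]))
        }
    }
    perCase <- do.call(rbind, perCase)
    perOAR <- do.call(rbind, perOAR)
    perOAR$delta_mean_Gy <- perOAR$kbp_mean_Gy - perOAR$manual_mean_Gy
    comp <- do.call(rbind, comp)
    if (!is.null(comp)) {
        comp$delta_mean_Gy <- comp$kbp_mean_Gy - comp$manual_mean_Gy
        rownames(comp) <- NULL
    }
    ser <- do.call(rbind, ser)
    if (!is.null(ser)) {
        ser$delta_max_Gy <- ser$kbp_max_Gy - ser$manual_max_Gy
        rownames(ser) <- NULL
    }
    rownames(perCase) <- rownames(perOAR) <- NULL
    list(per_case = perCase, per_oar = perOAR, composites = comp,
         serial_max = ser,
         summary = list(mean_delta_hi_b = mean(perCase$hi_b),
             mean_delta_hi_e = mean(perCase$hi_e),
             n_oars = nrow(perOAR),
             n_oars_increase_gt3 = sum(perOAR$delta_mean_Gy > 3),
             mean_delta_oar_mean_Gy = mean(perOAR$delta_mean_Gy)))
}

#' Model-quality diagnostics
#'
#' Per-OAR regression scatter data (geometric PC1 score vs dose PC1 score
#' with the fitted line and +/- 1 residual SD interval), residual-plot data
#' and an R-squared table.
#'
#' @param model a [KBModel-class] (in-memory, with training extras).
#' @return list with `r2_table` and `scatter` data frames.
#' @export
modelDiagnostics <- function(model) {
    r2 <- do.call(rbind, lapply(model@models, function(om)
        data.frame(oar = om@oar_name, n_train = om@n_train,
                   r_squared = om@r_squared,
                   n_dose_pcs = ncol(om@dose_pca$rotation),
                   n_geo_pcs = ncol(om@geo_pca$rotation))))
    scatter <- do.call(rbind, lapply(model@models, function(om) {
        if (is.null(om@extras$X)) return(NULL)
        x <- om@extras$geo_scores[, 1]
        y <- om@extras$dose_scores[, 1]
        fit <- stats::lm.fit(cbind(1, x), y)
        data.frame(oar = om@oar_name, case_id = om@extras$ids,
                   geo_score1 = x, dose_score1 = y,
                   fitted = as.numeric(fit$fitted.values),
                   residual = as.numeric(fit$residuals),
                   slope = unname(fit$coefficients[2]),
                   intercept = unname(fit$coefficients[1]),
                   resid_sd = om@residual_sd[1])
    }))
    rownames(r2) <- NULL
    if (!is.null(scatter)) rownames(scatter) <- NULL
    list(r2_table = r2, scatter = scatter)
}
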