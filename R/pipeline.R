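# End-to-end study pipeline on a synthetic cohort: generate phantoms,
# build manual library plans, train the model, predict for held-out
# evaluation cases, place objectives, optimize knowledge-based plans,
# normalize and evaluate.

#' Run the full knowledge-based planning study on a synthetic cohort
#'
#' Generates `n_train + n_eval` phantom cases, creates a manual-style plan
#' for every case, trains the DVH-prediction model on the training split,
#' then for each evaluation case predicts DVH bands, places objectives
#' (OAR priorities mirrored from the manual plan's planner-skill factor),
#' optimizes a knowledge-based plan, normalizes it to the manual plan's
#' mean boost-PTV dose, and computes the study endpoints.
#'
#' @param n_train,n_eval cohort split sizes (defaults 50/10).
#' @param seed base seed driving phantom sampling and planner skill.
#' @param spacing_mm phantom grid spacing.
#' @param ged_params a [GEDParams-class].
#' @param engine an [engineParams()] list.
#' @param config a [kbpConfig()] list.
#' @param manual_cfg a [manualConfig()] list.
#' @param verbose print per-case progress.
#' @return list with `model`, `diagnostics`, `accuracy` (predicted vs
#'   achieved), `comparison` (KBP vs manual), `bands`, `manual_plans` and
#'   `kbp_plans` (evaluation split, KBPs normalized), `cases` (evaluation
#'   split) and the cohort `manifest`.
#' @export
runStudy <- function(n_train = 50L, n_eval = 10L, seed = 1L,
                     spacing_mm = 4, ged_params = gedParams(),
                     engine = engineParams(), config = kbpConfig(),
                     manual_cfg = manualConfig(), verbose = FALSE) {
    spec <- cohortSpec(n_train + n_eval, seed = seed,
                       spacing_mm = spacing_mm)
    cohort <- generateCohort(spec)
    ids <- names(cohort$cases)
    trainIds <- ids[seq_len(n_train)]
    evalIds <- ids[n_train + seq_len(n_eval)]

    features <- list(); manualPlans <- list()
    evalGED <- list(); evalInfl <- list()
    for (id in ids) {
        case <- cohort$cases[[id]]
        resolved <- resolveGEDParams(ged_params, case)
        ged <- computeGED(case, resolved)
        infl <- caseInfluence(case, engine)
        man <- makeManualPlan(case, infl, engine, manual_cfg, seed = seed)
        features[[id]] <- extractFeatures(case, man@dose, ged, config)
        manualPlans[[id]] <- man
        if (id %in% evalIds) {
            evalGED[[id]] <- ged
            evalInfl[[id]] <- infl
        }
        if (verbose)
            message(sprintf("%s: manual plan %s (V95_B %.1f%%)", id,
                if (man@converged) "ok" else "missed aims",
                man@metrics$v95_b))
    }

    resolved <- resolveGEDParams(ged_params, cohort$cases[[1]])
    model <- trainModel(cohort$cases[trainIds], manualPlans[trainIds],
        ged_params = resolved, config = config,
        features = features[trainIds],
        provenance = list(seed = seed, n_train = n_train,
            manifest_hash = sum(utf8ToInt(paste(
                utils::capture.output(utils::str(cohort$manifest)),
                collapse = "")))))

    bands <- list(); kbpPlans <- list()
    for (id in evalIds) {
        case <- cohort$cases[[id]]
        bands[[id]] <- predictBands(model, case, ged = evalGED[[id]])
        skill <- manualPlans[[id]]@meta$skill
        obj <- placeObjectives(bands[[id]], case,
            oar_priority = manual_cfg$oar_priority * skill,
            target_priorities = manual_cfg$target_priorities,
            hot_priority = manual_cfg$hot_priority,
            serial_max_Gy = manual_cfg$serial_max_Gy,
            serial_priority = manual_cfg$serial_priority)
        kbp <- makeKBPlan(case, obj, infl = evalInfl[[id]], params = engine)
        ptvB <- caseTargets(case)$PTV_B
        kbpPlans[[id]] <- normalizeToMean(kbp, ptvB,
            meanDose(manualPlans[[id]]@dose, ptvB))
        if (verbose)
            message(sprintf("%s: KBP %s", id,
                if (kbp@converged) "ok" else "missed aims"))
    }

    accuracy <- predictedVsAchieved(bands, kbpPlans, cohort$cases)
    comparison <- comparePlans(manualPlans[evalIds], kbpPlans,
                               cohort$cases)
    list(model = model, diagnostics = modelDiagnostics(model),
         accuracy = accuracy, comparison = comparison, bands = bands,
         manual_plans = manualPlans[evalIds], kbp_plans = kbpPlans,
         cases = cohort$cases[evalIds], manifest = cohort$manifest,
         train_ids = trainIds, eval_ids = evalIds)
}
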