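# Spot-weight optimization: weighted quadratic penalties on objective
# violations, minimized by projected-gradient descent (weights >= 0) with a
# backtracking line search, plus the plan-construction policies built on it
# (library-style "manual" plans and knowledge-based plans).

#' Construct an objective set
#'
#' @param objectives data frame with columns `structure`, `kind`
#'   (`target_uniform`, `upper_dose_volume`, `mean_dose`, `max_point`),
#'   `dose_Gy`, `volume_percent` (NA unless dose-volume) and `priority`.
#' @return An [ObjectiveSet-class].
#' @export
objectiveSet <- function(objectives) {
    if (!"volume_percent" %in% names(objectives))
        objectives$volume_percent <- NA_real_
    objectives$volume_percent <- as.numeric(objectives$volume_percent)
    rownames(objectives) <- NULL
    new("ObjectiveSet", objectives = objectives)
}

# One objective row as a list.
objectiveRow <- function(structure, kind, dose_Gy, priority,
                         volume_percent = NA_real_) {
    data.frame(structure = structure, kind = kind, dose_Gy = dose_Gy,
               volume_percent = volume_percent, priority = priority)
}

#' Standard target and serial-structure objectives of a case
#'
#' Uniform-dose objectives at each level's prescription, hot-spot limits at
#' 107 percent of each prescription, and fixed maximum-point objectives for
#' the spinal-cord/brainstem analogs when present.
#'
#' @param case a [PlanCase-class].
#' @param target_priorities named priorities per target level.
#' @param hot_priority priority of the 107-percent hot-spot objectives.
#' @param serial_max_Gy named maximum point doses for serial structures.
#' @param serial_priority their priority.
#' @return data frame of objective rows.
#' @export
targetObjectives <- function(case,
        target_priorities = c(PTV_B = 100, PTV_O = 10, PTV_E = 80),
        hot_priority = 40,
        serial_max_Gy = c(spinal_cord = 45, brainstem = 54),
        serial_priority = 40) {
    rows <- list()
    for (tl in case@targets) {
        nm <- tl@structure@name
        pr <- if (nm %in% names(target_priorities))
            target_priorities[[nm]] else 50
        rows[[length(rows) + 1L]] <-
            objectiveRow(nm, "target_uniform", tl@prescription_Gy, pr)
        rows[[length(rows) + 1L]] <-
            objectiveRow(nm, "max_point", 1.07 * tl@prescription_Gy,
                         hot_priority)
    }
    for (nm in names(serial_max_Gy)) {
        if (nm %in% names(case@oars))
            rows[[length(rows) + 1L]] <- objectiveRow(nm, "max_point",
                serial_max_Gy[[nm]], serial_priority)
    }
    do.call(rbind, rows)
}

# Resolve each objective's voxel rows in the influence map. Sparing
# objectives (mean dose, upper dose-volume) on OARs act on the organ
# cropped from the target union, so they never fight target coverage in
# overlap regions (standard planning practice).
objectiveRows <- function(objectives, case, infl) {
    df <- objectives@objectives
    masks <- c(lapply(caseTargets(case), function(s) s@mask),
               lapply(case@oars, function(s) s@mask))
    tnames <- names(caseTargets(case))
    tu <- targetUnion(case)
    lapply(seq_len(nrow(df)), function(i) {
        nm <- df$structure[i]
        if (!nm %in% names(masks))
            stop(sprintf("objective references unknown structure '%s'", nm))
        m <- masks[[nm]]
        if (!nm %in% tnames &&
            df$kind[i] %in% c("mean_dose", "upper_dose_volume"))
            m <- m & !tu
        rows <- match(which(m), infl@voxels)
        rows <- rows[!is.na(rows)]
        list(rows = rows, kind = df$kind[i], dose = df$dose_Gy[i],
             vol = df$volume_percent[i], w = df$priority[i], n = length(rows))
    })
}

# Update the working voxel selection of dose-volume objectives: the
# hottest `vol` percent may stay above the dose level; cooler voxels that
# still exceed it are penalized (standard DVH-objective heuristic).
updateSelections <- function(obj, d) {
    lapply(obj, function(o) {
        if (o$kind != "upper_dose_volume") { o$sel <- o$rows; return(o) }
        dv <- d[o$rows]
        allowed <- floor(o$vol / 100 * o$n)
        hot <- which(dv > o$dose)
        if (length(hot) <= allowed) { o$sel <- integer(0); return(o) }
        keep <- hot[order(dv[hot], decreasing = TRUE)][seq_len(allowed)]
        o$sel <- o$rows[setdiff(hot, keep)]
        o
    })
}

# Objective value and dose-space gradient for frozen selections.
penaltyValue <- function(obj, d, under_factor = 4) {
    val <- 0
    for (o in obj) {
        if (!o$n) next
        if (o$kind == "target_uniform") {
            dev <- d[o$rows] - o$dose
            wv <- ifelse(dev < 0, under_factor, 1)
            val <- val + o$w / o$n * sum(wv * dev^2)
        } else if (o$kind == "max_point") {
            val <- val + o$w / o$n * sum(pmax(0, d[o$rows] - o$dose)^2)
        } else if (o$kind == "mean_dose") {
            val <- val + o$w * max(0, mean(d[o$rows]) - o$dose)^2
        } else {
            if (length(o$sel))
                val <- val + o$w / o$n * sum((d[o$sel] - o$dose)^2)
        }
    }
    val
}

penaltyGradient <- function(obj, d, under_factor = 4) {
    g <- numeric(length(d))
    for (o in obj) {
        if (!o$n) next
        if (o$kind == "target_uniform") {
            dev <- d[o$rows] - o$dose
            wv <- ifelse(dev < 0, under_factor, 1)
            g[o$rows] <- g[o$rows] + 2 * o$w / o$n * wv * dev
        } else if (o$kind == "max_point") {
            g[o$rows] <- g[o$rows] + 2 * o$w / o$n *
                pmax(0, d[o$rows] - o$dose)
        } else if (o$kind == "mean_dose") {
            ex <- max(0, mean(d[o$rows]) - o$dose)
            if (ex > 0) g[o$rows] <- g[o$rows] + 2 * o$w * ex / o$n
        } else {
            if (length(o$sel))
                g[o$sel] <- g[o$sel] + 2 * o$w / o$n * (d[o$sel] - o$dose)
        }
    }
    g
}

# Target planning aims: 95% of prescription to 99%/98% of PTV_B/PTV_E.
planAimsMet <- function(dose, case, v95_b = 99, v95_e = 98) {
    rx <- casePrescriptions(case)
    tgt <- caseTargets(case)
    nmB <- names(tgt)[1]
    vb <- volumeAtDose(computeDVH(dose, tgt[[nmB]]), 0.95 * rx[[nmB]])
    if (!is.null(tgt$PTV_E)) {
        ve <- volumeAtDose(computeDVH(dose, tgt$PTV_E),
                           0.95 * rx[["PTV_E"]])
        met <- vb >= v95_b && ve >= v95_e
    } else { ve <- NA_real_; met <- vb >= v95_b }
    c(v95_b = vb, v95_e = ve, met = met)
}

#' Optimize spot weights against an objective set
#'
#' Projected-gradient descent on the weighted quadratic penalty of
#' objective violations, with non-negativity projection and a backtracking
#' line search (the accepted objective sequence is monotone non-increasing
#' for a fixed dose-volume voxel selection). Deterministic given inputs and
#' iteration budget.
#'
#' @param infl an [InfluenceMap-class] (all fields of the case).
#' @param case the [PlanCase-class].
#' @param objectives an [ObjectiveSet-class] or objective data frame.
#' @param iterations gradient iterations.
#' @param dvh_every re-select dose-volume objective voxels every this many
#'   iterations.
#' @param w0 optional warm-start weight vector.
#' @return A [PlanResult-class]; `converged` flags whether the target
#'   coverage aims (V95 of 99/98 percent for boost/elective) were met.
#' @export
optimizePlan <- function(infl, case, objectives, iterations = 60L,
                         dvh_every = 5L, w0 = NULL) {
    if (is.data.frame(objectives)) objectives <- objectiveSet(objectives)
    validObject(objectives)
    obj <- objectiveRows(objectives, case, infl)
    A <- infl@A
    if (is.null(w0)) {
        ones <- rep(1, ncol(A))
        d1 <- as.numeric(A %*% ones)
        tuIdx <- which(vapply(obj, function(o)
            o$kind == "target_uniform", TRUE))[1]
        sc <- obj[[tuIdx]]$dose / max(mean(d1[obj[[tuIdx]]$rows]), 1e-9)
        w <- ones * sc
    } else w <- pmax(0, w0)
    d <- as.numeric(A %*% w)
    obj <- updateSelections(obj, d)
    # Jacobi preconditioner: per-spot inverse squared column norm
    prec <- 1 / (Matrix::colSums(A^2) + 1e-9)
    step <- NULL
    log <- numeric(iterations)
    for (it in seq_len(iterations)) {
        if (it > 1L && (it - 1L) %% dvh_every == 0L)
            obj <- updateSelections(obj, d)
        f0 <- penaltyValue(obj, d)
        g <- penaltyGradient(obj, d)
        gw <- as.numeric(Matrix::crossprod(A, g)) * prec
        if (is.null(step))
            step <- 0.5 / max(abs(gw) / (w + 1e-6))
        ok <- FALSE
        for (bt in 1:40) {
            wNew <- pmax(0, w - step * gw)
            dNew <- as.numeric(A %*% wNew)
            fNew <- penaltyValue(obj, dNew)
            if (fNew <= f0 + 1e-12) { ok <- TRUE; break }
            step <- step / 2
        }
        if (ok) {
            w <- wNew; d <- dNew
            log[it] <- fNew
            step <- step * 1.3
        } else log[it] <- f0
    }
    dose <- influenceDose(infl, w)
    aims <- planAimsMet(dose, case)
    new("PlanResult", spot_weights = w, dose = dose, convergence = log,
        converged = as.logical(aims[["met"]]),
        metrics = list(v95_b = aims[["v95_b"]], v95_e = aims[["v95_e"]]),
        meta = list(objectives = objectives@objectives,
                    iterations = iterations))
}

#' Continue an optimization with escalated target priorities
#'
#' Warm-start re-optimization used when a plan misses the target coverage
#' aims: target-uniform priorities are multiplied by `factor` and the
#' optimizer restarts from the current spot weights (`factor = 1` is a
#' plain warm-start re-run).
#'
#' @param plan a [PlanResult-class].
#' @param infl,case as in [optimizePlan()].
#' @param factor escalation factor on target-uniform priorities.
#' @param iterations additional iterations.
#' @param only_if_needed skip (return `plan` unchanged) when the aims are
#'   already met.
#' @return A [PlanResult-class].
#' @export
continueOptimization <- function(plan, infl, case, factor = 6,
                                 iterations = 60L, only_if_needed = TRUE) {
    if (only_if_needed && plan@converged) return(plan)
    objDf <- plan@meta$objectives
    tu <- objDf$kind == "target_uniform"
    objDf$priority[tu] <- objDf$priority[tu] * factor
    out <- optimizePlan(infl, case, objectiveSet(objDf),
                        iterations = iterations, w0 = plan@spot_weights)
    out@meta$continued <- TRUE
    out
}

#' Normalize a plan to a reference structure mean dose
#'
#' Scales spot weights and dose so that the mean dose over `mask` equals
#' `reference_mean_Gy` exactly (knowledge-based plans are normalized to the
#' mean boost-PTV dose of their manual counterpart before comparison).
#'
#' @param plan a [PlanResult-class].
#' @param mask structure mask or [RTStructure-class].
#' @param reference_mean_Gy positive reference mean dose.
#' @return The rescaled [PlanResult-class].
#' @export
normalizeToMean <- function(plan, mask, reference_mean_Gy) {
    stopifnot(reference_mean_Gy > 0)
    cur <- meanDose(plan@dose, mask)
    if (cur <= 0) stop("cannot normalize: current mean dose is zero")
    sc <- reference_mean_Gy / cur
    plan@spot_weights <- plan@spot_weights * sc
    plan@dose@values <- plan@dose@values * sc
    plan@meta$normalization <- sc
    plan
}

#' Manual-planning configuration
#'
#' Tunables of the interactive-planning emulation: target priorities, the
#' per-round pull factor applied to achieved OAR mean doses, the number of
#' objective re-weighting rounds, and the planner-skill range that injects
#' library-realistic variability into OAR effort.
#' @export
manualConfig <- function() {
    list(target_priorities = c(PTV_B = 100, PTV_O = 10, PTV_E = 80),
         hot_priority = 40,
         serial_max_Gy = c(spinal_cord = 45, brainstem = 54),
         serial_priority = 40,
         oar_priority = 10, pull = 0.75, rounds = 2L,
         iterations = c(80L, 40L, 40L), skill_range = c(0.6, 1))
}

# OAR names entering manual objective rounds and DVH models.
modelOARNames <- function(case) {
    setdiff(names(case@oars), c(serialStructureNames(), "body"))
}

#' Create a library-style manual plan
#'
#' Emulates interactive planning as automated objective re-weighting
#' rounds: a target-only optimization, then `rounds` passes in which every
#' modelled OAR receives a mean-dose objective at `pull` times its current
#' achieved mean (priorities scaled by a per-case planner-skill factor
#' drawn uniformly from `skill_range`), followed by a continue-optimization
#' if the coverage aims are missed. Deterministic given `(case, seed)`.
#'
#' @param case a [PlanCase-class].
#' @param infl optional precomputed [InfluenceMap-class].
#' @param params an [engineParams()] list.
#' @param config a [manualConfig()] list.
#' @param seed integer seed for the planner-skill draw.
#' @return A [PlanResult-class] with the skill factor in `meta$skill`.
#' @export
makeManualPlan <- function(case, infl = NULL, params = engineParams(),
                           config = manualConfig(), seed = 1L) {
    if (is.null(infl)) infl <- caseInfluence(case, params)
    oldseed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
    set.seed((seed * 48271L +
              sum(utf8ToInt(case@id)) * 131L) %% 2147483629L)
    skill <- stats::runif(1, config$skill_range[1], config$skill_range[2])

    tObj <- targetObjectives(case, config$target_priorities,
        config$hot_priority, config$serial_max_Gy, config$serial_priority)
    plan <- optimizePlan(infl, case, objectiveSet(tObj),
                         iterations = config$iterations[1])
    oarNames <- modelOARNames(case)
    for (r in seq_len(config$rounds)) {
        rows <- list(tObj)
        for (nm in oarNames) {
            cur <- meanDose(plan@dose, case@oars[[nm]])
            rows[[length(rows) + 1L]] <- objectiveRow(nm, "mean_dose",
                config$pull * cur, config$oar_priority * skill)
        }
        it <- config$iterations[min(r + 1L, length(config$iterations))]
        plan <- optimizePlan(infl, case, objectiveSet(do.call(rbind, rows)),
                             iterations = it, w0 = plan@spot_weights)
    }
    plan <- continueOptimization(plan, infl, case)
    plan@meta$skill <- skill
    plan@meta$mode <- "manual"
    plan
}

#' Create a knowledge-based plan from an objective set
#'
#' Optimizes against the automatically placed objectives and applies a
#' continue-optimization if the coverage aims are missed.
#'
#' @param case a [PlanCase-class].
#' @param objectives an [ObjectiveSet-class] (from [placeObjectives()]).
#' @param infl optional precomputed [InfluenceMap-class].
#' @param params an [engineParams()] list.
#' @param iterations main optimization iterations.
#' @return A [PlanResult-class].
#' @export
makeKBPlan <- function(case, objectives, infl = NULL,
                       params = engineParams(), iterations = 80L) {
    if (is.null(infl)) infl <- caseInfluence(case, params)
    plan <- optimizePlan(infl, case, objectives, iterations = iterations)
    plan <- continueOptimization(plan, infl, case)
    plan@meta$mode <- "kbp"
    plan
}

setMethod("show", "PlanResult", function(object) {
    cat(sprintf("PlanResult (%s): %d spots, V95_B %.1f%%, V95_E %.1f%%, %s\n",
        if (is.null(object@meta$mode)) "plan" else object@meta$mode,
        length(object@spot_weights),
        object@metrics$v95_b, object@metrics$v95_e,
        if (object@converged) "aims met" else "aims NOT met"))
})
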