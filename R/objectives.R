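# Conversion of DVH prediction bands into an optimization objective set.

#' Place optimization objectives from prediction bands
#'
#' For every OAR with a prediction band, emits `k` upper dose-volume
#' objectives at fixed volume anchors whose dose is read off the lower
#' boundary of the predicted DVH range minus a configurable offset
#' (objectives sit "near the lower boundary" to pull the optimizer toward
#' the best plausible sparing). Target-uniform objectives at each
#' prescription and fixed maximum-point objectives for the serial
#' structures are always included.
#'
#' @param bands named list of [PredictionBand-class] (from
#'   [predictBands()]).
#' @param case the [PlanCase-class].
#' @param volume_anchors volume percentages of the dose-volume objectives.
#' @param offset_Gy dose subtracted from the lower-boundary read-off.
#' @param oar_priority priority of the OAR objectives (scalar, or named
#'   per-OAR vector mirroring the manual plan priorities).
#' @param target_priorities,hot_priority,serial_max_Gy,serial_priority see
#'   [targetObjectives()].
#' @return An [ObjectiveSet-class]. OARs of the case without a band get no
#'   objective (warning).
#' @export
placeObjectives <- function(bands, case, volume_anchors = c(10, 50, 85),
        offset_Gy = 0, oar_priority = 10,
        target_priorities = c(PTV_B = 100, PTV_O = 10, PTV_E = 80),
        hot_priority = 40,
        serial_max_Gy = c(spinal_cord = 45, brainstem = 54),
        serial_priority = 40) {
    rows <- list(targetObjectives(case, target_priorities, hot_priority,
                                  serial_max_Gy, serial_priority))
    missing <- setdiff(modelOARNames(case), names(bands))
    if (length(missing))
        warning(sprintf("no prediction band for OAR(s): %s",
            paste(missing, collapse = ", ")))
    for (nm in intersect(modelOARNames(case), names(bands))) {
        pr <- if (length(oar_priority) > 1L) {
            if (nm %in% names(oar_priority)) oar_priority[[nm]] else
                stop(sprintf("no priority given for OAR '%s'", nm))
        } else oar_priority
        lower <- bands[[nm]]@lower
        for (v in volume_anchors) {
            d <- max(0, doseAtVolume(lower, v) - offset_Gy)
            rows[[length(rows) + 1L]] <-
                objectiveRow(nm, "upper_dose_volume", d, pr,
                             volume_percent = v)
        }
    }
    objectiveSet(do.call(rbind, rows))
}

#' Write / read an objective set as JSON
#'
#' @param objectives an [ObjectiveSet-class].
#' @param path JSON file path.
#' @return `readObjectives()` returns an [ObjectiveSet-class].
#' @export
writeObjectives <- function(objectives, path) {
    jsonlite::write_json(objectives@objectives, path, auto_unbox = FALSE,
                         digits = NA, pretty = TRUE, na = "null")
    invisible(path)
}

#' @rdname writeObjectives
#' @export
readObjectives <- function(path) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
    objectiveSet(as.data.frame(df))
}

setMethod("show", "ObjectiveSet", function(object) {
    df <- object@objectives
    cat(sprintf("ObjectiveSet: %d objectives (%d target, %d OAR)\n",
        nrow(df), sum(df$kind == "target_uniform"),
        sum(df$kind %in% c("upper_dose_volume", "mean_dose"))))
})
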