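# Constructors, accessors and geometry helpers for the case model.

#' Construct an anatomical structure
#'
#' @param name structure label (also the mask file name in a case bundle).
#' @param mask logical 3-D array.
#' @param role `"target"`, `"oar"` or `"composite"`.
#' @param laterality `"ipsilateral"`, `"contralateral"`, `"midline"` or
#'   `"n/a"`.
#' @param members member structure names (composites only).
#' @return An [RTStructure-class].
#' @export
rtStructure <- function(name, mask, role = "oar", laterality = "n/a",
                        members = character(0)) {
    storage.mode(mask) <- "logical"
    new("RTStructure", name = name, mask = mask, role = role,
        laterality = laterality, members = members)
}

#' Construct a target level
#' @param structure an [RTStructure-class] with role `"target"`.
#' @param prescription_Gy total prescription dose in Gy.
#' @export
targetLevel <- function(structure, prescription_Gy) {
    new("TargetLevel", structure = structure,
        prescription_Gy = prescription_Gy)
}

#' Construct a beam field
#' @param gantry_deg gantry angle in degrees (IEC 61217, couch 0).
#' @param field_target the per-field union target ([RTStructure-class]).
#' @export
beamField <- function(gantry_deg, field_target) {
    new("BeamField", gantry_deg = gantry_deg %% 360, field_target = field_target)
}

#' Construct a case
#'
#' @param id case identifier.
#' @param grid shared [VoxelGrid-class].
#' @param targets list of [TargetLevel-class], boost first.
#' @param oars list of [RTStructure-class].
#' @param fields list of [BeamField-class].
#' @param fractions number of fractions.
#' @return A validated [PlanCase-class].
#' @export
planCase <- function(id, grid, targets, oars = list(), fields = list(),
                     fractions = 35L) {
    names(oars) <- vapply(oars, function(s) s@name, "")
    new("PlanCase", id = id, grid = grid, targets = targets, oars = oars,
        fields = fields, fractions = as.integer(fractions))
}

#' Beam travel direction for a gantry angle
#'
#' Unit vector in the axial plane: gantry 0 deg is a beam entering from
#' anterior and travelling posteriorly (+y); angles increase clockwise viewed
#' from the feet, so gantry 90 deg enters from the patient's left (-x
#' travel).
#'
#' @param gantry_deg gantry angle in degrees, or a [BeamField-class].
#' @return numeric(3) unit vector.
#' @export
beamDirection <- function(gantry_deg) {
    if (is(gantry_deg, "BeamField")) gantry_deg <- gantry_deg@gantry_deg
    g <- gantry_deg * pi / 180
    c(-sin(g), cos(g), 0)
}

# In-plane lateral axis orthogonal to the beam (right-handed with +z).
beamLateral <- function(gantry_deg) {
    if (is(gantry_deg, "BeamField")) gantry_deg <- gantry_deg@gantry_deg
    g <- gantry_deg * pi / 180
    c(cos(g), sin(g), 0)
}

#' Case accessors
#'
#' `caseTargets()` returns the named list of target structures,
#' `casePrescriptions()` the named vector of target prescriptions,
#' `caseOAR()` one OAR by name, `targetUnion()` the logical union of all
#' target masks (PTV_COMP).
#'
#' @param case a [PlanCase-class].
#' @name case-accessors
#' @export
caseTargets <- function(case) {
    out <- lapply(case@targets, function(t) t@structure)
    names(out) <- vapply(out, function(s) s@name, "")
    out
}

#' @rdname case-accessors
#' @export
casePrescriptions <- function(case) {
    rx <- vapply(case@targets, function(t) t@prescription_Gy, 0)
    names(rx) <- vapply(case@targets, function(t) t@structure@name, "")
    rx
}

#' @rdname case-accessors
#' @param name OAR name.
#' @export
caseOAR <- function(case, name) {
    if (!name %in% names(case@oars))
        stop(sprintf("no OAR named '%s' in case '%s'", name, case@id))
    case@oars[[name]]
}

#' @rdname case-accessors
#' @export
caseBodyMask <- function(case) {
    if ("body" %in% names(case@oars)) case@oars[["body"]]@mask
    else array(TRUE, case@grid@dims)
}

#' @rdname case-accessors
#' @export
targetUnion <- function(case) {
    Reduce(`|`, lapply(case@targets, function(t) t@structure@mask))
}

# Centroid of a mask in world coordinates (mm).
maskCentroid <- function(mask, grid) {
    idx <- which(mask, arr.ind = TRUE) - 1L
    colMeans(indexToWorld(grid, idx))
}

# Distance (mm) from a point to the nearest TRUE voxel centre of a mask.
distToMask <- function(point, mask, grid) {
    idx <- which(mask, arr.ind = TRUE) - 1L
    w <- indexToWorld(grid, idx)
    sqrt(min(rowSums(sweep(w, 2, point)^2)))
}

#' Assign laterality to a left/right structure pair
#'
#' The member of the pair with the greater fractional overlap with the PTV
#' is labelled ipsilateral and the other contralateral; ties are broken by
#' the smaller distance from the structure centroid to the nearest PTV
#' voxel. A single unpaired midline structure gets `"midline"`.
#'
#' @param oar an [RTStructure-class]; with `partner = NULL` the structure is
#'   treated as unpaired and labelled midline.
#' @param ptv target mask (logical array or [RTStructure-class]).
#' @param grid the [VoxelGrid-class].
#' @param partner the opposite member of the pair, or `NULL`.
#' @return For a pair, a named character vector (first element for `oar`,
#'   second for `partner`); for an unpaired structure, `"midline"`.
#' @export
assignLaterality <- function(oar, ptv, grid, partner = NULL) {
    if (is(ptv, "RTStructure")) ptv <- ptv@mask
    if (is.null(partner)) return("midline")
    ovl <- function(s) sum(s@mask & ptv) / sum(s@mask)
    o1 <- ovl(oar); o2 <- ovl(partner)
    if (abs(o1 - o2) > 1e-12) {
        lab <- if (o1 > o2) c("ipsilateral", "contralateral")
               else c("contralateral", "ipsilateral")
    } else {
        d1 <- distToMask(maskCentroid(oar@mask, grid), ptv, grid)
        d2 <- distToMask(maskCentroid(partner@mask, grid), ptv, grid)
        if (abs(d1 - d2) < 1e-9)
            stop("ambiguous laterality: pair identical in overlap and distance")
        lab <- if (d1 < d2) c("ipsilateral", "contralateral")
               else c("contralateral", "ipsilateral")
    }
    names(lab) <- c(oar@name, partner@name)
    lab
}

setMethod("show", "VoxelGrid", function(object) {
    cat(sprintf("VoxelGrid: %d x %d x %d voxels, spacing %s mm\n",
        object@dims[1], object@dims[2], object@dims[3],
        paste(signif(object@spacing, 4), collapse = " x ")))
})

setMethod("show", "RTStructure", function(object) {
    cat(sprintf("RTStructure '%s' (%s, %s): %d voxels\n", object@name,
        object@role, object@laterality, sum(object@mask)))
})

setMethod("show", "PlanCase", function(object) {
    rx <- casePrescriptions(object)
    cat(sprintf("PlanCase '%s'\n", object@id))
    show(object@grid)
    cat(sprintf("  targets: %s\n",
        paste(sprintf("%s (%.4g Gy)", names(rx), rx), collapse = ", ")))
    cat(sprintf("  OARs: %d | fields: %s deg | %d fractions\n",
        length(object@oars),
        paste(vapply(object@fields, function(f) format(f@gantry_deg), ""),
              collapse = "/"),
        object@fractions))
})
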