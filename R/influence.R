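# Simplified pencil-beam-scanning dose model.
#
# Each field carries a rectangular lateral spot grid (spacing 0.425 x the
# in-air FWHM at isocenter) and energy layers whose spread-out-Bragg-peak
# (SOBP) depth profiles have a flat top of one layer spacing, a constant
# entry plateau and a shared exponential distal fall-off. Lateral profiles
# are Gaussian with sigma growing linearly with the layer range. Dose is
# linear in the spot weights; the influence matrix maps weights to dose at
# the voxels of all case structures (plus a conformity ring around the
# targets).

#' Dose-engine parameters
#'
#' @param spot_sigma_mm in-air lateral sigma at the isocenter (3.9 mm for
#'   240 MeV beams).
#' @param sigma_growth_per_mm linear increase of lateral sigma with layer
#'   range (scattering surrogate).
#' @param spacing_factor lateral spot spacing as a fraction of the in-air
#'   FWHM (0.425).
#' @param layer_spacing_mm depth spacing of SOBP peaks (also the flat-top
#'   length of each layer profile).
#' @param entry_plateau relative entry dose of a layer profile.
#' @param falloff_s_mm distal exponential fall-off scale (shared with the
#'   GED model).
#' @param proximal_mm,distal_mm,lateral_mm per-field target margins.
#' @param range_shifter_wet_mm water-equivalent thickness of the range
#'   shifter (bookkeeping for the nominal beam range; the phantom is
#'   water-equivalent so it does not alter the in-patient profile).
#' @param ring_mm width of the conformity ring around the union target
#'   included in the influence voxel set.
#' @return list of class `EngineParams`.
#' @export
engineParams <- function(spot_sigma_mm = 3.9, sigma_growth_per_mm = 0.015,
        spacing_factor = 0.425, layer_spacing_mm = 5, entry_plateau = 0.3,
        falloff_s_mm = 4, proximal_mm = 2, distal_mm = 3, lateral_mm = 5,
        range_shifter_wet_mm = 57, ring_mm = 6) {
    structure(list(spot_sigma_mm = spot_sigma_mm,
        sigma_growth_per_mm = sigma_growth_per_mm,
        spacing_factor = spacing_factor,
        layer_spacing_mm = layer_spacing_mm,
        entry_plateau = entry_plateau, falloff_s_mm = falloff_s_mm,
        proximal_mm = proximal_mm, distal_mm = distal_mm,
        lateral_mm = lateral_mm,
        range_shifter_wet_mm = range_shifter_wet_mm, ring_mm = ring_mm),
        class = "EngineParams")
}

#' SOBP layer depth-dose profile (closed form)
#'
#' Relative dose of one energy layer at water-equivalent depth `d_mm`:
#' zero before the surface, a constant entry plateau, a flat top of
#' `flat_mm` ending at the peak depth, and an exponential distal fall-off.
#'
#' @param d_mm depth below the surface (mm; negative = upstream of the
#'   patient).
#' @param peak_mm depth of the distal end of the flat top.
#' @param params an [engineParams()] list.
#' @return numeric vector of relative dose values in [0, 1].
#' @export
sobpDepthProfile <- function(d_mm, peak_mm, params = engineParams()) {
    out <- numeric(length(d_mm))
    top <- d_mm >= peak_mm - params$layer_spacing_mm & d_mm <= peak_mm
    ent <- d_mm >= 0 & d_mm < peak_mm - params$layer_spacing_mm
    dis <- d_mm > peak_mm
    out[top] <- 1
    out[ent] <- params$entry_plateau
    out[dis] <- exp(-(d_mm[dis] - peak_mm) / params$falloff_s_mm)
    out
}

#' Influence map of one or several beam fields
#'
#' @slot A sparse matrix (voxels x spots) of dose per unit spot weight.
#' @slot voxels integer linear array indices of the rows.
#' @slot spots data frame (field, gantry_deg, u_mm, z_mm, range_mm,
#'   sigma_mm) describing the columns.
#' @slot grid the [VoxelGrid-class].
#' @export
setClass("InfluenceMap",
    representation(A = "ANY", voxels = "integer", spots = "data.frame",
        grid = "VoxelGrid"))

setMethod("show", "InfluenceMap", function(object) {
    cat(sprintf("InfluenceMap: %d voxels x %d spots (%d fields), %.2g%% dense\n",
        nrow(object@A), ncol(object@A),
        length(unique(object@spots$field)),
        100 * Matrix::nnzero(object@A) / prod(dim(object@A))))
})

# Voxel set entering optimization and dose reporting: all targets, all OARs
# except the body contour, plus a conformity ring around the union target.
influenceVoxels <- function(case, params = engineParams()) {
    tu <- targetUnion(case)
    ring <- binaryDilate3D(tu, params$ring_mm, case@grid@spacing) &
        caseBodyMask(case)
    m <- tu | ring
    for (s in case@oars) if (s@name != "body") m <- m | s@mask
    which(m)
}

# Per-voxel (u, z, depth-from-surface) coordinates in one field's frame.
fieldFrameCoords <- function(case, field, voxels) {
    fr <- beamFrame(case@grid, field@gantry_deg)
    body <- which(caseBodyMask(case))
    entry <- rep(Inf, fr$nray)
    be <- tapply(fr$vq[body], fr$ray[body], min)
    entry[as.integer(names(be))] <- be - fr$h / 2
    zc <- rep(axisCoords(case@grid, 3),
              each = case@grid@dims[1] * case@grid@dims[2])
    list(u = fr$u[voxels], z = zc[voxels],
         depth = fr$vq[voxels] - entry[fr$ray[voxels]])
}

#' Build the spot grid and sparse influence matrix of one field
#'
#' Spots are placed on a square lateral grid of spacing
#' `spacing_factor * FWHM` covering the field target expanded by the
#' lateral margin; energy layers are spaced `layer_spacing_mm` apart in
#' depth and restricted per lateral position to the local target depth
#' interval expanded by the proximal/distal margins.
#'
#' @param case a [PlanCase-class].
#' @param field a [BeamField-class].
#' @param params an [engineParams()] list.
#' @param voxels integer array indices to evaluate dose at (default: the
#'   structure voxel set of the case).
#' @param field_id integer label stored in the spot table.
#' @return An [InfluenceMap-class] for this field.
#' @export
buildInfluence <- function(case, field, params = engineParams(),
                           voxels = NULL, field_id = 1L) {
    if (is.null(voxels)) voxels <- influenceVoxels(case, params)
    co <- fieldFrameCoords(case, field, voxels)
    tsel <- which(field@field_target@mask)
    if (!length(tsel)) stop("empty spot grid: field target is empty")
    tin <- match(tsel, voxels)
    if (anyNA(tin)) {
        cot <- fieldFrameCoords(case, field, tsel)
    } else {
        cot <- list(u = co$u[tin], z = co$z[tin], depth = co$depth[tin])
    }
    fwhm <- 2 * sqrt(2 * log(2)) * params$spot_sigma_mm
    delta <- params$spacing_factor * fwhm
    us <- seq(min(cot$u) - params$lateral_mm, max(cot$u) + params$lateral_mm,
              by = delta)
    zs <- seq(min(cot$z) - params$lateral_mm, max(cot$z) + params$lateral_mm,
              by = delta)
    layerR <- seq(floor(min(cot$depth) - params$proximal_mm),
                  max(cot$depth) + params$distal_mm,
                  by = params$layer_spacing_mm)
    spotU <- c(); spotZ <- c(); spotR <- c()
    rloc <- max(delta, 1.01 * max(case@grid@spacing))
    for (u0 in us) {
        duOK <- abs(cot$u - u0) <= params$lateral_mm + delta / 2
        if (!any(duOK)) next
        for (z0 in zs) {
            near <- duOK & abs(cot$z - z0) <= params$lateral_mm + delta / 2
            if (!any(near)) next
            loc <- abs(cot$u - u0) <= rloc & abs(cot$z - z0) <= rloc
            if (!any(loc)) loc <- near
            dmin <- min(cot$depth[loc]); dmax <- max(cot$depth[loc])
            keep <- layerR >= dmin - params$proximal_mm &
                    layerR <= dmax + params$distal_mm
            nk <- sum(keep)
            if (!nk) next
            spotU <- c(spotU, rep(u0, nk)); spotZ <- c(spotZ, rep(z0, nk))
            spotR <- c(spotR, layerR[keep])
        }
    }
    nspot <- length(spotU)
    if (!nspot) stop("empty spot grid")
    sigma <- params$spot_sigma_mm + params$sigma_growth_per_mm * spotR
    ii <- vector("list", nspot); xx <- vector("list", nspot)
    cut <- 3.0
    for (j in seq_len(nspot)) {
        rad <- cut * sigma[j]
        cand <- which(abs(co$u - spotU[j]) <= rad &
                      abs(co$z - spotZ[j]) <= rad)
        if (!length(cand)) { ii[[j]] <- integer(0); xx[[j]] <- numeric(0); next }
        lat <- exp(-((co$u[cand] - spotU[j])^2 + (co$z[cand] - spotZ[j])^2) /
                   (2 * sigma[j]^2))
        dep <- sobpDepthProfile(co$depth[cand], spotR[j], params)
        val <- lat * dep
        keep <- val > 2e-3
        ii[[j]] <- cand[keep]
        xx[[j]] <- val[keep]
    }
    lens <- lengths(ii)
    A <- Matrix::sparseMatrix(i = unlist(ii),
        j = rep(seq_len(nspot), lens), x = unlist(xx),
        dims = c(length(voxels), nspot))
    spots <- data.frame(field = field_id, gantry_deg = field@gantry_deg,
        u_mm = spotU, z_mm = spotZ, range_mm = spotR, sigma_mm = sigma,
        nominal_range_mm = spotR + params$range_shifter_wet_mm)
    new("InfluenceMap", A = A, voxels = as.integer(voxels), spots = spots,
        grid = case@grid)
}

#' Joint influence map of all fields of a case
#'
#' Column-binds the per-field influence matrices over one shared voxel set
#' (multi-field optimization treats all spots jointly).
#'
#' @inheritParams buildInfluence
#' @return An [InfluenceMap-class].
#' @export
caseInfluence <- function(case, params = engineParams()) {
    voxels <- influenceVoxels(case, params)
    maps <- lapply(seq_along(case@fields), function(i)
        buildInfluence(case, case@fields[[i]], params, voxels, field_id = i))
    new("InfluenceMap", A = do.call(cbind, lapply(maps, function(m) m@A)),
        voxels = as.integer(voxels),
        spots = do.call(rbind, lapply(maps, function(m) m@spots)),
        grid = case@grid)
}

# Dose array from an influence map and a weight vector.
influenceDose <- function(infl, weights) {
    vals <- as.numeric(infl@A %*% weights)
    arr <- array(0, infl@grid@dims)
    arr[infl@voxels] <- vals
    new("DoseGrid", values = arr, grid = infl@grid)
}
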