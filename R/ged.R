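# Geometry-based expected dose (GED) engine.
#
# For every beam field and target level, each voxel receives a surrogate
# dose determined by its position along the beamline relative to the target:
# target voxels receive the prescription; voxels upstream receive an entry
# dose that grows with the target length along the beam and tapers with
# distance from the target; voxels downstream receive an exponentially
# falling distal dose. Disjoint target crossings of one ray (non-convex
# targets) are treated as separate sub-targets. Field doses are averaged,
# levels combined by voxelwise maximum, and the total is grey-dilated and
# Gaussian-blurred to emulate the penumbra.

#' Construct GED model parameters
#'
#' @param a0,a1,L0_mm entry-ratio parameters: `r(L) = a0 + a1 * L/(L + L0)`.
#' @param entry_decay_mm linear taper length of the entry dose with upstream
#'   distance from the target.
#' @param falloff_s_mm distal exponential fall-off scale.
#' @param dilation_mm grey-dilation radius applied to the total GED.
#' @param sigma_mm 3-D Gaussian sigma applied after dilation.
#' @param tau_in_Gy,tau_out_Gy in-field / out-of-field partition thresholds;
#'   `NA` (default) resolves to 5 percent of the lowest prescription of the
#'   case being processed.
#' @return A [GEDParams-class].
#' @export
gedParams <- function(a0 = 0.6, a1 = 0.4, L0_mm = 50, entry_decay_mm = 150,
                      falloff_s_mm = 4, dilation_mm = 4, sigma_mm = 4,
                      tau_in_Gy = NA_real_, tau_out_Gy = NA_real_) {
    new("GEDParams", a0 = a0, a1 = a1, L0_mm = L0_mm,
        entry_decay_mm = entry_decay_mm, falloff_s_mm = falloff_s_mm,
        dilation_mm = dilation_mm, sigma_mm = sigma_mm,
        tau_in_Gy = tau_in_Gy, tau_out_Gy = tau_out_Gy)
}

# Resolve NA thresholds against a case's lowest prescription.
resolveGEDParams <- function(params, case) {
    if (is.na(params@tau_in_Gy) || is.na(params@tau_out_Gy)) {
        tau <- 0.05 * min(casePrescriptions(case))
        if (is.na(params@tau_in_Gy)) params@tau_in_Gy <- tau
        if (is.na(params@tau_out_Gy)) params@tau_out_Gy <- tau
        if (params@tau_out_Gy > params@tau_in_Gy)
            params@tau_out_Gy <- params@tau_in_Gy
    }
    validObject(params)
    params
}

# --- beam frame -------------------------------------------------------------

# Rotate all voxel centres into the beam frame of a coplanar field and bin
# them into rays: u = in-plane lateral coordinate, v = depth along the beam
# travel direction, z unchanged. Rays are (u-slot, z-slice) bins at the
# in-plane voxel resolution; depths are quantized to the same step so that
# ray casting is deterministic and oracle-checkable.
.frameCache <- new.env(parent = emptyenv())

beamFrame <- function(grid, gantry_deg) {
    key <- paste(paste(grid@dims, collapse = ","),
                 paste(signif(grid@spacing, 10), collapse = ","),
                 paste(signif(grid@origin, 10), collapse = ","),
                 signif(gantry_deg, 10), sep = "|")
    hit <- .frameCache[[key]]
    if (!is.null(hit)) return(hit)
    d <- beamDirection(gantry_deg)
    l <- beamLateral(gantry_deg)
    nx <- grid@dims[1]; ny <- grid@dims[2]; nz <- grid@dims[3]
    xs <- axisCoords(grid, 1); ys <- axisCoords(grid, 2)
    # in-plane coordinates replicated over z
    Uxy <- outer(xs * l[1], ys * l[2], `+`)
    Vxy <- outer(xs * d[1], ys * d[2], `+`)
    u <- rep(as.vector(Uxy), times = nz)
    v <- rep(as.vector(Vxy), times = nz)
    iz <- rep(seq_len(nz), each = nx * ny)
    h <- min(grid@spacing[1:2])
    iu <- as.integer(round((u - min(u)) / h))
    iv <- as.integer(round((v - min(v)) / h))
    vq <- min(v) + iv * h                       # quantized depth (mm)
    ray <- iu + (iz - 1L) * (max(iu) + 1L) + 1L # 1-based ray id
    fr <- list(u = u, v = v, vq = vq, iv = iv, ray = ray, h = h,
               nray = max(ray))
    if (length(ls(.frameCache)) > 24L) rm(list = ls(.frameCache),
                                          envir = .frameCache)
    assign(key, fr, envir = .frameCache)
    fr
}

# Per-ray disjoint in-target depth intervals for a mask, as a list of dense
# per-ray matrices: entry/exit depth (mm, half-voxel beyond the first/last
# in-target sample) for up to K sub-targets per ray.
rayIntervals <- function(frame, mask) {
    sel <- which(as.vector(mask))
    if (!length(sel)) return(list(K = 0L))
    ray <- frame$ray[sel]; iv <- frame$iv[sel]; vq <- frame$vq[sel]
    ord <- order(ray, iv)
    ray <- ray[ord]; iv <- iv[ord]; vq <- vq[ord]
    # a new sub-target starts at a ray change or a depth gap > 1 slot
    newRun <- c(TRUE, diff(ray) != 0L | diff(iv) > 1L)
    runId <- cumsum(newRun)
    entry <- vq[newRun] - frame$h / 2
    exit <- vq[c(newRun[-1], TRUE)] + frame$h / 2
    runRay <- ray[newRun]
    k <- sequence(rle(runRay)$lengths)  # sub-target index within each ray
    K <- max(k)
    entryM <- matrix(NA_real_, frame$nray, K)
    exitM <- matrix(NA_real_, frame$nray, K)
    entryM[cbind(runRay, k)] <- entry
    exitM[cbind(runRay, k)] <- exit
    list(K = K, entry = entryM, exit = exitM)
}

#' Trace a beam ray through a target mask
#'
#' Returns the disjoint depth intervals (mm along the beam travel
#' direction) where the ray passing closest to a world point crosses the
#' target; a non-convex target crossed twice yields two intervals
#' (sub-targets).
#'
#' @param mask logical target mask or [RTStructure-class].
#' @param grid the [VoxelGrid-class].
#' @param gantry_deg gantry angle of the beam (degrees).
#' @param through numeric(3) world point (mm) identifying the ray (its
#'   lateral/z bin).
#' @return A matrix with columns `entry_depth`, `exit_depth` (mm), zero rows
#'   when the ray misses the target; intervals ordered by depth.
#' @export
traceRayIntervals <- function(mask, grid, gantry_deg, through) {
    if (is(mask, "RTStructure")) mask <- mask@mask
    fr <- beamFrame(grid, gantry_deg)
    l <- beamLateral(gantry_deg)
    uq <- sum(through[1:2] * l[1:2])
    izq <- round((through[3] - grid@origin[3]) / grid@spacing[3]) + 1
    izq <- max(1, min(grid@dims[3], izq))
    # nearest occupied ray in this z-slice
    inz <- which(rep(seq_len(grid@dims[3]),
                     each = grid@dims[1] * grid@dims[2]) == izq)
    rid <- fr$ray[inz[which.min(abs(fr$u[inz] - uq))]]
    ints <- rayIntervals(fr, mask)
    if (ints$K == 0L || all(is.na(ints$entry[rid, ])))
        return(matrix(numeric(0), 0, 2,
                      dimnames = list(NULL, c("entry_depth", "exit_depth"))))
    keep <- !is.na(ints$entry[rid, ])
    out <- cbind(entry_depth = ints$entry[rid, keep],
                 exit_depth = ints$exit[rid, keep])
    out[order(out[, 1]), , drop = FALSE]
}

# Scalar GED contribution of one sub-target interval at quantized depth vq.
# Shared by the vectorized engine and the 1-D reference implementation.
gedContribution <- function(vq, entry, exit, Dp, params) {
    L <- exit - entry
    rL <- params@a0 + params@a1 * L / (L + params@L0_mm)
    ifelse(vq >= entry & vq <= exit, Dp,
        ifelse(vq < entry,
            Dp * rL * pmax(0, 1 - (entry - vq) / params@entry_decay_mm),
            Dp * exp(-(vq - exit) / params@falloff_s_mm)))
}

#' Reference 1-D GED profile
#'
#' Direct scalar implementation of the per-ray GED formulas: given the
#' sub-target depth intervals of one ray, the GED at each sample depth is
#' the maximum over intervals of prescription inside, tapered entry ratio
#' upstream and exponential fall-off downstream. Used as the independent
#' oracle for the volumetric engine.
#'
#' @param depths numeric vector of sample depths (mm along the beam).
#' @param intervals matrix with columns entry/exit depth (mm).
#' @param prescription_Gy target level prescription.
#' @param params a [GEDParams-class].
#' @return numeric vector of GED values (Gy).
#' @export
gedProfile1D <- function(depths, intervals, prescription_Gy, params) {
    if (nrow(intervals) == 0L) return(rep(0, length(depths)))
    val <- rep(0, length(depths))
    for (i in seq_len(nrow(intervals))) {
        val <- pmax(val, gedContribution(depths, intervals[i, 1],
            intervals[i, 2], prescription_Gy, params))
    }
    val
}

#' Raw GED of one field and target level
#'
#' @param case a [PlanCase-class].
#' @param field a [BeamField-class].
#' @param level a [TargetLevel-class] with non-empty target.
#' @param params a [GEDParams-class].
#' @param split_subtargets treat disjoint target crossings of one ray as
#'   separate sub-targets (the default); `FALSE` merges each ray's crossings
#'   into one interval (diagnostic mode).
#' @return numeric 3-D array of GED values (Gy) on the case grid.
#' @export
fieldLevelGED <- function(case, field, level, params = gedParams(),
                          split_subtargets = TRUE) {
    mask <- level@structure@mask
    if (!any(mask)) stop(sprintf("empty target '%s'", level@structure@name))
    Dp <- level@prescription_Gy
    fr <- beamFrame(case@grid, field@gantry_deg)
    ints <- rayIntervals(fr, mask)
    if (!split_subtargets && ints$K > 1L) {
        entry <- suppressWarnings(apply(ints$entry, 1, min, na.rm = TRUE))
        exit <- suppressWarnings(apply(ints$exit, 1, max, na.rm = TRUE))
        entry[!is.finite(entry)] <- NA_real_
        exit[!is.finite(exit)] <- NA_real_
        ints <- list(K = 1L, entry = matrix(entry, ncol = 1),
                     exit = matrix(exit, ncol = 1))
    }
    val <- rep(0, length(fr$ray))
    for (k in seq_len(ints$K)) {
        e <- ints$entry[fr$ray, k]
        x <- ints$exit[fr$ray, k]
        hit <- !is.na(e)
        if (!any(hit)) next
        val[hit] <- pmax(val[hit], gedContribution(fr$vq[hit], e[hit],
            x[hit], Dp, params))
    }
    array(val, dim = case@grid@dims)
}

#' Combine per-field per-level GED volumes and apply the penumbra model
#'
#' Fields of one target level are averaged (keeping the GED on the
#' prescription scale), levels are combined by voxelwise maximum, and the
#' total is grey-dilated then Gaussian-blurred.
#'
#' @param per_field_per_level list (fields) of lists (levels) of GED arrays
#'   on one grid.
#' @param params a [GEDParams-class] (thresholds must be resolved).
#' @param grid the shared [VoxelGrid-class].
#' @return A [GEDResult-class].
#' @export
combineAndSmooth <- function(per_field_per_level, params, grid) {
    dims <- lapply(per_field_per_level, function(fl)
        lapply(fl, dim))
    if (length(unique(lapply(unlist(dims, recursive = FALSE), identity))) > 1L)
        stop("mismatched grids across GED volumes")
    nlev <- length(per_field_per_level[[1]])
    nfield <- length(per_field_per_level)
    levelMean <- lapply(seq_len(nlev), function(li) {
        Reduce(`+`, lapply(per_field_per_level, `[[`, li)) / nfield
    })
    total_raw <- Reduce(pmax, levelMean)
    total_smoothed <- gaussianBlur3D(
        greyDilate3D(total_raw, params@dilation_mm, grid@spacing),
        params@sigma_mm, grid@spacing)
    total_smoothed[total_smoothed < 0] <- 0
    new("GEDResult", per_field_per_level = per_field_per_level,
        total_raw = total_raw, total_smoothed = total_smoothed,
        grid = grid, params = params)
}

#' Compute the full GED distribution of a case
#'
#' Evaluates the raw GED for every beam field and target level, combines
#' them and applies the dilation + Gaussian penumbra model.
#'
#' @param case a [PlanCase-class].
#' @param params a [GEDParams-class]; `NA` thresholds resolve to 5 percent
#'   of the lowest prescription.
#' @param split_subtargets see [fieldLevelGED()].
#' @return A [GEDResult-class].
#' @export
computeGED <- function(case, params = gedParams(), split_subtargets = TRUE) {
    params <- resolveGEDParams(params, case)
    pfl <- lapply(case@fields, function(f)
        lapply(case@targets, function(tl)
            fieldLevelGED(case, f, tl, params, split_subtargets)))
    combineAndSmooth(pfl, params, case@grid)
}

#' Partition an OAR into overlap / in-field / out-of-field regions
#'
#' The target-overlap region is the intersection with any target level; of
#' the remainder, voxels with smoothed GED at or above `tau_in_Gy` are
#' in-field and voxels below `tau_out_Gy` are out-of-field; voxels between
#' the two thresholds are assigned to the in-field region (conservative).
#'
#' @param oar an [RTStructure-class] (non-empty).
#' @param ged a [GEDResult-class].
#' @param targets list of target [RTStructure-class] or a [PlanCase-class].
#' @return An [OARPartition-class].
#' @export
partitionOAR <- function(oar, ged, targets) {
    if (is(targets, "PlanCase")) targets <- caseTargets(targets)
    if (!any(oar@mask)) stop(sprintf("empty OAR '%s'", oar@name))
    tu <- Reduce(`|`, lapply(targets, function(s)
        if (is(s, "RTStructure")) s@mask else s))
    overlap <- oar@mask & tu
    rest <- oar@mask & !tu
    infield <- rest & ged@total_smoothed >= ged@params@tau_out_Gy
    outfield <- rest & !infield
    n <- sum(oar@mask)
    fr <- c(overlap = sum(overlap), in_field = sum(infield),
            out_of_field = sum(outfield)) / n
    new("OARPartition", oar_name = oar@name, overlap = overlap,
        in_field = infield, out_of_field = outfield, fractions = fr)
}

setMethod("show", "GEDResult", function(object) {
    cat(sprintf("GEDResult: %d fields x %d levels, max raw %.3g Gy, max smoothed %.3g Gy\n",
        length(object@per_field_per_level),
        length(object@per_field_per_level[[1]]),
        max(object@total_raw), max(object@total_smoothed)))
})

setMethod("show", "OARPartition", function(object) {
    cat(sprintf("OARPartition '%s': overlap %.1f%%, in-field %.1f%%, out-of-field %.1f%%\n",
        object@oar_name, 100 * object@fractions[1], 100 * object@fractions[2],
        100 * object@fractions[3]))
})
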