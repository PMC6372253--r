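#' @import methods
NULL

#' Voxel grid geometry
#'
#' Regular 3-D raster shared by all masks and dose arrays of a case.
#' Conventions: voxel indices are 0-based in all external metadata, masks are
#' cell-centered, world coordinates are millimetres with patient axes
#' x = left, y = posterior, z = superior.
#'
#' @slot dims integer(3), voxels per axis (all >= 1).
#' @slot spacing numeric(3), voxel spacing in mm (all > 0).
#' @slot origin numeric(3), world position (mm) of the centre of voxel (0,0,0).
#'
#' @seealso [voxelGrid()], [indexToWorld()], [worldToIndex()]
#' @export
setClass("VoxelGrid",
    representation(dims = "integer", spacing = "numeric", origin = "numeric"))

setValidity("VoxelGrid", function(object) {
    if (length(object@dims) != 3L || any(object@dims < 1L))
        return("dims must be three integers >= 1")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        return("spacing must be three positive values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        return("origin must be three finite values (mm)")
    TRUE
})

#' Anatomical structure on a voxel grid
#'
#' A named binary mask with a planning role and a laterality label.
#'
#' @slot name character scalar label.
#' @slot mask logical 3-D array on the case grid.
#' @slot role one of `"target"`, `"oar"`, `"composite"`.
#' @slot laterality one of `"ipsilateral"`, `"contralateral"`, `"midline"`,
#'   `"n/a"`.
#' @slot members character vector of member structure names (composite
#'   structures only, e.g. combined salivary glands; empty otherwise).
#'
#' @seealso [rtStructure()], [assignLaterality()]
#' @export
setClass("RTStructure",
    representation(name = "character", mask = "array", role = "character",
        laterality = "character", members = "character"),
    prototype(members = character(0)))

setValidity("RTStructure", function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
        return("name must be a non-empty string")
    if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
        return("mask must be a logical 3-D array")
    if (!object@role %in% c("target", "oar", "composite"))
        return("role must be one of target/oar/composite")
    if (!object@laterality %in% c("ipsilateral", "contralateral", "midline", "n/a"))
        return("invalid laterality label")
    TRUE
})

#' Target dose level
#'
#' A target structure together with its total prescription dose, e.g. the
#' boost PTV at 70 Gy of a simultaneous-integrated-boost prescription.
#'
#' @slot structure an [RTStructure-class] with role `"target"`.
#' @slot prescription_Gy positive total dose in Gy.
#' @export
setClass("TargetLevel",
    representation(structure = "RTStructure", prescription_Gy = "numeric"))

setValidity("TargetLevel", function(object) {
    if (length(object@prescription_Gy) != 1L ||
        !is.finite(object@prescription_Gy) || object@prescription_Gy <= 0)
        return("prescription_Gy must be a positive scalar")
    if (object@structure@role != "target")
        return("target level structure must have role 'target'")
    TRUE
})

#' Treatment beam field
#'
#' Coplanar beam defined by its gantry angle (IEC 61217: 0 deg = beam from
#' anterior, increasing clockwise viewed from the feet; couch 0) and the
#' per-field target (the union target PTV_COMP).
#'
#' @slot gantry_deg angle in [0, 360).
#' @slot field_target an [RTStructure-class] union target.
#' @seealso [beamField()], [beamDirection()]
#' @export
setClass("BeamField",
    representation(gantry_deg = "numeric", field_target = "RTStructure"))

setValidity("BeamField", function(object) {
    if (length(object@gantry_deg) != 1L || !is.finite(object@gantry_deg) ||
        object@gantry_deg < 0 || object@gantry_deg >= 360)
        return("gantry_deg must lie in [0, 360)")
    if (!any(object@field_target@mask))
        return("field_target must be non-empty")
    TRUE
})

#' Treatment-planning case
#'
#' One patient-like case: grid geometry, ordered target levels (boost PTV_B,
#' transition PTV_O, elective PTV_E), organs at risk and beam fields.
#'
#' @slot id character case identifier.
#' @slot grid the shared [VoxelGrid-class].
#' @slot targets list of [TargetLevel-class], prescriptions strictly
#'   decreasing (boost first); masks pairwise disjoint.
#' @slot oars named list of [RTStructure-class].
#' @slot fields list of [BeamField-class].
#' @slot fractions integer number of fractions.
#' @seealso [planCase()], [readCase()], [generateCase()]
#' @export
setClass("PlanCase",
    representation(id = "character", grid = "VoxelGrid", targets = "list",
        oars = "list", fields = "list", fractions = "integer"))

setValidity("PlanCase", function(object) {
    d <- object@grid@dims
    if (length(object@targets) < 1L)
        return("at least one target level required")
    for (tl in object@targets) {
        if (!is(tl, "TargetLevel")) return("targets must be TargetLevel objects")
        if (!identical(dim(tl@structure@mask), as.integer(d)))
            return(sprintf("grid mismatch for target '%s'", tl@structure@name))
    }
    rx <- vapply(object@targets, function(t) t@prescription_Gy, 0)
    if (length(rx) > 1L && any(diff(rx) >= 0))
        return("prescription order: target prescriptions must be strictly decreasing (boost first)")
    if (length(object@targets) > 1L) {
        tot <- Reduce(`+`, lapply(object@targets, function(t) t@structure@mask))
        if (any(tot > 1L)) return("target masks must be pairwise disjoint")
    }
    for (s in object@oars) {
        if (!is(s, "RTStructure")) return("oars must be RTStructure objects")
        if (!identical(dim(s@mask), as.integer(d)))
            return(sprintf("grid mismatch for OAR '%s'", s@name))
    }
    nm <- vapply(object@oars, function(s) s@name, "")
    if (anyDuplicated(nm)) return("duplicate OAR names")
    for (f in object@fields) {
        if (!is(f, "BeamField")) return("fields must be BeamField objects")
        if (!identical(dim(f@field_target@mask), as.integer(d)))
            return("grid mismatch for field target")
    }
    if (length(object@fractions) != 1L || object@fractions < 1L)
        return("fractions must be a positive integer")
    TRUE
})

#' Dose distribution on a case grid
#'
#' Total physical dose in Gy, one value per voxel. Variable proton RBE is not
#' modelled; values are physical dose.
#'
#' @slot values numeric 3-D array, finite and >= 0.
#' @slot grid the [VoxelGrid-class] the values live on.
#' @export
setClass("DoseGrid",
    representation(values = "array", grid = "VoxelGrid"))

setValidity("DoseGrid", function(object) {
    if (!identical(dim(object@values), as.integer(object@grid@dims)))
        return("values must match grid dims")
    if (any(!is.finite(object@values)) || any(object@values < 0))
        return("dose must be finite and non-negative")
    TRUE
})

#' Cumulative dose-volume histogram
#'
#' @slot dose_Gy increasing dose bin edges in Gy, starting at 0.
#' @slot volume_fraction fraction of the structure receiving at least each
#'   dose, monotone non-increasing from 1 to 0.
#' @seealso [computeDVH()], [doseAtVolume()], [volumeAtDose()]
#' @export
setClass("DVHCurve",
    representation(dose_Gy = "numeric", volume_fraction = "numeric"))

setValidity("DVHCurve", function(object) {
    if (length(object@dose_Gy) != length(object@volume_fraction))
        return("dose and volume vectors must have equal length")
    if (is.unsorted(object@dose_Gy, strictly = TRUE))
        return("dose edges must be strictly increasing")
    if (any(diff(object@volume_fraction) > 1e-12))
        return("volume_fraction must be non-increasing")
    if (any(object@volume_fraction < -1e-12 | object@volume_fraction > 1 + 1e-12))
        return("volume_fraction must lie in [0, 1]")
    TRUE
})

#' Parameters of the geometry-based expected dose model
#'
#' Entry dose before the target follows prescription times
#' `r(L) = a0 + a1 * L / (L + L0)` (L = sub-target length along the beam)
#' tapered linearly to zero over `entry_decay_mm`; dose past the distal edge
#' falls off as `exp(-d / falloff_s_mm)`. The combined distribution is
#' grey-dilated by `dilation_mm` and blurred with a 3-D Gaussian of
#' `sigma_mm` to emulate the penumbra. `tau_in_Gy`/`tau_out_Gy` are the
#' in-field / out-of-field thresholds used to partition OARs; when `NA` they
#' default to 5\% of the lowest prescription of the case at hand.
#'
#' @seealso [gedParams()], [computeGED()], [partitionOAR()]
#' @export
setClass("GEDParams",
    representation(a0 = "numeric", a1 = "numeric", L0_mm = "numeric",
        entry_decay_mm = "numeric", falloff_s_mm = "numeric",
        dilation_mm = "numeric", sigma_mm = "numeric",
        tau_in_Gy = "numeric", tau_out_Gy = "numeric"))

setValidity("GEDParams", function(object) {
    if (object@falloff_s_mm <= 0) return("falloff_s_mm must be > 0")
    if (object@sigma_mm < 0) return("sigma_mm must be >= 0")
    if (object@dilation_mm < 0) return("dilation_mm must be >= 0")
    if (object@a0 <= 0 || object@a1 < 0 || object@a0 + object@a1 > 1 + 1e-12)
        return("entry ratio must satisfy 0 < r(L) <= 1 for all L")
    if (object@L0_mm <= 0 || object@entry_decay_mm <= 0)
        return("L0_mm and entry_decay_mm must be > 0")
    tin <- object@tau_in_Gy; tout <- object@tau_out_Gy
    if (!is.na(tin) && !is.na(tout) && (tout <= 0 || tout > tin))
        return("thresholds must satisfy 0 < tau_out <= tau_in")
    TRUE
})

#' Geometry-based expected dose result
#'
#' @slot per_field_per_level list (fields) of lists (target levels) of raw
#'   GED arrays in Gy.
#' @slot total_raw voxelwise max over levels of the per-level field means.
#' @slot total_smoothed total after grey dilation and Gaussian convolution.
#' @slot grid the [VoxelGrid-class].
#' @slot params the [GEDParams-class] used (thresholds resolved).
#' @export
setClass("GEDResult",
    representation(per_field_per_level = "list", total_raw = "array",
        total_smoothed = "array", grid = "VoxelGrid", params = "GEDParams"))

setValidity("GEDResult", function(object) {
    if (any(!is.finite(object@total_raw)) || any(object@total_raw < 0))
        return("total_raw must be finite and >= 0")
    if (any(!is.finite(object@total_smoothed)) || any(object@total_smoothed < 0))
        return("total_smoothed must be finite and >= 0")
    TRUE
})

#' OAR volume partition
#'
#' Disjoint decomposition of an OAR into target-overlap, in-field (smoothed
#' GED at or above threshold, no target overlap) and out-of-field regions.
#'
#' @slot oar_name character.
#' @slot overlap,in_field,out_of_field logical arrays, pairwise disjoint,
#'   union equal to the OAR mask.
#' @slot fractions named numeric(3) volume fractions summing to 1.
#' @export
setClass("OARPartition",
    representation(oar_name = "character", overlap = "array",
        in_field = "array", out_of_field = "array", fractions = "numeric"))

setValidity("OARPartition", function(object) {
    tot <- object@overlap + object@in_field + object@out_of_field
    if (any(tot > 1L)) return("partition regions must be pairwise disjoint")
    if (abs(sum(object@fractions) - 1) > 1e-9)
        return("fractions must sum to 1")
    TRUE
})

#' Optimization objective set
#'
#' Objectives as a data frame with columns `structure`, `kind` (one of
#' `target_uniform`, `upper_dose_volume`, `mean_dose`, `max_point`),
#' `dose_Gy`, `volume_percent` (NA unless dose-volume) and `priority`.
#'
#' @slot objectives the data frame described above.
#' @seealso [objectiveSet()], [placeObjectives()], [optimizePlan()]
#' @export
setClass("ObjectiveSet", representation(objectives = "data.frame"))

setValidity("ObjectiveSet", function(object) {
    df <- object@objectives
    need <- c("structure", "kind", "dose_Gy", "volume_percent", "priority")
    if (!all(need %in% names(df))) return("missing objective columns")
    if (!all(df$kind %in% c("target_uniform", "upper_dose_volume",
                            "mean_dose", "max_point")))
        return("unknown objective kind")
    if (any(df$dose_Gy < 0)) return("objective dose must be >= 0")
    dv <- df$kind == "upper_dose_volume"
    if (any(dv & (is.na(df$volume_percent) | df$volume_percent <= 0 |
                  df$volume_percent > 100)))
        return("volume_percent must lie in (0, 100] for dose-volume objectives")
    if (any(df$priority < 0)) return("priorities must be >= 0")
    if (!any(df$kind == "target_uniform"))
        return("at least one target objective required")
    TRUE
})

#' Optimized plan
#'
#' @slot spot_weights non-negative spot weight vector (all fields
#'   concatenated).
#' @slot dose resulting [DoseGrid-class].
#' @slot convergence numeric vector of accepted objective values per
#'   iteration (monotone non-increasing).
#' @slot converged logical: were the target planning aims met.
#' @slot metrics named list of achieved plan metrics.
#' @slot meta bookkeeping (objectives used, planner-skill factor, seeds).
#' @export
setClass("PlanResult",
    representation(spot_weights = "numeric", dose = "DoseGrid",
        convergence = "numeric", converged = "logical", metrics = "list",
        meta = "list"))

setValidity("PlanResult", function(object) {
    if (any(object@spot_weights < 0)) return("spot weights must be >= 0")
    TRUE
})

#' Per-OAR trained model component
#'
#' Principal-component parameterization of achieved in-field DVHs and of
#' in-field GED DVHs, a linear regression from geometric features to dose PC
#' scores, residual spread, and mean +/- SD bands for the low-modulation
#' (target-overlap and out-of-field) regions.
#'
#' @slot oar_name character.
#' @slot dose_pca,geo_pca lists with elements `mean` (curve), `rotation`
#'   (orthonormal columns), `sdev`.
#' @slot coef regression coefficient matrix (features + intercept x dose PCs).
#' @slot residual_sd per-dose-PC residual standard deviation.
#' @slot r_squared R^2 of the dose-PC1 regression.
#' @slot n_train number of training cases matched.
#' @slot training_ranges data frame (feature, min, max) of scalar features.
#' @slot low_mod_bands list per region (`overlap`, `out_of_field`) with mean
#'   and SD dose-at-volume curves.
#' @slot extras diagnostics (training scores, feature matrix, ids).
#' @export
setClass("OARModel",
    representation(oar_name = "character", dose_pca = "list", geo_pca = "list",
        coef = "matrix", residual_sd = "numeric", r_squared = "numeric",
        n_train = "integer", training_ranges = "data.frame",
        low_mod_bands = "list", extras = "list"))

setValidity("OARModel", function(object) {
    if (!is.na(object@r_squared) &&
        (object@r_squared < -1e-9 || object@r_squared > 1 + 1e-9))
        return("r_squared must lie in [0, 1]")
    if (object@n_train < 2L) return("n_train must be >= 2")
    TRUE
})

#' Knowledge-based planning model
#'
#' @slot models named list of [OARModel-class], one per organ at risk.
#' @slot ged_params snapshot of the [GEDParams-class] used during training.
#' @slot config training configuration (volume grid, PC cap, thresholds).
#' @slot provenance list (seed, cohort manifest hash, package version).
#' @seealso [trainModel()], [predictBands()]
#' @export
setClass("KBModel",
    representation(models = "list", ged_params = "GEDParams",
        config = "list", provenance = "list"))

#' Predicted DVH band for one OAR
#'
#' @slot oar_name character.
#' @slot lower,median,upper [DVHCurve-class] triple, pointwise ordered.
#' @slot mean_dose_Gy mean dose implied by the median curve.
#' @slot outlier_flags character vector of geometric-outlier labels (empty
#'   when the case lies within the training ranges).
#' @export
setClass("PredictionBand",
    representation(oar_name = "character", lower = "DVHCurve",
        median = "DVHCurve", upper = "DVHCurve", mean_dose_Gy = "numeric",
        outlier_flags = "character"))

setValidity("PredictionBand", function(object) {
    lo <- object@lower@volume_fraction
    md <- object@median@volume_fraction
    up <- object@upper@volume_fraction
    if (any(lo > md + 1e-9) || any(md > up + 1e-9))
        return("band curves must be pointwise ordered lower <= median <= upper")
    TRUE
})
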