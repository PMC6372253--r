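# Cumulative DVH computation and scalar plan-quality metrics.

#' Compute a cumulative dose-volume histogram
#'
#' Fraction of the structure receiving at least each dose level, on a
#' regular edge grid from 0 to just past the maximum dose.
#'
#' @param dose a [DoseGrid-class] or numeric array of doses in Gy.
#' @param mask an [RTStructure-class] or logical array (non-empty).
#' @param bin_width_Gy histogram bin width; the default 0.05 Gy keeps metric
#'   interpolation error well below 0.1 Gy.
#' @return A [DVHCurve-class].
#' @examples
#' g <- voxelGrid(c(5, 5, 5), 4)
#' d <- new("DoseGrid", values = array(54.25, c(5, 5, 5)), grid = g)
#' dvh <- computeDVH(d, array(TRUE, c(5, 5, 5)))
#' doseAtVolume(dvh, 50)
#' @export
computeDVH <- function(dose, mask, bin_width_Gy = 0.05) {
    v <- if (is(dose, "DoseGrid")) dose@values else dose
    m <- if (is(mask, "RTStructure")) mask@mask else mask
    if (!any(m)) stop("empty mask")
    dv <- v[m]
    edges <- seq(0, max(dv) + bin_width_Gy, by = bin_width_Gy)
    # fraction receiving >= edge
    cnt <- length(dv) - findInterval(edges - 1e-12, sort(dv))
    new("DVHCurve", dose_Gy = edges, volume_fraction = cnt / length(dv))
}

#' Dose received by the hottest v percent of the volume (D2\%, D50\%, D98\%)
#'
#' Inverse of the cumulative DVH: the highest tabulated dose still
#' delivered to at least `v_percent` of the volume. This step convention is
#' exact in homogeneous regions (a uniform dose has D2 = D50 = D98 equal to
#' that dose) and at most one bin below the continuum quantile elsewhere;
#' it is monotone non-increasing in `v_percent`.
#'
#' @param dvh a [DVHCurve-class].
#' @param v_percent volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
doseAtVolume <- function(dvh, v_percent) {
    if (any(v_percent <= 0 | v_percent > 100))
        stop("v_percent must lie in (0, 100]")
    vf <- dvh@volume_fraction
    d <- dvh@dose_Gy
    vapply(v_percent / 100, function(tv) {
        if (tv > vf[1]) return(d[1])
        d[max(which(vf >= tv))]
    }, 0)
}

#' Volume percentage receiving at least a dose
#'
#' @param dvh a [DVHCurve-class].
#' @param d_Gy dose in Gy (>= 0).
#' @return Volume percent in [0, 100].
#' @export
volumeAtDose <- function(dvh, d_Gy) {
    if (any(d_Gy < 0)) stop("d_Gy must be >= 0")
    vf <- c(dvh@volume_fraction, 0)
    d <- c(dvh@dose_Gy, max(dvh@dose_Gy) + 1)
    100 * stats::approx(d, vf, xout = pmin(d_Gy, max(d)), rule = 2)$y
}

#' Homogeneity index
#'
#' `HI = 100 * (D2\% - D98\%) / D50\%`; 0 for a perfectly homogeneous dose,
#' invariant to dose rescaling.
#'
#' @param dvh a [DVHCurve-class] of a target structure.
#' @return HI in percent (>= 0 up to interpolation tolerance).
#' @export
homogeneityIndex <- function(dvh) {
    d2 <- doseAtVolume(dvh, 2)
    d50 <- doseAtVolume(dvh, 50)
    d98 <- doseAtVolume(dvh, 98)
    if (d50 <= 0) stop("homogeneity index undefined: D50 is zero")
    100 * (d2 - d98) / d50
}

#' Mean and maximum point dose over a structure
#'
#' @param dose a [DoseGrid-class] or numeric array.
#' @param mask an [RTStructure-class] or logical array (non-empty).
#' @return Dose in Gy.
#' @export
meanDose <- function(dose, mask) {
    v <- if (is(dose, "DoseGrid")) dose@values else dose
    m <- if (is(mask, "RTStructure")) mask@mask else mask
    if (!any(m)) stop("empty mask")
    mean(v[m])
}

#' @rdname meanDose
#' @export
maxPointDose <- function(dose, mask) {
    v <- if (is(dose, "DoseGrid")) dose@values else dose
    m <- if (is(mask, "RTStructure")) mask@mask else mask
    if (!any(m)) stop("empty mask")
    max(v[m])
}

#' Export DVH curves to a data frame
#'
#' Long-format table with columns `structure`, `dose_Gy`, `volume_fraction`,
#' suitable for CSV export or plotting.
#'
#' @param dvhs named list of [DVHCurve-class].
#' @export
dvhTable <- function(dvhs) {
    do.call(rbind, lapply(names(dvhs), function(nm) {
        data.frame(structure = nm, dose_Gy = dvhs[[nm]]@dose_Gy,
                   volume_fraction = dvhs[[nm]]@volume_fraction)
    }))
}

setMethod("show", "DVHCurve", function(object) {
    cat(sprintf("DVHCurve: %d edges, D50 = %.3g Gy, max = %.3g Gy\n",
        length(object@dose_Gy), doseAtVolume(object, 50),
        max(object@dose_Gy)))
})
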