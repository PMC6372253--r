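# Seeded generator of head-and-neck-like synthetic cases.
#
# Each case is a water-equivalent phantom: an elliptical body, a nested
# simultaneous-integrated-boost target set (irregular boost blob PTV_B, the
# exact 5-mm transition shell PTV_O, an elongated elective envelope PTV_E),
# paired lateral salivary-gland analogs, midline swallowing-structure
# analogs with Table-like volume distributions, serial cord/brainstem
# analogs, and a standard three-field beam arrangement. Everything is
# deterministic given (seed, index).

#' Cohort specification for the phantom generator
#'
#' Volume distributions are truncated normals (mean, SD, clipped to
#' min/max, in cm^3) mirroring the published head-and-neck model library
#' population; gantry angles are sampled uniformly in the standard
#' three-field ranges (35-55, 180, 305-330 degrees).
#'
#' @param n_cases number of cases (>= 1).
#' @param seed base RNG seed; case `index` uses a stream derived from
#'   `(seed, index)`.
#' @param spacing_mm isotropic grid spacing (default 4 mm; clinical-scale
#'   grids would use 2.5 mm).
#' @param dims grid dimensions (default sized to hold the body phantom).
#' @param ptv_b_cm3 c(mean, sd, min, max) boost-PTV volume distribution.
#' @param ptv_e_margin_mm range of the elective envelope margin beyond the
#'   boost (the 5-mm transition shell is always constructed exactly).
#' @param oar_menu data frame (name, paired, mean, sd, min, max) of OAR
#'   volume distributions in cm^3.
#' @param proximity range of the per-OAR pull factor toward the boost
#'   centroid (controls PTV overlap variability).
#' @param gantry_1,gantry_3 ranges for the two anterior-oblique fields (the
#'   second field is fixed at 180 degrees).
#' @param prescriptions_Gy named boost/transition/elective total doses.
#' @param fractions fraction count.
#' @param u_shape generate a horseshoe elective envelope wrapping the
#'   midline (exercises ray sub-target splitting).
#' @return A list of class `CohortSpec`.
#' @export
cohortSpec <- function(n_cases = 50L, seed = 1L, spacing_mm = 4,
        dims = NULL,
        ptv_b_cm3 = c(mean = 35, sd = 15, min = 15, max = 60),
        ptv_e_margin_mm = c(8, 14),
        oar_menu = defaultOARMenu(),
        proximity = c(0, 0.35),
        gantry_1 = c(35, 55), gantry_3 = c(305, 330),
        prescriptions_Gy = c(PTV_B = 70, PTV_O = 62.125, PTV_E = 54.25),
        fractions = 35L, u_shape = FALSE) {
    if (n_cases < 1L) stop("n_cases must be >= 1")
    if (is.null(dims)) dims <- ceiling(c(164, 148, 116) / spacing_mm)
    stopifnot(ptv_b_cm3["min"] < ptv_b_cm3["max"],
              diff(ptv_e_margin_mm) >= 0, diff(gantry_1) >= 0,
              diff(gantry_3) >= 0)
    structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
        spacing_mm = spacing_mm, dims = as.integer(dims),
        ptv_b_cm3 = ptv_b_cm3, ptv_e_margin_mm = ptv_e_margin_mm,
        oar_menu = oar_menu, proximity = proximity,
        gantry_1 = gantry_1, gantry_3 = gantry_3,
        prescriptions_Gy = prescriptions_Gy, fractions = fractions,
        u_shape = u_shape), class = "CohortSpec")
}

#' Default OAR volume menu
#'
#' Head-and-neck OAR analogs with truncated-normal volume distributions
#' (cm^3) matching the model-library population statistics: paired parotid
#' and submandibular glands, oral cavity, pharyngeal constrictor muscles,
#' larynx, cricopharynx and upper esophageal sphincter.
#'
#' @return data frame with columns name, paired, mean, sd, min, max.
#' @export
defaultOARMenu <- function() {
    data.frame(
        name = c("parotid", "submandibular", "oral_cavity", "cricopharynx",
                 "larynx_lower", "larynx_upper", "pcm_inferior",
                 "pcm_medial", "pcm_superior", "ues"),
        paired = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE),
        mean = c(27.6, 9.3, 152.8, 3.1, 6.3, 11.6, 4.2, 3.5, 7.3, 1.6),
        sd = c(8.9, 2.6, 84.9, 1.4, 5.5, 5.5, 1.8, 2.6, 3.5, 0.9),
        min = c(12.3, 4.1, 21.1, 0.7, 1.5, 4.4, 1.4, 0.8, 0.8, 0.7),
        max = c(46, 14.9, 362.3, 7.8, 27.3, 30.3, 9.7, 12.9, 17.4, 5.9))
}

#' Structures excluded from DVH-prediction models by default
#'
#' The body contour and serial structures (spinal cord, brainstem) carry
#' fixed maximum-point objectives and are not modelled.
#' @export
serialStructureNames <- function() c("spinal_cord", "brainstem")

# Frozen-coefficient angular noise factor for irregular blob boundaries.
makeAngularNoise <- function(amplitude, ncoef = 4L) {
    a <- stats::rnorm(ncoef); b <- stats::rnorm(ncoef)
    ph <- stats::runif(ncoef, 0, 2 * pi)
    function(theta, phi) {
        val <- 0
        for (l in seq_len(ncoef)) {
            val <- val + (a[l] * cos(l * theta) + b[l] * sin(l * theta)) *
                cos(l * phi + ph[l]) / l
        }
        pmax(0.4, 1 + amplitude * val / 2)
    }
}

# World-coordinate arrays of all voxel centres.
gridCoords <- function(grid) {
    d <- grid@dims
    list(x = array(rep(axisCoords(grid, 1), times = d[2] * d[3]), d),
         y = array(rep(rep(axisCoords(grid, 2), each = d[1]), times = d[3]), d),
         z = array(rep(axisCoords(grid, 3), each = d[1] * d[2]), d))
}

# Superellipsoid blob with angular boundary noise, calibrated in two passes
# to a target volume, then clipped to a bounding mask.
blobMask <- function(grid, co, center, volume_cm3, ratios = c(1, 1, 1),
                     p = 2, noise = NULL, clip = NULL) {
    vol0 <- 4 / 3 * pi * prod(ratios)
    s <- (volume_cm3 * 1000 / vol0)^(1 / 3)
    build <- function(s) {
        a <- s * ratios
        dx <- (co$x - center[1]) / a[1]
        dy <- (co$y - center[2]) / a[2]
        dz <- (co$z - center[3]) / a[3]
        r <- (abs(dx)^p + abs(dy)^p + abs(dz)^p)^(1 / p)
        if (is.null(noise)) m <- r <= 1
        else {
            theta <- atan2(dy, dx)
            rr <- pmax(r, 1e-9)
            phi <- acos(pmin(1, pmax(-1, dz / rr)))
            m <- r <= noise(theta, phi)
        }
        if (!is.null(clip)) m <- m & clip
        m
    }
    m <- build(s)
    v1 <- volumeCm3(m, grid)
    if (v1 > 0) m <- build(s * (volume_cm3 / v1)^(1 / 3))
    m
}

#' Generate one synthetic case
#'
#' Deterministic given `(spec$seed, index)`. The transition target PTV_O is
#' exactly the 5-mm dilation shell of PTV_B clipped to the body; PTV_E is
#' the elective envelope minus boost and shell. OAR laterality is assigned
#' with [assignLaterality()].
#'
#' @param spec a [cohortSpec()].
#' @param index 0-based case index within the cohort.
#' @return A list with elements `case` (a [PlanCase-class]) and `params`
#'   (one-row data frame of the sampled parameters).
#' @export
generateCase <- function(spec, index = 0L) {
    stopifnot(inherits(spec, "CohortSpec"))
    oldseed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
    set.seed((spec$seed * 100003L + as.integer(index) * 7919L) %% 2147483629L)

    grid <- voxelGrid(spec$dims, spec$spacing_mm)
    co <- gridCoords(grid)
    ext <- spec$dims * spec$spacing_mm
    bodyAx <- c(0.44, 0.44, 0.52) * ext   # semi-axes with margin to the edge
    body <- (co$x / bodyAx[1])^2 + (co$y / bodyAx[2])^2 <= 1
    body <- body & abs(co$z) <= bodyAx[3]

    samp <- list(index = index)

    # --- targets -----------------------------------------------------------
    vb <- rtruncnorm1(1, spec$ptv_b_cm3["mean"], spec$ptv_b_cm3["sd"],
                      spec$ptv_b_cm3["min"], spec$ptv_b_cm3["max"])
    bc <- c(stats::runif(1, -20, 20), stats::runif(1, -15, 10),
            stats::runif(1, -5, 20))
    ratios <- exp(stats::runif(3, -0.25, 0.25))
    ratios <- ratios / prod(ratios)^(1 / 3)
    noise <- makeAngularNoise(stats::runif(1, 0.1, 0.3))
    innerBody <- binaryDilate3D(!body, 6, grid@spacing)
    ptvB <- blobMask(grid, co, bc, vb, ratios, p = stats::runif(1, 2, 2.8),
                     noise = noise, clip = !innerBody)
    if (!any(ptvB)) stop("infeasible spec: boost target empty after clipping")

    shell <- binaryDilate3D(ptvB, 5, grid@spacing) & !ptvB & body
    margin <- stats::runif(1, spec$ptv_e_margin_mm[1], spec$ptv_e_margin_mm[2])
    electSeed <- blobMask(grid, co, c(bc[1] * 0.3, 12, bc[3] - 28),
                          0.35 * vb, c(1.3, 0.8, 1), p = 2,
                          clip = !innerBody)
    envelope <- binaryDilate3D(ptvB | electSeed, margin, grid@spacing) & body
    if (spec$u_shape) {
        gap <- abs(co$x) < 9 & co$y < 8
        envelope <- envelope & !gap
        shell <- shell & !gap
        ptvB <- ptvB & !gap
        shell <- binaryDilate3D(ptvB, 5, grid@spacing) & !ptvB & body & !gap
    }
    ptvE <- envelope & !ptvB & !shell
    if (!any(shell) || !any(ptvE))
        stop("infeasible spec: degenerate target set")
    samp$ptv_b_cm3 <- volumeCm3(ptvB, grid)
    samp$ptv_b_sampled_cm3 <- vb
    samp$ptv_e_margin_mm <- margin

    rx <- spec$prescriptions_Gy
    targets <- list(
        targetLevel(rtStructure("PTV_B", ptvB, "target"), rx[["PTV_B"]]),
        targetLevel(rtStructure("PTV_O", shell, "target"), rx[["PTV_O"]]),
        targetLevel(rtStructure("PTV_E", ptvE, "target"), rx[["PTV_E"]]))
    ptvComp <- rtStructure("PTV_COMP", ptvB | shell | ptvE, "target")

    # --- OARs --------------------------------------------------------------
    anchors <- list(
        parotid = c(55, 5, 25), submandibular = c(30, -15, 0),
        oral_cavity = c(0, -32, 10), cricopharynx = c(0, 10, -34),
        larynx_lower = c(0, -4, -30), larynx_upper = c(0, -6, -14),
        pcm_inferior = c(0, 20, -22), pcm_medial = c(0, 21, -6),
        pcm_superior = c(0, 19, 10), ues = c(0, 12, -42))
    shapeRatios <- list(
        parotid = c(0.8, 1, 1.3), submandibular = c(1, 1, 0.9),
        oral_cavity = c(1.2, 1, 0.8), cricopharynx = c(1.4, 0.8, 0.9),
        larynx_lower = c(1.1, 1, 1), larynx_upper = c(1.1, 1, 1),
        pcm_inferior = c(1.8, 0.5, 1.1), pcm_medial = c(1.8, 0.5, 1.1),
        pcm_superior = c(1.8, 0.5, 1.1), ues = c(1.3, 0.9, 0.9))
    oars <- list()
    menu <- spec$oar_menu
    tu <- ptvB | shell | ptvE
    for (i in seq_len(nrow(menu))) {
        nm <- menu$name[i]
        sides <- if (menu$paired[i]) c("left", "right") else "mid"
        for (side in sides) {
            v <- rtruncnorm1(1, menu$mean[i], menu$sd[i], menu$min[i],
                             menu$max[i])
            prox <- stats::runif(1, spec$proximity[1], spec$proximity[2])
            anchor <- anchors[[nm]]
            if (side == "right") anchor[1] <- -anchor[1]
            center <- anchor + stats::runif(3, -4, 4)
            center <- center + prox * (bc - center)
            onoise <- makeAngularNoise(stats::runif(1, 0.05, 0.2))
            m <- blobMask(grid, co, center, v, shapeRatios[[nm]],
                          p = 2, noise = onoise, clip = body)
            if (volumeCm3(m, grid) < 0.4 * v)
                stop(sprintf("infeasible spec: OAR '%s' volume %.1f cm^3 does not fit the body",
                    nm, v))
            oname <- if (side == "mid") nm else paste(nm, side, sep = "_")
            lat <- if (side == "mid") "midline" else "n/a"
            oars[[oname]] <- rtStructure(oname, m, "oar", lat)
            samp[[paste0(oname, "_cm3")]] <- v
            samp[[paste0(oname, "_prox")]] <- prox
        }
        if (menu$paired[i]) {
            ln <- paste(nm, "left", sep = "_"); rn <- paste(nm, "right", sep = "_")
            lab <- assignLaterality(oars[[ln]], tu, grid,
                                    partner = oars[[rn]])
            oars[[ln]]@laterality <- lab[[ln]]
            oars[[rn]]@laterality <- lab[[rn]]
        }
    }
    # serial analogs + body
    cord <- (co$x^2 + (co$y - 38)^2) <= (5 + stats::runif(1, -0.5, 0.5))^2 & body
    bs <- (co$x^2 + (co$y - 30)^2) <= 8^2 & co$z > bodyAx[3] - 28 & body
    oars$spinal_cord <- rtStructure("spinal_cord", cord, "oar", "midline")
    oars$brainstem <- rtStructure("brainstem", bs, "oar", "midline")
    oars$body <- rtStructure("body", body, "oar", "n/a")

    # --- beams -------------------------------------------------------------
    g1 <- stats::runif(1, spec$gantry_1[1], spec$gantry_1[2])
    g3 <- stats::runif(1, spec$gantry_3[1], spec$gantry_3[2])
    fields <- list(beamField(g1, ptvComp), beamField(180, ptvComp),
                   beamField(g3, ptvComp))
    samp$gantry_1 <- g1; samp$gantry_2 <- 180; samp$gantry_3 <- g3

    id <- sprintf("phantom_%03d", as.integer(index))
    samp$id <- id
    case <- planCase(id, grid, targets, oars, fields, spec$fractions)
    list(case = case, params = as.data.frame(samp, stringsAsFactors = FALSE))
}

#' Generate a phantom cohort
#'
#' @param spec a [cohortSpec()].
#' @param indices 0-based case indices (default `0:(n_cases-1)`).
#' @return list with `cases` (named list of [PlanCase-class]) and
#'   `manifest` (data frame of all sampled per-case parameters).
#' @export
generateCohort <- function(spec, indices = NULL) {
    stopifnot(inherits(spec, "CohortSpec"))
    if (spec$n_cases < 1L) stop("n_cases must be >= 1")
    if (is.null(indices)) indices <- seq_len(spec$n_cases) - 1L
    gen <- lapply(indices, function(i) generateCase(spec, i))
    cases <- lapply(gen, `[[`, "case")
    names(cases) <- vapply(cases, function(c) c@id, "")
    manifest <- do.call(rbind, lapply(gen, `[[`, "params"))
    manifest$seed <- spec$seed
    list(cases = cases, manifest = manifest)
}
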