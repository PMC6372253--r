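# Small deterministic fixtures built in code.

# Logical box mask on a grid, limits in 1-based voxel index ranges.
boxMask <- function(dims, xr, yr, zr) {
    m <- array(FALSE, dims)
    m[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
    m
}

# Spherical mask around a world-space centre.
ballMask <- function(grid, center, radius_mm) {
    d <- grid@dims
    x <- axisCoords(grid, 1); y <- axisCoords(grid, 2); z <- axisCoords(grid, 3)
    X <- array(rep(x, times = d[2] * d[3]), d)
    Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
    Z <- array(rep(z, each = d[1] * d[2]), d)
    (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2 <= radius_mm^2
}

# Slab target spanning the full x/z extent: one clean interval per ray for
# a beam from anterior (gantry 0).
slabCase <- function(spacing = 2) {
    dims <- c(11L, 40L, 5L)
    grid <- voxelGrid(dims, spacing)
    slab <- boxMask(dims, c(1, 11), c(16, 25), c(1, 5))
    tl <- targetLevel(rtStructure("PTV_B", slab, "target"), 70)
    fld <- beamField(0, rtStructure("PTV_COMP", slab, "target"))
    planCase("slab", grid, list(tl), fields = list(fld))
}

# C-shaped (horseshoe) target: two lateral arms joined posteriorly, open
# anteriorly. A beam from the left (gantry 90) crosses both arms with a gap
# between them.
horseshoeCase <- function() {
    dims <- c(30L, 30L, 5L)
    grid <- voxelGrid(dims, 4)
    arms <- boxMask(dims, c(6, 9), c(6, 24), c(2, 4)) |
            boxMask(dims, c(22, 25), c(6, 24), c(2, 4)) |
            boxMask(dims, c(6, 25), c(21, 24), c(2, 4))
    tl <- targetLevel(rtStructure("PTV_B", arms, "target"), 70)
    fld <- beamField(90, rtStructure("PTV_COMP", arms, "target"))
    list(case = planCase("horseshoe", grid, list(tl), fields = list(fld)),
         gap = boxMask(dims, c(11, 20), c(10, 18), c(2, 4)))
}

# Compact three-level case with a body and two OARs; fast enough for
# dose-engine tests.
miniCase <- function(two_oars = TRUE) {
    dims <- c(26L, 26L, 14L)
    grid <- voxelGrid(dims, 4)
    body <- ballMask(grid, c(0, 0, 0), 46)
    ptvB <- ballMask(grid, c(0, 0, 0), 12) & body
    shell <- binaryDilate3D(ptvB, 5, grid@spacing) & !ptvB & body
    ptvE <- ballMask(grid, c(0, 4, 0), 22) & body & !ptvB & !shell
    targets <- list(
        targetLevel(rtStructure("PTV_B", ptvB, "target"), 70),
        targetLevel(rtStructure("PTV_O", shell, "target"), 62.125),
        targetLevel(rtStructure("PTV_E", ptvE, "target"), 54.25))
    comp <- rtStructure("PTV_COMP", ptvB | shell | ptvE, "target")
    oars <- list(rtStructure("body", body))
    if (two_oars) {
        oars <- c(list(
            rtStructure("parotid_left", ballMask(grid, c(34, 0, 4), 10) & body),
            rtStructure("oral_cavity",
                        ballMask(grid, c(0, -30, 0), 12) & body, laterality = "midline")),
            oars)
    }
    planCase("mini", grid, targets, oars,
             list(beamField(45, comp), beamField(180, comp)))
}

# Objective data-frame row (mirrors the objective table schema).
objRow <- function(structure, kind, dose_Gy, priority,
                   volume_percent = NA_real_) {
    data.frame(structure = structure, kind = kind, dose_Gy = dose_Gy,
               volume_percent = volume_percent, priority = priority)
}

uniformDose <- function(grid, value) {
    new("DoseGrid", values = array(value, grid@dims), grid = grid)
}

# Synthetic in-field curve library with a known linear geometry-dose
# relation (used to probe the PCA regression).
synthLibrary <- function(n, beta = 2, noise_sd = 0, seed = 1,
                         shuffle = FALSE) {
    set.seed(seed)
    p <- 100
    gmean <- seq(0.9, 0.1, length.out = p)
    gvec <- cos(seq(0, pi, length.out = p)); gvec <- gvec / sqrt(sum(gvec^2))
    dmean <- seq(0.85, 0.05, length.out = p)
    dvec <- sin(seq(0, pi, length.out = p)); dvec <- dvec / sqrt(sum(dvec^2))
    a <- rnorm(n)
    s <- beta * a + rnorm(n, sd = noise_sd)
    if (shuffle) s <- sample(s)
    feats <- list()
    for (i in seq_len(n)) {
        feats[[sprintf("case%02d", i)]] <- list(oar = list(
            geo_curve = gmean + a[i] * gvec,
            dose_curve = dmean + s[i] * dvec,
            overlap_curves = list(),
            overlap_by_level = c(PTV_B = 0, PTV_O = 0, PTV_E = 0),
            oof_curve = NULL,
            scalars = c(oar_volume_cm3 = runif(1, 20, 40),
                        overlap_fraction = runif(1, 0, 0.1),
                        target_volume_cm3 = runif(1, 130, 170),
                        out_of_field_fraction = runif(1, 0, 0.2)),
            fractions = c(overlap = 0, in_field = 1, out_of_field = 0),
            ref_dose_Gy = 70, low_mod_only = FALSE))
    }
    list(features = feats, a = a, s = s)
}

trainSynth <- function(lib, min_train = 10) {
    trainModel(NULL, NULL, config = kbpConfig(min_train = min_train),
               features = lib$features)
}

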