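# Low-level 3-D array helpers shared by the GED engine, the phantom
# generator and the dose engine. All distances are mm; all arrays are
# indexed [x, y, z] with x = left, y = posterior, z = superior.

#' Construct a voxel grid
#'
#' @param dims integer(3) voxels per axis.
#' @param spacing numeric(3) or scalar voxel spacing in mm.
#' @param origin numeric(3) world position (mm) of the centre of voxel
#'   (0,0,0); defaults to centring the grid on the world origin.
#' @return A [VoxelGrid-class].
#' @examples
#' g <- voxelGrid(c(20, 20, 10), 4)
#' @export
voxelGrid <- function(dims, spacing, origin = NULL) {
    dims <- as.integer(dims)
    spacing <- rep_len(as.numeric(spacing), 3L)
    if (is.null(origin))
        origin <- -(dims - 1L) * spacing / 2
    new("VoxelGrid", dims = dims, spacing = spacing,
        origin = as.numeric(origin))
}

#' Convert 0-based voxel indices to world coordinates (mm)
#'
#' @param grid a [VoxelGrid-class].
#' @param ijk numeric matrix (n x 3) of 0-based voxel indices.
#' @return numeric matrix (n x 3) of world coordinates of voxel centres.
#' @export
indexToWorld <- function(grid, ijk) {
    ijk <- rbind(ijk)
    sweep(sweep(ijk, 2, grid@spacing, `*`), 2, grid@origin, `+`)
}

#' Convert world coordinates (mm) to 0-based fractional voxel indices
#'
#' Exact inverse of [indexToWorld()].
#' @inheritParams indexToWorld
#' @param xyz numeric matrix (n x 3) of world coordinates.
#' @export
worldToIndex <- function(grid, xyz) {
    xyz <- rbind(xyz)
    sweep(sweep(xyz, 2, grid@origin, `-`), 2, grid@spacing, `/`)
}

#' Voxel-centre coordinates along one axis
#' @param grid a [VoxelGrid-class].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of world coordinates (mm).
#' @export
axisCoords <- function(grid, axis) {
    grid@origin[axis] + (seq_len(grid@dims[axis]) - 1L) * grid@spacing[axis]
}

#' Voxel volume in cm^3
#' @param grid a [VoxelGrid-class].
#' @export
voxelVolumeCm3 <- function(grid) prod(grid@spacing) / 1000

#' Structure volume in cm^3
#' @param x an [RTStructure-class] or logical mask array.
#' @param grid the [VoxelGrid-class]; taken from the mask context.
#' @export
volumeCm3 <- function(x, grid) {
    m <- if (is(x, "RTStructure")) x@mask else x
    sum(m) * voxelVolumeCm3(grid)
}

# --- separable filters ------------------------------------------------------

# Apply an n x n row-stochastic band matrix along one axis of a 3-D array.
applyAlongAxis <- function(arr, axis, mat) {
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(arr, perm), nrow = d[axis])
    out <- mat %*% m
    aperm(array(out, dim = d[perm]), order(perm))
}

# Dense convolution matrix for a symmetric kernel with reflection padding.
reflectKernelMatrix <- function(n, kernel) {
    hw <- (length(kernel) - 1L) / 2L
    K <- matrix(0, n, n)
    for (off in -hw:hw) {
        j <- seq_len(n) + off
        # reflect out-of-range indices back into 1..n
        j <- ifelse(j < 1L, 2L - j, j)
        j <- ifelse(j > n, 2L * n - j, j)
        K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + kernel[off + hw + 1L]
    }
    K
}

#' Separable 3-D Gaussian blur
#'
#' Discrete sampled Gaussian, normalized so constants are preserved;
#' reflection padding at the array boundary. `sigma_mm = 0` is the identity.
#'
#' @param arr numeric 3-D array.
#' @param sigma_mm Gaussian standard deviation in mm (scalar, isotropic).
#' @param spacing numeric(3) voxel spacing in mm.
#' @export
gaussianBlur3D <- function(arr, sigma_mm, spacing) {
    if (sigma_mm <= 0) return(arr)
    for (axis in 1:3) {
        sv <- sigma_mm / spacing[axis]
        hw <- max(1L, ceiling(3 * sv))
        k <- stats::dnorm(-hw:hw, sd = sv)
        k <- k / sum(k)
        arr <- applyAlongAxis(arr, axis, reflectKernelMatrix(dim(arr)[axis], k))
    }
    arr
}

# Shift a 3-D array by one voxel along an axis, replicating the edge slab.
shiftArray <- function(arr, axis, by) {
    d <- dim(arr)
    idx <- seq_len(d[axis]) - by
    idx[idx < 1L] <- 1L
    idx[idx > d[axis]] <- d[axis]
    switch(axis, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
           arr[, , idx, drop = FALSE])
}

#' Grey (maximum) dilation with a separable cube structuring element
#'
#' Running maximum of radius `radius_mm` (rounded to voxels per axis) along
#' each axis in turn; `radius_mm = 0` is the identity.
#'
#' @inheritParams gaussianBlur3D
#' @param radius_mm dilation radius in mm.
#' @export
greyDilate3D <- function(arr, radius_mm, spacing) {
    if (radius_mm <= 0) return(arr)
    for (axis in 1:3) {
        r <- round(radius_mm / spacing[axis])
        if (r < 1L) next
        out <- arr
        for (by in seq_len(r)) {
            out <- pmax(out, shiftArray(arr, axis, by),
                        shiftArray(arr, axis, -by))
        }
        arr <- out
    }
    arr
}

#' Binary dilation with a Euclidean ball
#'
#' A voxel is set when any mask voxel centre lies within `radius_mm` of its
#' centre (offset enumeration; exact for voxel-centre distances).
#'
#' @param mask logical 3-D array.
#' @param radius_mm ball radius in mm.
#' @param spacing numeric(3) voxel spacing in mm.
#' @export
binaryDilate3D <- function(mask, radius_mm, spacing) {
    if (radius_mm <= 0) return(mask)
    rv <- floor(radius_mm / spacing)
    off <- expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2], dz = -rv[3]:rv[3])
    dist <- sqrt((off$dx * spacing[1])^2 + (off$dy * spacing[2])^2 +
                 (off$dz * spacing[3])^2)
    off <- off[dist <= radius_mm + 1e-9, , drop = FALSE]
    d <- dim(mask)
    out <- array(FALSE, d)
    for (i in seq_len(nrow(off))) {
        sh <- mask
        if (off$dx[i] != 0) sh <- shiftArrayZero(sh, 1L, off$dx[i])
        if (off$dy[i] != 0) sh <- shiftArrayZero(sh, 2L, off$dy[i])
        if (off$dz[i] != 0) sh <- shiftArrayZero(sh, 3L, off$dz[i])
        out <- out | sh
    }
    out
}

# Shift with zero (FALSE) fill rather than edge replication.
shiftArrayZero <- function(arr, axis, by) {
    d <- dim(arr)
    out <- array(if (is.logical(arr)) FALSE else 0, d)
    n <- d[axis]
    if (abs(by) >= n) return(out)
    src <- if (by > 0) 1L:(n - by) else (1L - by):n
    dst <- if (by > 0) (1L + by):n else 1L:(n + by)
    switch(axis,
        out[dst, , ] <- arr[src, , ],
        out[, dst, ] <- arr[, src, ],
        out[, , dst] <- arr[, , src])
    out
}

# --- sampling helpers -------------------------------------------------------

# Truncated normal via rejection with inverse-CDF fallback.
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
    lo <- stats::pnorm(lower, mean, sd)
    hi <- stats::pnorm(upper, mean, sd)
    stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# Smooth periodic pseudo-noise on the unit sphere: low-order spherical
# harmonics with random coefficients, used to roughen phantom boundaries.
sphericalNoise <- function(theta, phi, amplitude, ncoef = 4L) {
    val <- 0
    for (l in seq_len(ncoef)) {
        a <- stats::rnorm(1); b <- stats::rnorm(1); c1 <- stats::rnorm(1)
        val <- val + (a * cos(l * theta) + b * sin(l * theta)) *
            cos(l * phi + c1) / l
    }
    1 + amplitude * val / 2
}
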