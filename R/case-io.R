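# Case bundle I/O: a directory with `case.json` (grid geometry,
# prescriptions, fraction count, gantry angles, structure table) plus one
# NIfTI mask file per structure, filename = structure name.

#' Write a case bundle
#'
#' @param case a [PlanCase-class].
#' @param path directory to create (must not exist or be empty).
#' @return `path`, invisibly.
#' @seealso [readCase()]
#' @export
writeCase <- function(case, path) {
    if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
        stop(sprintf("cannot create case directory '%s'", path))
    writeMask <- function(mask, name) {
        im <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
        RNifti::pixdim(im) <- case@grid@spacing
        RNifti::writeNifti(im, file.path(path, paste0(name, ".nii.gz")))
    }
    structRow <- function(s) {
        row <- list(name = s@name, role = s@role, laterality = s@laterality)
        if (s@role == "composite") row$members <- as.list(s@members)
        row
    }
    for (tl in case@targets) writeMask(tl@structure@mask, tl@structure@name)
    for (s in case@oars) if (s@role != "composite") writeMask(s@mask, s@name)
    ftNames <- unique(vapply(case@fields, function(f) f@field_target@name, ""))
    for (nm in ftNames) {
        f <- case@fields[[which(vapply(case@fields,
                function(f) f@field_target@name, "") == nm)[1]]]
        writeMask(f@field_target@mask, nm)
    }
    meta <- list(
        id = case@id,
        fractions = case@fractions,
        grid = list(dims = case@grid@dims, spacing_mm = case@grid@spacing,
                    origin_mm = case@grid@origin),
        targets = lapply(case@targets, function(tl)
            list(name = tl@structure@name,
                 prescription_Gy = tl@prescription_Gy)),
        oars = lapply(unname(case@oars), structRow),
        fields = lapply(case@fields, function(f)
            list(gantry_deg = f@gantry_deg,
                 field_target = f@field_target@name)))
    jsonlite::write_json(meta, file.path(path, "case.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

readMaskFile <- function(path, name, grid) {
    f <- file.path(path, paste0(name, ".nii.gz"))
    if (!file.exists(f)) f <- file.path(path, paste0(name, ".nii"))
    if (!file.exists(f))
        stop(sprintf("missing mask file for structure '%s'", name))
    im <- RNifti::readNifti(f)
    if (!identical(as.integer(dim(im)), grid@dims))
        stop(sprintf("grid mismatch: mask '%s' has dims %s, expected %s",
            name, paste(dim(im), collapse = "x"),
            paste(grid@dims, collapse = "x")))
    pd <- RNifti::pixdim(im)[1:3]
    if (any(abs(pd - grid@spacing) > 1e-3))
        stop(sprintf("grid mismatch: mask '%s' spacing differs from case.json by > 1e-3 mm",
            name))
    array(as.vector(im) > 0.5, dim = grid@dims)
}

#' Read a case bundle
#'
#' Inverse of [writeCase()]: reads `case.json` and the per-structure NIfTI
#' masks, validates that all masks share the declared grid geometry (spacing
#' mismatches beyond 1e-3 mm are rejected) and that prescriptions are
#' strictly decreasing across target levels.
#'
#' @param path case bundle directory.
#' @return A validated [PlanCase-class].
#' @export
readCase <- function(path) {
    jf <- file.path(path, "case.json")
    if (!file.exists(jf)) stop(sprintf("no case.json in '%s'", path))
    meta <- jsonlite::read_json(jf, simplifyVector = FALSE)
    grid <- voxelGrid(unlist(meta$grid$dims), unlist(meta$grid$spacing_mm),
                      unlist(meta$grid$origin_mm))
    targets <- lapply(meta$targets, function(t) {
        mask <- readMaskFile(path, t$name, grid)
        targetLevel(rtStructure(t$name, mask, role = "target"),
                    t$prescription_Gy)
    })
    oars <- list()
    for (o in meta$oars) {
        if (!is.null(o$role) && !o$role %in% c("target", "oar", "composite"))
            stop(sprintf("unknown role label '%s' for structure '%s'",
                o$role, o$name))
        if (identical(o$role, "composite")) {
            members <- unlist(o$members)
            masks <- lapply(members, function(m) {
                hit <- Filter(function(s) s@name == m, oars)
                if (length(hit)) hit[[1]]@mask else readMaskFile(path, m, grid)
            })
            mask <- Reduce(`|`, masks)
            oars[[o$name]] <- rtStructure(o$name, mask, role = "composite",
                laterality = o$laterality, members = members)
        } else {
            oars[[o$name]] <- rtStructure(o$name, readMaskFile(path, o$name, grid),
                role = "oar", laterality = o$laterality)
        }
    }
    ftCache <- list()
    fields <- lapply(meta$fields, function(f) {
        nm <- f$field_target
        if (is.null(ftCache[[nm]]))
            ftCache[[nm]] <<- rtStructure(nm, readMaskFile(path, nm, grid),
                                          role = "target")
        beamField(f$gantry_deg, ftCache[[nm]])
    })
    planCase(meta$id, grid, targets, oars, fields,
             fractions = meta$fractions)
}
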