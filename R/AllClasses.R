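#' @include AllGenerics.R
NULL

#' ImageVolume: a 3D scalar intensity grid
#'
#' The FLAIR image at any pipeline stage: a 3D numeric array plus voxel
#' spacing in mm. Background (out-of-brain) voxels are expected to be
#' exactly zero once a brain mask has been applied; in-brain intensities
#' must be finite.
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric(3), voxel size in mm along x, y, z.
#' @aliases ImageVolume
#' @exportClass ImageVolume
setClass("ImageVolume",
    representation(data = "array", spacing = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(dim(object@data)) != 3L)
            msg <- c(msg, "data must be a 3D array")
        if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
            any(object@spacing <= 0))
            msg <- c(msg, "spacing must be 3 positive finite values (mm)")
        if (anyNA(object@data) || any(!is.finite(object@data)))
            msg <- c(msg, "intensities must be finite")
        if (is.null(msg)) TRUE else msg
    })

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing voxel size in mm, `c(x, y, z)`.
#' @return an [ImageVolume-class].
#' @examples
#' vol <- ImageVolume(array(rnorm(8 * 8 * 3), c(8, 8, 3)),
#'                    spacing = c(0.43, 0.43, 4))
#' voxelSize(vol)
#' @export
ImageVolume <- function(data, spacing = c(0.43, 0.43, 4)) {
    storage.mode(data) <- "double"
    new("ImageVolume", data = data, spacing = as.numeric(spacing))
}

.MASK_ROLES <- c("brain", "WM", "GM", "CSF", "WMH", "NAWM", "layer", "generic")

#' MaskVolume: a binary 3D grid aligned to an image
#'
#' Values are strictly 0/1. The `role` records what the mask delineates
#' (brain, WM, GM, CSF, WMH, NAWM, a peri-WMH layer, or generic).
#'
#' @slot data 3D array with values in \{0, 1\}.
#' @slot spacing numeric(3), voxel size in mm.
#' @slot role character scalar.
#' @aliases MaskVolume
#' @exportClass MaskVolume
setClass("MaskVolume",
    representation(data = "array", spacing = "numeric", role = "character"),
    validity = function(object) {
        msg <- NULL
        if (length(dim(object@data)) != 3L)
            msg <- c(msg, "data must be a 3D array")
        v <- unique(as.vector(object@data))
        if (!all(v %in% c(0, 1)))
            msg <- c(msg, "mask values must be strictly 0 or 1")
        if (length(object@spacing) != 3L || any(object@spacing <= 0))
            msg <- c(msg, "spacing must be 3 positive values (mm)")
        if (length(object@role) != 1L ||
            !(object@role %in% .MASK_ROLES || grepl("^layer", object@role)))
            msg <- c(msg, sprintf("role must be one of: %s",
                                  paste(.MASK_ROLES, collapse = ", ")))
        if (is.null(msg)) TRUE else msg
    })

#' Construct a MaskVolume
#'
#' @param data 3D array (logical or 0/1 numeric).
#' @param spacing voxel size in mm.
#' @param role mask role label.
#' @return a [MaskVolume-class].
#' @export
MaskVolume <- function(data, spacing = c(0.43, 0.43, 4), role = "generic") {
    d <- array(as.integer(data != 0), dim = dim(data))
    new("MaskVolume", data = d, spacing = as.numeric(spacing), role = role)
}

#' QuantizedVolume: integer grey levels for GLCM analysis
#'
#' In-brain voxels carry levels 1..N (global equal-width binning of the
#' in-brain intensity range, minimum mapped to 1 and maximum to N);
#' background is 0.
#'
#' @slot data 3D integer array.
#' @slot levels number of grey levels N.
#' @slot spacing numeric(3).
#' @aliases QuantizedVolume
#' @exportClass QuantizedVolume
setClass("QuantizedVolume",
    representation(data = "array", levels = "integer", spacing = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(dim(object@data)) != 3L)
            msg <- c(msg, "data must be a 3D array")
        if (object@levels < 2L)
            msg <- c(msg, "levels must be >= 2")
        v <- as.vector(object@data)
        if (any(v < 0L) || any(v > object@levels))
            msg <- c(msg, "values must lie in {0, 1, .., levels}")
        if (is.null(msg)) TRUE else msg
    })

#' GLCM: a grey-level co-occurrence table
#'
#' An N x N table of co-occurrence counts or probabilities of quantized
#' level pairs. When all 8 in-plane directions at distance 1 are
#' accumulated the table is symmetric; when normalized its entries sum
#' to 1.
#'
#' @slot table N x N numeric matrix.
#' @slot normalized logical; TRUE if entries are probabilities.
#' @slot levels number of grey levels N.
#' @aliases GLCM
#' @exportClass GLCM
setClass("GLCM",
    representation(table = "matrix", normalized = "logical",
                   levels = "integer"),
    validity = function(object) {
        msg <- NULL
        if (nrow(object@table) != object@levels ||
            ncol(object@table) != object@levels)
            msg <- c(msg, "table must be levels x levels")
        if (any(object@table < 0))
            msg <- c(msg, "table entries must be nonnegative")
        if (isTRUE(object@normalized) &&
            abs(sum(object@table) - 1) > 1e-12)
            msg <- c(msg, "normalized table must sum to 1")
        if (is.null(msg)) TRUE else msg
    })

#' TextureMaps: per-voxel Haralick feature volumes
#'
#' Four 3D feature grids (contrast, energy, entropy, homogeneity) on the
#' source grid, each voxel holding the feature of the summed 8-direction
#' GLCM of its 3x3 axial neighbourhood, plus a valid-mask marking voxels
#' with a defined neighbourhood. At valid voxels the bounds
#' energy, homogeneity in (0, 1], contrast in [0, (N-1)^2] and
#' entropy in [0, log(N^2)] (natural log) hold.
#'
#' @slot contrast,energy,entropy,homogeneity 3D numeric arrays (NA where
#'   invalid).
#' @slot valid 3D logical array.
#' @slot levels grey levels N used.
#' @slot spacing numeric(3).
#' @aliases TextureMaps
#' @exportClass TextureMaps
setClass("TextureMaps",
    representation(contrast = "array", energy = "array", entropy = "array",
                   homogeneity = "array", valid = "array",
                   levels = "integer", spacing = "numeric"),
    validity = function(object) {
        dims <- lapply(list(object@contrast, object@energy, object@entropy,
                            object@homogeneity, object@valid), dim)
        if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
            return("all maps must share one grid")
        TRUE
    })

#' LayerSet: concentric peri-WMH layers
#'
#' An ordered list of disjoint ring masks built by incremental per-slice
#' disk dilation of the WMH mask, each intersected with the WM mask and
#' exclusive of all previous layers. Layer k spans in-plane distances
#' ((k-1) * increment, k * increment] voxels from the WMH boundary, i.e.
#' thickness `increment * in-plane voxel size` mm.
#'
#' @slot layers list of [MaskVolume-class].
#' @slot incrementVoxels dilation increment per layer, in voxels.
#' @slot inPlaneVoxelMM in-plane voxel size in mm.
#' @aliases LayerSet
#' @exportClass LayerSet
setClass("LayerSet",
    representation(layers = "list", incrementVoxels = "integer",
                   inPlaneVoxelMM = "numeric"),
    validity = function(object) {
        if (!all(vapply(object@layers, is, TRUE, "MaskVolume")))
            return("layers must be MaskVolume objects")
        if (object@incrementVoxels < 1L)
            return("incrementVoxels must be >= 1")
        TRUE
    })

#' ModelResult: a fitted-model summary
#'
#' Term-level output of one regression: estimates, standard errors,
#' t-values, raw and (once a family has been adjusted) FDR-corrected
#' p-values, with the model formula and the number of complete cases
#' used after listwise deletion.
#'
#' @slot outcome outcome variable name.
#' @slot terms data.frame with columns term, estimate, se, t_value,
#'   p_value and optionally p_fdr.
#' @slot nUsed integer, rows used.
#' @slot formula character, the fitted formula.
#' @slot extra list of auxiliary output (e.g. marginal means).
#' @aliases ModelResult
#' @exportClass ModelResult
setClass("ModelResult",
    representation(outcome = "character", terms = "data.frame",
                   nUsed = "integer", formula = "character", extra = "list"),
    validity = function(object) {
        need <- c("term", "estimate", "se", "t_value", "p_value")
        if (!all(need %in% names(object@terms)))
            return(sprintf("terms must contain columns: %s",
                           paste(need, collapse = ", ")))
        p <- object@terms$p_value
        if (any(!is.na(p) & (p < 0 | p > 1)))
            return("p values must lie in [0, 1]")
        TRUE
    })

# ---- show methods -----------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("ImageVolume %dx%dx%d, voxel %.3gx%.3gx%.3g mm\n",
                d[1], d[2], d[3], object@spacing[1], object@spacing[2],
                object@spacing[3]))
    nz <- object@data[object@data != 0]
    if (length(nz))
        cat(sprintf("  non-zero intensities: [%.4g, %.4g], n = %d\n",
                    min(nz), max(nz), length(nz)))
})

setMethod("show", "MaskVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("MaskVolume [%s] %dx%dx%d, %d voxels set\n", object@role,
                d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "QuantizedVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("QuantizedVolume %dx%dx%d, %d levels\n",
                d[1], d[2], d[3], object@levels))
})

setMethod("show", "GLCM", function(object) {
    cat(sprintf("GLCM %dx%d (%s)\n", object@levels, object@levels,
                if (object@normalized) "normalized" else "counts"))
    print(signif(object@table, 4))
})

setMethod("show", "TextureMaps", function(object) {
    d <- dim(object@contrast)
    cat(sprintf(
        "TextureMaps %dx%dx%d (N = %d): contrast, energy, entropy, homogeneity\n",
        d[1], d[2], d[3], object@levels))
    cat(sprintf("  valid voxels: %d\n", sum(object@valid)))
})

setMethod("show", "LayerSet", function(object) {
    cat(sprintf("LayerSet: %d layers, increment %d voxels (%.2f mm each)\n",
                length(object@layers), object@incrementVoxels,
                object@incrementVoxels * object@inPlaneVoxelMM))
    cat(sprintf("  outer distances (mm): %s\n",
                paste(format(layerDistances(object), digits = 3),
                      collapse = ", ")))
})

setMethod("show", "ModelResult", function(object) {
    cat(sprintf("ModelResult: %s  (n = %d)\n", object@formula, object@nUsed))
    print(object@terms, row.names = FALSE)
})

# ---- accessor methods -------------------------------------------------

#' @rdname accessors
#' @export
setMethod("imgData", "ImageVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelSize", "ImageVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("voxelSize", "MaskVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("maskData", "MaskVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("maskRole", "MaskVolume", function(x) x@role)

#' @rdname texture-accessors
#' @export
setMethod("textureMap", "TextureMaps", function(x, which) {
    which <- match.arg(which,
        c("contrast", "energy", "entropy", "homogeneity"))
    slot(x, which)
})

#' @rdname texture-accessors
#' @export
setMethod("validMask", "TextureMaps", function(x) x@valid)

#' @rdname layer-accessors
#' @export
setMethod("layerMasks", "LayerSet", function(x) x@layers)

#' @rdname layer-accessors
#' @export
setMethod("layerThickness", "LayerSet",
    function(x) x@incrementVoxels * x@inPlaneVoxelMM)

#' @rdname layer-accessors
#' @export
setMethod("layerDistances", "LayerSet",
    function(x) seq_along(x@layers) * layerThickness(x))

# ---- small shared helpers --------------------------------------------

.checkAligned <- function(a, b, what = c("volumes")) {
    da <- dim(if (is(a, "ImageVolume")) a@data else a@data)
    db <- dim(if (is(b, "ImageVolume")) b@data else b@data)
    if (!identical(da, db))
        stop(sprintf("grids are not aligned: %s vs %s (%s)",
                     paste(da, collapse = "x"), paste(db, collapse = "x"),
                     paste(what, collapse = ", ")))
    invisible(TRUE)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}
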