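#' @include AllClasses.R
NULL

#' Quantize in-brain intensities to N grey levels
#'
#' Equal-width binning of the in-brain intensity range into `N` bins,
#' computed over the whole volume (maps first, ROIs second — per-ROI
#' rebinning would make voxel values depend on the ROI definition). The
#' in-brain minimum maps to level 1 and the maximum to level `N` (the
#' top edge is clamped into bin `N`; values landing exactly on an
#' interior bin edge go to the upper bin). Background voxels are 0.
#'
#' Any strictly increasing affine transform of the in-brain intensities
#' leaves the quantized volume — and hence all GLCM features —
#' unchanged.
#'
#' @param img an [ImageVolume-class].
#' @param brain brain [MaskVolume-class].
#' @param N number of grey levels (>= 2), default 8.
#' @return a [QuantizedVolume-class].
#' @export
quantizeVolume <- function(img, brain, N = 8L) {
    stopifnot(is(img, "ImageVolume"), is(brain, "MaskVolume"))
    .checkAligned(img, brain)
    N <- as.integer(N)
    if (N < 2L) stop("N must be >= 2")
    inb <- brain@data > 0
    v <- img@data[inb]
    lo <- min(v); hi <- max(v)
    if (hi == lo) stop("constant in-brain intensity: cannot quantize")
    q <- array(0L, dim(img@data))
    lev <- floor((v - lo) / (hi - lo) * N) + 1L
    lev[lev > N] <- N
    q[inb] <- as.integer(lev)
    new("QuantizedVolume", data = q, levels = N, spacing = img@spacing)
}

.GLCM_DIRS <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                   c(1L, 1L), c(-1L, -1L), c(1L, -1L), c(-1L, 1L))

#' GLCM of one 3x3 axial patch
#'
#' Accumulates, for each of the 8 in-plane direction offsets at
#' distance 1, the ordered level pairs between every patch voxel and
#' its offset neighbour when the neighbour also lies inside the patch,
#' then sums the 8 directional tables. Pairs involving background
#' (level 0) voxels are excluded — counting them would fabricate an
#' artificial extra level at brain edges. Because the direction set is
#' closed under negation, the summed table is symmetric, and the order
#' of the directions is immaterial.
#'
#' @param q a [QuantizedVolume-class].
#' @param center integer(3) voxel coordinate; its full 3x3 in-plane
#'   neighbourhood must lie inside the grid.
#' @param normalize divide by the total pair count (default TRUE).
#' @param directions list of in-plane integer offsets; defaults to all
#'   8 neighbours.
#' @return a [GLCM-class].
#' @export
patchGLCM <- function(q, center, normalize = TRUE,
                      directions = .GLCM_DIRS) {
    stopifnot(is(q, "QuantizedVolume"))
    d <- dim(q@data)
    center <- as.integer(center)
    if (center[1] < 2L || center[1] > d[1] - 1L ||
        center[2] < 2L || center[2] > d[2] - 1L ||
        center[3] < 1L || center[3] > d[3])
        stop("center must have a full 3x3 in-plane neighbourhood inside the grid")
    N <- q@levels
    P <- matrix(0, N, N)
    z <- center[3]
    xs <- (center[1] - 1L):(center[1] + 1L)
    ys <- (center[2] - 1L):(center[2] + 1L)
    for (dir in directions) {
        for (px in xs) for (py in ys) {
            nx <- px + dir[1]; ny <- py + dir[2]
            if (nx < xs[1] || nx > xs[3] || ny < ys[1] || ny > ys[3]) next
            a <- q@data[px, py, z]; b <- q@data[nx, ny, z]
            if (a > 0L && b > 0L) P[a, b] <- P[a, b] + 1
        }
    }
    tot <- sum(P)
    if (normalize) {
        if (tot == 0)
            stop("patch contains no countable (non-background) pair")
        P <- P / tot
    }
    new("GLCM", table = P, normalized = normalize, levels = N)
}

#' Haralick features of a normalized GLCM
#'
#' For a normalized co-occurrence table `p(i, j)`:
#' contrast `sum p(i,j) (i-j)^2`, energy `sum p(i,j)^2`, entropy
#' `-sum p(i,j) log p(i,j)` (natural log; `0 log 0 := 0`), homogeneity
#' `sum p(i,j) / (1 + |i-j|)`. A distribution concentrated on one
#' diagonal cell gives (0, 1, 0, 1).
#'
#' @param glcm a normalized [GLCM-class] (or a matrix summing to 1).
#' @return named numeric: `contrast`, `energy`, `entropy`,
#'   `homogeneity`.
#' @export
haralickFeatures <- function(glcm) {
    if (is(glcm, "GLCM")) {
        if (!glcm@normalized)
            stop("GLCM is unnormalized: normalize before computing features")
        P <- glcm@table
    } else if (is.matrix(glcm)) {
        P <- glcm
        if (abs(sum(P) - 1) > 1e-8)
            stop("GLCM is unnormalized: entries must sum to 1")
    } else stop("glcm must be a GLCM or a matrix")
    N <- nrow(P)
    i <- row(P); j <- col(P)
    pos <- P > 0
    c(contrast = sum(P * (i - j)^2),
      energy = sum(P^2),
      entropy = -sum(P[pos] * log(P[pos])),
      homogeneity = sum(P / (1 + abs(i - j))))
}

#' Voxel-wise Haralick texture maps
#'
#' Slides a 3x3 in-plane patch across every axial slice, computes the
#' summed 8-direction GLCM of each patch and assigns the four Haralick
#' features of that table to the centre voxel, producing four texture
#' volumes aligned with the source grid. Voxels on slice borders, and
#' voxels whose patch yields no countable pair (fully background), are
#' flagged invalid and carry NA.
#'
#' The heavy lifting runs in compiled code; [patchGLCM()] plus
#' [haralickFeatures()] reproduce any single voxel of the result
#' exactly.
#'
#' @param q a [QuantizedVolume-class].
#' @return a [TextureMaps-class].
#' @examples
#' a <- array(0, c(12, 12, 3)); a[3:10, 3:10, ] <- 50
#' br <- MaskVolume(a > 0)
#' tm <- makeTextureMaps(quantizeVolume(ImageVolume(a + (a > 0) *
#'   rep(c(0, 10), 216)), br))
#' range(textureMap(tm, "contrast"), na.rm = TRUE)
#' @export
makeTextureMaps <- function(q) {
    stopifnot(is(q, "QuantizedVolume"))
    res <- cpp_texture_maps(q@data, q@levels)
    new("TextureMaps",
        contrast = res$contrast, energy = res$energy,
        entropy = res$entropy, homogeneity = res$homogeneity,
        valid = array(res$valid, dim(q@data)),
        levels = q@levels, spacing = q@spacing)
}

#' Extract first- and second-order features within an ROI
#'
#' First-order features (`mean`, `std`) are computed from the
#' normalized intensity image over all ROI voxels (`std` uses the
#' unbiased n-1 estimator and is NA for a single voxel). Second-order
#' features are the means of each texture map over the ROI intersected
#' with the valid-mask; invalid voxels are dropped silently, but a
#' dropped fraction above 50% triggers a warning. An empty effective
#' ROI yields all-NA features with a warning rather than an error, so
#' subjects without WMH flow through cohort runs.
#'
#' @param img_norm normalized [ImageVolume-class] (see
#'   [normalizeIntensities()]).
#' @param maps a [TextureMaps-class] on the same grid.
#' @param roi a [MaskVolume-class].
#' @return named numeric
#'   (`mean`, `std`, `contrast`, `energy`, `entropy`, `homog`) with
#'   attributes `n_voxels`, `n_valid`, `dropped_frac`.
#' @export
extractRoiFeatures <- function(img_norm, maps, roi) {
    stopifnot(is(img_norm, "ImageVolume"), is(maps, "TextureMaps"),
              is(roi, "MaskVolume"))
    .checkAligned(img_norm, roi)
    roiIdx <- roi@data > 0
    n_roi <- sum(roiIdx)
    out <- c(mean = NA_real_, std = NA_real_, contrast = NA_real_,
             energy = NA_real_, entropy = NA_real_, homog = NA_real_)
    eff <- roiIdx & maps@valid
    n_valid <- sum(eff)
    if (n_roi == 0L || n_valid == 0L) {
        warning("empty effective ROI: returning missing features")
        attr(out, "n_voxels") <- n_roi
        attr(out, "n_valid") <- n_valid
        attr(out, "dropped_frac") <- if (n_roi > 0) 1 else NA_real_
        return(out)
    }
    v <- img_norm@data[roiIdx]
    out["mean"] <- mean(v)
    out["std"] <- if (length(v) > 1L) stats::sd(v) else NA_real_
    if (length(v) == 1L)
        warning("single-voxel ROI: std undefined under the n-1 convention")
    out["contrast"] <- mean(maps@contrast[eff])
    out["energy"] <- mean(maps@energy[eff])
    out["entropy"] <- mean(maps@entropy[eff])
    out["homog"] <- mean(maps@homogeneity[eff])
    dropped <- 1 - n_valid / n_roi
    if (dropped > 0.5)
        warning(sprintf(
            "%.0f%% of ROI voxels lack a valid texture neighbourhood",
            100 * dropped))
    attr(out, "n_voxels") <- n_roi
    attr(out, "n_valid") <- n_valid
    attr(out, "dropped_frac") <- dropped
    out
}

#' Signed cube root
#'
#' `sign(x) * |x|^(1/3)`; the transform applied to all textural
#' measures to tame skewness. 0 and 1 are fixed points.
#'
#' @param x numeric.
#' @return numeric of the same shape.
#' @export
cubeRoot <- function(x) sign(x) * abs(x)^(1 / 3)

.FEATURE_COL_RE <- "^(WMHT|NAWMT|layer[0-9]+)_(mean|std|contrast|energy|entropy|homog)$"

#' Cube-root transform the textural columns of a feature record
#'
#' Every textural measure (`WMHT_*`, `NAWMT_*`, `layer<k>_*` columns)
#' is replaced by its signed cube root; the raw value is retained in a
#' `<name>_raw` column.
#'
#' @param features a one-or-more-row data.frame of subject features.
#' @return the transformed data.frame.
#' @export
transformFeatures <- function(features) {
    stopifnot(is.data.frame(features))
    cols <- grep(.FEATURE_COL_RE, names(features), value = TRUE)
    for (cn in cols) {
        features[[paste0(cn, "_raw")]] <- features[[cn]]
        features[[cn]] <- cubeRoot(features[[cn]])
    }
    features
}
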