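#' @include AllClasses.R
NULL

#' Threshold-based WMH segmentation
#'
#' A voxel is labelled white matter hyperintensity when its (bias
#' corrected) intensity exceeds `k` times the median of the in-brain
#' non-zero intensities and it lies inside the WM mask. This is the
#' automated seeding stage; the manual rater refinement used on real
#' scans is out of scope, and the WM intersection takes over its role
#' of suppressing GM/CSF false positives.
#'
#' Because the threshold is a multiple of the median, the segmentation
#' is invariant to positive rescaling of the intensities, but not to
#' additive shifts.
#'
#' @param img bias-corrected [ImageVolume-class].
#' @param brain brain [MaskVolume-class].
#' @param wm WM [MaskVolume-class] (nonempty).
#' @param k threshold multiplier (> 0), default 1.2.
#' @param min_size minimum connected-component size in voxels
#'   (26-connectivity); the default 1 disables the filter.
#' @return a [MaskVolume-class] with role `"WMH"` (possibly empty).
#' @export
segmentWMH <- function(img, brain, wm, k = 1.2, min_size = 1L) {
    stopifnot(is(img, "ImageVolume"), is(brain, "MaskVolume"),
              is(wm, "MaskVolume"))
    .checkAligned(img, brain); .checkAligned(img, wm)
    if (k <= 0) stop("k must be positive")
    if (sum(wm@data) == 0) stop("WM mask is empty")
    inb <- img@data[brain@data > 0]
    inb <- inb[inb != 0]
    if (length(inb) == 0L) stop("brain mask contains no non-zero intensities")
    thr <- k * stats::median(inb)
    m <- (img@data > thr) & brain@data > 0 & wm@data > 0
    if (min_size > 1L && any(m)) {
        lab <- cpp_label3d(array(as.integer(m), dim(m)))
        keep <- which(tabulate(lab[lab > 0]) >= min_size)
        m <- array(lab %in% keep, dim(m))
    }
    MaskVolume(m, img@spacing, role = "WMH")
}

# 2x2 square erosion per axial slice, anchor fixed at the top-left
# element: output voxel (x, y) survives iff (x, y), (x+1, y), (x, y+1)
# and (x+1, y+1) are all set. A 2x2 kernel has no centre, so the anchor
# convention is part of the contract (bit-exact reproducibility).
.erode2x2 <- function(m) {
    d <- dim(m)
    out <- array(FALSE, d)
    if (d[1] < 2L || d[2] < 2L) return(out)
    a <- m[-d[1], -d[2], , drop = FALSE]
    b <- m[-1,    -d[2], , drop = FALSE]
    cc <- m[-d[1], -1,   , drop = FALSE]
    e <- m[-1,    -1,    , drop = FALSE]
    out[-d[1], -d[2], ] <- a & b & cc & e
    out
}

#' Construct the normal-appearing white matter mask
#'
#' NAWM is the WM mask minus the WMH mask, eroded with a 2x2 square
#' kernel applied per axial slice to limit partial-volume contamination
#' from GM and CSF at the WM boundary. The result is disjoint from WMH
#' and contained in WM; re-subtracting WMH changes nothing.
#'
#' @param wm WM [MaskVolume-class].
#' @param wmh WMH [MaskVolume-class] on the same grid.
#' @return a [MaskVolume-class] with role `"NAWM"` (may be empty).
#' @export
buildNAWM <- function(wm, wmh) {
    stopifnot(is(wm, "MaskVolume"), is(wmh, "MaskVolume"))
    .checkAligned(wm, wmh)
    core <- wm@data > 0 & wmh@data == 0
    MaskVolume(.erode2x2(core), wm@spacing, role = "NAWM")
}

#' Lesion-volume summary normalized by head size
#'
#' WMH volume in mm^3 (voxel count times voxel volume), expressed as a
#' percentage of the estimated total intracranial volume,
#' `100 * WMH / eTIV`, and its cube root (the transform applied for
#' skewness).
#'
#' @param wmh WMH [MaskVolume-class].
#' @param etiv_mm3 estimated total intracranial volume in mm^3 (> 0);
#'   an input scalar, typically from volumetric T1 processing.
#' @return a list with `wmh_volume_mm3`, `etiv_mm3`, `wmh_pct_eTIV`,
#'   `wmh_pct_eTIV_cuberoot`.
#' @examples
#' m <- array(0, c(10, 10, 10)); m[1:10, 1:10, 1:10][1:1000] <- 1
#' s <- summarizeVolumes(MaskVolume(m, c(0.43, 0.43, 4)), 1485100)
#' round(s$wmh_pct_eTIV, 4)
#' @export
summarizeVolumes <- function(wmh, etiv_mm3) {
    stopifnot(is(wmh, "MaskVolume"))
    if (!is.numeric(etiv_mm3) || length(etiv_mm3) != 1L || etiv_mm3 <= 0)
        stop("etiv_mm3 must be a single positive value")
    vol <- sum(wmh@data) * prod(wmh@spacing)
    pct <- 100 * vol / etiv_mm3
    list(wmh_volume_mm3 = vol, etiv_mm3 = etiv_mm3,
         wmh_pct_eTIV = pct, wmh_pct_eTIV_cuberoot = pct^(1 / 3))
}

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b [MaskVolume-class] objects on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
diceCoefficient <- function(a, b) {
    stopifnot(is(a, "MaskVolume"), is(b, "MaskVolume"))
    .checkAligned(a, b)
    sa <- sum(a@data); sb <- sum(b@data)
    if (sa + sb == 0) return(1)
    2 * sum(a@data & b@data) / (sa + sb)
}
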