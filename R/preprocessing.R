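#' @include AllClasses.R synthetic.R
NULL

#' BiasField: a smooth multiplicative intensity field
#'
#' Strictly positive everywhere; the corrected image is the input
#' divided by the field.
#'
#' @aliases BiasField
#' @exportClass BiasField
setClass("BiasField", contains = "ImageVolume",
    validity = function(object) {
        if (any(object@data <= 0))
            return("bias field must be strictly positive")
        TRUE
    })

#' Estimate a multiplicative bias field
#'
#' Least-squares fit of a low-order 3D polynomial to the in-brain
#' log-intensity, made tissue-aware: the log image is modelled as a
#' piecewise-constant tissue term (`n_classes` intensity classes) plus
#' the smooth polynomial log-bias, and the two are estimated by
#' alternating Lloyd-style class assignment with a polynomial fit of
#' the class-detrended residual. Without the tissue term a polynomial
#' fit absorbs anatomy (the brain's dark-CSF/bright-GM layout is
#' itself low-order in space) instead of the scanner bias. The field
#' is the exponential of the fitted surface, normalized to mean 1
#' in-brain. This substitutes for N4-style correction; real data that
#' were already N4-corrected can skip the stage.
#'
#' Nonpositive in-brain intensities cannot enter the log fit; they are
#' excluded and their count reported via a message.
#'
#' @param img an [ImageVolume-class].
#' @param brain brain [MaskVolume-class] (nonempty).
#' @param degree polynomial degree, >= 1 (default 2; degree <= 3
#'   recommended — higher orders start absorbing anatomy).
#' @param n_classes number of tissue intensity classes for the
#'   piecewise-constant term (default 4: CSF, WM, GM, lesion); 1 gives
#'   the plain polynomial fit.
#' @param n_iter alternating iterations.
#' @return a [BiasField-class] on the same grid.
#' @seealso [correctBias()]
#' @export
estimateBiasField <- function(img, brain, degree = 2L, n_classes = 4L,
                              n_iter = 10L) {
    stopifnot(is(img, "ImageVolume"), is(brain, "MaskVolume"))
    .checkAligned(img, brain)
    if (degree < 1L)
        stop("degree must be >= 1")
    inb <- which(brain@data > 0)
    if (length(inb) == 0L)
        stop("brain mask is empty (all zero)")
    y <- img@data[inb]
    pos <- y > 0
    if (!any(pos))
        stop("no positive in-brain intensities to fit")
    if (any(!pos))
        message(sprintf(
            "estimateBiasField: excluded %d nonpositive in-brain voxels from the log fit",
            sum(!pos)))
    d <- dim(img@data)
    ly <- log(y[pos])
    X <- .polyBasis(d, degree, subset = inb[pos])
    K <- min(as.integer(n_classes), length(unique(ly)))
    g <- rep(0, length(ly))
    centers <- stats::quantile(ly, probs = (seq_len(K) - 0.5) / K,
                               names = FALSE)
    for (it in seq_len(n_iter)) {
        r <- ly - g
        # Lloyd step: assign to nearest class level, update levels
        a <- max.col(-abs(outer(r, centers, `-`)), ties.method = "first")
        for (ki in seq_len(K))
            if (any(a == ki)) centers[ki] <- mean(r[a == ki])
        fit <- stats::lm.fit(X, ly - centers[a])
        g <- as.vector(X %*% fit$coefficients)
    }
    Xall <- .polyBasis(d, degree)
    field <- exp(array(as.vector(Xall %*% fit$coefficients), d))
    field <- field / mean(field[inb])
    new("BiasField", data = field, spacing = img@spacing)
}

#' Divide an image by a bias field
#'
#' @param img an [ImageVolume-class].
#' @param field a [BiasField-class] (or any positive `ImageVolume`).
#' @return the corrected [ImageVolume-class]; exact zeros (background)
#'   stay zero.
#' @export
correctBias <- function(img, field) {
    stopifnot(is(img, "ImageVolume"), is(field, "ImageVolume"))
    .checkAligned(img, field)
    ImageVolume(img@data / field@data, img@spacing)
}

#' Min-range intensity normalization over non-zero voxels
#'
#' Subtracts the minimum and divides by the range of the non-zero
#' values in the (skull-stripped) image, so that non-zero voxels land
#' in \[0, 1\] while background zeros remain zero. This is the
#' normalization used before first-order (mean/SD) feature extraction.
#'
#' @param img an [ImageVolume-class] with at least two distinct
#'   non-zero values.
#' @return the normalized [ImageVolume-class].
#' @examples
#' a <- array(0, c(8, 8, 3)); a[2:4, 2:4, 2] <- c(10, 20, 30)
#' rng <- range(imgData(normalizeIntensities(ImageVolume(a)))[a != 0])
#' stopifnot(rng[1] == 0, rng[2] == 1)
#' @export
normalizeIntensities <- function(img) {
    stopifnot(is(img, "ImageVolume"))
    dat <- img@data
    nz <- dat != 0
    v <- dat[nz]
    if (length(v) < 2L)
        stop("image needs at least 2 non-zero voxels")
    m <- min(v)
    r <- max(v) - m
    if (r == 0)
        stop("zero intensity range: non-zero foreground is constant")
    dat[nz] <- (v - m) / r
    ImageVolume(dat, img@spacing)
}
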