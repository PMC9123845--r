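#' @include AllClasses.R
NULL

#' PhantomSpec: geometry and signal model of a synthetic FLAIR phantom
#'
#' Describes a skull-stripped FLAIR-like head phantom built from four
#' nested ellipsoids: an outer sulcal-CSF shell, a GM shell, a WM shell
#' and an inner ventricular-CSF core. Fractions in `tissueGeometry` are
#' relative semi-axes: `brain` scales the half-grid; `gmOuter`,
#' `wmOuter` and `csfInner` scale the brain semi-axes and must satisfy
#' `1 > gmOuter > wmOuter > csfInner > 0`. Tissue means follow FLAIR
#' ordering (CSF darkest; lesions, added via [lesionSpec()], brightest).
#' With `noiseSD = 0` and `biasAmplitude = 0` every voxel of a tissue
#' class carries exactly its tissue mean.
#'
#' The default grid (96 x 96 x 27 at 0.43 x 0.43 x 4 mm) mirrors an
#' axial FLAIR acquisition at desk scale; the default tissue fractions
#' give brain composition of roughly 40% GM, 31% WM and 29% CSF so that
#' the median in-brain intensity falls in WM, which is what makes a
#' threshold at 1.2 x median separate lesions from GM.
#'
#' @slot gridShape integer(3).
#' @slot voxelSizeMM numeric(3), mm.
#' @slot tissueGeometry named list: brain, gmOuter, wmOuter, csfInner.
#' @slot tissueMeans named numeric: csf, wm, gm.
#' @slot noiseSD additive Gaussian noise SD.
#' @slot biasAmplitude peak-to-trough multiplicative bias range minus 1
#'   (0.1 means the field spans a factor of 1.1 across the brain).
#' @slot biasOrder polynomial degree of the simulated bias field.
#' @slot rngSeed integer seed; identical seeds reproduce the phantom
#'   bit-for-bit.
#' @aliases PhantomSpec
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(gridShape = "integer", voxelSizeMM = "numeric",
                   tissueGeometry = "list", tissueMeans = "numeric",
                   noiseSD = "numeric", biasAmplitude = "numeric",
                   biasOrder = "integer", rngSeed = "integer"),
    validity = function(object) {
        msg <- NULL
        if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
            msg <- c(msg, "gridShape must be 3 integers >= 4")
        if (length(object@voxelSizeMM) != 3L || any(object@voxelSizeMM <= 0))
            msg <- c(msg, "voxelSizeMM must be 3 positive values")
        g <- object@tissueGeometry
        need <- c("brain", "gmOuter", "wmOuter", "csfInner")
        if (!all(need %in% names(g)))
            msg <- c(msg, "tissueGeometry needs brain, gmOuter, wmOuter, csfInner")
        else if (!(g$brain > 0 && g$brain <= 1 && 1 > g$gmOuter &&
                   g$gmOuter > g$wmOuter && g$wmOuter > g$csfInner &&
                   g$csfInner > 0))
            msg <- c(msg, "need 1 > gmOuter > wmOuter > csfInner > 0")
        if (!all(c("csf", "wm", "gm") %in% names(object@tissueMeans)))
            msg <- c(msg, "tissueMeans needs csf, wm, gm")
        if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
        if (object@biasAmplitude < 0)
            msg <- c(msg, "biasAmplitude must be >= 0")
        if (object@biasOrder < 1L) msg <- c(msg, "biasOrder must be >= 1")
        if (is.null(msg)) TRUE else msg
    })

#' @rdname PhantomSpec-class
#' @param grid_shape,voxel_size_mm grid dimensions and voxel size.
#' @param tissue_geometry,tissue_means,noise_sd,bias_amplitude,bias_order,rng_seed
#'   see the class slots.
#' @return a `PhantomSpec`.
#' @examples
#' spec <- phantomSpec(grid_shape = c(48, 48, 9), noise_sd = 0)
#' @export
phantomSpec <- function(grid_shape = c(96L, 96L, 27L),
                        voxel_size_mm = c(0.43, 0.43, 4),
                        tissue_geometry = list(brain = 0.92, gmOuter = 0.97,
                                               wmOuter = 0.80,
                                               csfInner = 0.587),
                        tissue_means = c(csf = 30, wm = 100, gm = 120),
                        noise_sd = 2, bias_amplitude = 0.1,
                        bias_order = 2L, rng_seed = 1L) {
    new("PhantomSpec", gridShape = as.integer(grid_shape),
        voxelSizeMM = as.numeric(voxel_size_mm),
        tissueGeometry = tissue_geometry, tissueMeans = tissue_means,
        noiseSD = noise_sd, biasAmplitude = bias_amplitude,
        biasOrder = as.integer(bias_order), rngSeed = as.integer(rng_seed))
}

#' LesionSpec: white matter lesions with controllable texture
#'
#' Lesions are spheres (in mm) clipped to the WM shell, centred at given
#' or randomly sampled WM voxels, with a constant intensity offset above
#' the WM mean plus an optional spatially correlated Gaussian random
#' field (white noise smoothed with an isotropic kernel of width
#' `correlationLengthMM`, rescaled to SD `heterogeneity` within the
#' lesion). `heterogeneity = 0` gives internally constant lesions before
#' noise and bias.
#'
#' An optional textured penumbra can be added: a spatially correlated
#' field of SD `penumbraHeterogeneity` confined to the in-plane shell of
#' WM within `penumbraExtentMM` of the lesion boundary (measured with
#' the same per-slice Euclidean distance used by [buildLayers()]). The
#' default of 0 disables it; it exists so that cohorts can carry
#' peri-lesion texture signal confined to the first few layers.
#'
#' @slot nLesions nonnegative integer.
#' @slot centers n x 3 voxel-coordinate matrix, or 0-row matrix to
#'   sample centers uniformly from WM.
#' @slot radiiMM lesion radii in mm (recycled).
#' @slot intensityOffset added to the WM mean inside lesions.
#' @slot heterogeneity SD of the within-lesion correlated field.
#' @slot correlationLengthMM kernel width of that field, mm.
#' @slot penumbraHeterogeneity,penumbraExtentMM,penumbraCorrelationLengthMM
#'   peri-lesion field parameters (see above).
#' @aliases LesionSpec
#' @exportClass LesionSpec
setClass("LesionSpec",
    representation(nLesions = "integer", centers = "matrix",
                   radiiMM = "numeric", intensityOffset = "numeric",
                   heterogeneity = "numeric", correlationLengthMM = "numeric",
                   penumbraHeterogeneity = "numeric",
                   penumbraExtentMM = "numeric",
                   penumbraCorrelationLengthMM = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (object@nLesions < 0L) msg <- c(msg, "nLesions must be >= 0")
        if (nrow(object@centers) > 0 && ncol(object@centers) != 3L)
            msg <- c(msg, "centers must be an n x 3 matrix")
        if (!anyNA(object@radiiMM) && any(object@radiiMM <= 0))
            msg <- c(msg, "radii must be positive")  # NA = draw at generation
        if (object@intensityOffset <= 0)
            msg <- c(msg, "intensityOffset must be positive")
        if (object@heterogeneity < 0 || object@penumbraHeterogeneity < 0)
            msg <- c(msg, "heterogeneity terms must be >= 0")
        if (object@correlationLengthMM <= 0 ||
            object@penumbraCorrelationLengthMM <= 0)
            msg <- c(msg, "correlation lengths must be positive")
        if (is.null(msg)) TRUE else msg
    })

#' @rdname LesionSpec-class
#' @param n_lesions,centers,radii_mm,intensity_offset,heterogeneity,correlation_length_mm
#'   see the class slots.
#' @param penumbra_heterogeneity,penumbra_extent_mm,penumbra_correlation_length_mm
#'   peri-lesion field parameters.
#' @return a `LesionSpec`.
#' @export
lesionSpec <- function(n_lesions = 4L, centers = NULL, radii_mm = NULL,
                       intensity_offset = 40, heterogeneity = 4,
                       correlation_length_mm = 1,
                       penumbra_heterogeneity = 0,
                       penumbra_extent_mm = 2.58,
                       penumbra_correlation_length_mm = 1) {
    if (is.null(centers)) centers <- matrix(numeric(0), 0, 3)
    if (is.null(radii_mm)) radii_mm <- NA_real_
    new("LesionSpec", nLesions = as.integer(n_lesions),
        centers = as.matrix(centers), radiiMM = as.numeric(radii_mm),
        intensityOffset = intensity_offset, heterogeneity = heterogeneity,
        correlationLengthMM = correlation_length_mm,
        penumbraHeterogeneity = penumbra_heterogeneity,
        penumbraExtentMM = penumbra_extent_mm,
        penumbraCorrelationLengthMM = penumbra_correlation_length_mm)
}

#' CohortSpec: a multi-subject synthetic cohort with planted effects
#'
#' Covariate distributions default to the composition of a midlife
#' cognitively healthy cohort (age 51.9 +/- 5.4 y, 69.9% female,
#' education 16.0 +/- 3.4 y, dementia risk score 5.8 +/- 2.9, eTIV
#' 1485.1 +/- 150.2 cm^3, reaction time centred at 341 ms, vascular
#' risk-factor prevalences 2% / 5% / 14.2%). Lesion load (count, radii)
#' and lesion heterogeneity vary across subjects within
#' `lesion_params` ranges.
#'
#' `effect_map` plants linear covariate-texture-outcome associations:
#' each element is `list(feature =, outcome =, slope =)` where `feature`
#' names a ground-truth texture feature the pipeline computes (e.g.
#' `"WMHT_mean"`, `"layer2_contrast"`), `outcome` is
#' `"reaction_time_ms"` or `"risk_score"`, and `slope` is in outcome
#' units per SD of the ground-truth feature. The realized raw-scale
#' slope (slope divided by the cohort SD of the ground-truth feature) is
#' recorded in the generated effects table.
#'
#' @slot nSubjects positive integer (>= 3; regressions need residual
#'   degrees of freedom).
#' @slot covariates named list of distribution parameters.
#' @slot lesionParams named list of per-subject lesion parameter ranges.
#' @slot effectMap list of planted (feature, outcome, slope) triples.
#' @slot outcomeNoiseSD residual SD of generated outcomes.
#' @slot rngSeed integer seed; the whole cohort is reproducible
#'   bit-for-bit.
#' @aliases CohortSpec
#' @exportClass CohortSpec
setClass("CohortSpec",
    representation(nSubjects = "integer", covariates = "list",
                   lesionParams = "list", effectMap = "list",
                   outcomeNoiseSD = "numeric", rngSeed = "integer"),
    validity = function(object) {
        msg <- NULL
        if (object@nSubjects < 3L)
            msg <- c(msg, "nSubjects must be >= 3 (regressions need residual df)")
        if (object@outcomeNoiseSD <= 0)
            msg <- c(msg, "outcomeNoiseSD must be positive")
        for (e in object@effectMap)
            if (!all(c("feature", "outcome", "slope") %in% names(e)))
                msg <- c(msg, "each effect needs feature, outcome, slope")
        if (is.null(msg)) TRUE else msg
    })

#' @rdname CohortSpec-class
#' @param n_subjects,covariates,lesion_params,effect_map,outcome_noise_sd,rng_seed
#'   see the class slots; values supplied in `covariates`/`lesion_params`
#'   override the listed defaults element-wise.
#' @return a `CohortSpec`.
#' @export
cohortSpec <- function(n_subjects = 50L,
                       covariates = list(),
                       lesion_params = list(),
                       effect_map = list(list(feature = "WMHT_mean",
                                              outcome = "reaction_time_ms",
                                              slope = -25)),
                       outcome_noise_sd = 25,
                       rng_seed = 1L) {
    cov_def <- list(age_mean = 51.9, age_sd = 5.4, female_prop = 0.699,
                    education_mean = 16.0, education_sd = 3.4,
                    risk_mean = 5.8, risk_sd = 2.9,
                    etiv_mean_mm3 = 1485100, etiv_sd_mm3 = 150200,
                    rt_mean_ms = 341,
                    diabetes_prop = 0.02, smoking_prop = 0.05,
                    hypertension_prop = 0.142)
    les_def <- list(n_lesions_mean = 4, radii_range_mm = c(2.5, 5.5),
                    offset_range = c(35, 50), heterogeneity_range = c(3, 5),
                    penumbra_range = c(0, 0), correlation_length_mm = 1,
                    penumbra_extent_mm = 2.58,
                    centers = NULL)  # fixed voxel centers: same lesion
                                     # geometry for every subject
    cov_def[names(covariates)] <- covariates
    les_def[names(lesion_params)] <- lesion_params
    new("CohortSpec", nSubjects = as.integer(n_subjects),
        covariates = cov_def, lesionParams = les_def,
        effectMap = effect_map, outcomeNoiseSD = outcome_noise_sd,
        rngSeed = as.integer(rng_seed))
}

# ---- internal field helpers ------------------------------------------

# Separable Gaussian smoothing of a 3D array, sigma in voxels per axis.
.gaussSmooth3d <- function(arr, sigma) {
    d <- dim(arr)
    for (ax in 1:3) {
        s <- sigma[ax]
        if (s < 0.15) next
        K <- max(1L, ceiling(3 * s))
        w <- exp(-(-K:K)^2 / (2 * s^2))
        w <- w / sum(w)
        out <- array(0, d)
        for (k in -K:K) {
            src <- pmin(pmax(seq_len(d[ax]) + k, 1L), d[ax])  # replicate edges
            idx <- switch(ax,
                `1` = arr[src, , , drop = FALSE],
                `2` = arr[, src, , drop = FALSE],
                `3` = arr[, , src, drop = FALSE])
            out <- out + w[k + K + 1] * idx
        }
        arr <- out
    }
    arr
}

# Correlated zero-mean field with target SD over the voxels of `where`.
.correlatedField <- function(dims, sigma_vox, sd_target, where) {
    f <- .gaussSmooth3d(array(stats::rnorm(prod(dims)), dims), sigma_vox)
    v <- f[where]
    if (length(v) < 2L || stats::sd(v) == 0) return(array(0, dims))
    (f - mean(v)) / stats::sd(v) * sd_target
}

# Random polynomial log-bias field over the brain, scaled so the
# multiplicative field spans a factor of (1 + amplitude) in-brain.
.randomBiasField <- function(dims, brain, degree, amplitude) {
    if (amplitude <= 0) return(array(1, dims))
    X <- .polyBasis(dims, degree)
    beta <- stats::rnorm(ncol(X))
    beta[1] <- 0
    g <- array(as.vector(X %*% beta), dims)
    gb <- g[brain > 0]
    rng <- max(gb) - min(gb)
    if (rng == 0) return(array(1, dims))
    g <- g * (log1p(amplitude) / rng)
    g <- g - mean(g[brain > 0])
    array(exp(g), dims)
}

# Polynomial design matrix in scaled voxel coordinates ([-1, 1] per axis),
# all monomials x^a y^b z^c with a + b + c <= degree.
.polyBasis <- function(dims, degree, subset = NULL) {
    cx <- (seq_len(dims[1]) - (dims[1] + 1) / 2) / (dims[1] / 2)
    cy <- (seq_len(dims[2]) - (dims[2] + 1) / 2) / (dims[2] / 2)
    cz <- (seq_len(dims[3]) - (dims[3] + 1) / 2) / (dims[3] / 2)
    g <- expand.grid(x = cx, y = cy, z = cz)
    if (!is.null(subset)) g <- g[subset, , drop = FALSE]
    cols <- list()
    for (a in 0:degree) for (b in 0:(degree - a)) for (ci in 0:(degree - a - b))
        cols[[length(cols) + 1L]] <- g$x^a * g$y^b * g$z^ci
    do.call(cbind, cols)
}

.ellipsoidU <- function(dims, brainFrac) {
    ctr <- (dims + 1) / 2
    semi <- brainFrac * (dims - 1) / 2
    x2 <- ((seq_len(dims[1]) - ctr[1]) / semi[1])^2
    y2 <- ((seq_len(dims[2]) - ctr[2]) / semi[2])^2
    z2 <- ((seq_len(dims[3]) - ctr[3]) / semi[3])^2
    outer(outer(x2, y2, `+`), z2, `+`)
}

# Per-slice in-plane Euclidean distance (voxels) to a binary mask.
.sliceDistance <- function(mask) {
    d <- dim(mask)
    out <- array(Inf, d)
    for (z in seq_len(d[3])) {
        sl <- matrix(as.integer(mask[, , z]), d[1], d[2])
        out[, , z] <- sqrt(cpp_sedt2d(sl))
    }
    out
}

# ---- phantom generation ----------------------------------------------

#' Generate a synthetic FLAIR phantom with ground-truth masks
#'
#' Builds the tissue geometry of `spec`, adds the lesions of `lesions`,
#' multiplies by a smooth polynomial bias field and adds Gaussian noise.
#' Background (non-brain) voxels are exactly zero. The noise-free,
#' bias-free image and the bias field itself are returned alongside as
#' ground truth.
#'
#' @param spec a [PhantomSpec-class].
#' @param lesions a [LesionSpec-class].
#' @return a list with elements `image` (the observed [ImageVolume-class]),
#'   `clean` (noise-free, unbiased counterpart), `biasField`
#'   (ImageVolume; 1 outside the brain is not enforced, the field is a
#'   smooth volume), and `masks`, a named list of ground-truth
#'   [MaskVolume-class] objects: `brain`, `WM`, `GM`, `CSF`, `WMH`.
#' @examples
#' ph <- generatePhantom(phantomSpec(grid_shape = c(48, 48, 9)),
#'                       lesionSpec(n_lesions = 2))
#' sum(maskData(ph$masks$WMH))
#' @export
generatePhantom <- function(spec, lesions = lesionSpec()) {
    stopifnot(is(spec, "PhantomSpec"), is(lesions, "LesionSpec"))
    methods::validObject(spec); methods::validObject(lesions)
    d <- spec@gridShape
    vox <- spec@voxelSizeMM
    geom <- spec@tissueGeometry
    u <- .ellipsoidU(d, geom$brain)
    brain <- u <= 1
    wm  <- u <= geom$wmOuter^2 & u > geom$csfInner^2
    gm  <- u <= geom$gmOuter^2 & u > geom$wmOuter^2
    csf <- brain & !wm & !gm

    .withSeed(spec@rngSeed, {
        tm <- spec@tissueMeans
        clean <- array(0, d)
        clean[csf] <- tm[["csf"]]
        clean[wm]  <- tm[["wm"]]
        clean[gm]  <- tm[["gm"]]

        wmh <- array(FALSE, d)
        if (lesions@nLesions > 0L) {
            wmIdx <- which(wm)
            centers <- lesions@centers
            if (nrow(centers) == 0L) {
                pick <- sample(wmIdx, lesions@nLesions)
                centers <- arrayInd(pick, d)
            } else {
                for (i in seq_len(nrow(centers))) {
                    ci <- centers[i, ]
                    if (!wm[ci[1], ci[2], ci[3]])
                        stop(sprintf(
                            "lesion %d center (%s) lies outside the WM region",
                            i, paste(ci, collapse = ", ")))
                }
            }
            radii <- lesions@radiiMM
            if (anyNA(radii)) radii <- stats::runif(lesions@nLesions,
                                                    2.5, 5.5)  # default draw
            radii <- rep_len(radii, lesions@nLesions)
            sig_vox <- lesions@correlationLengthMM / vox
            for (i in seq_len(lesions@nLesions)) {
                ci <- centers[i, ]
                r <- radii[i]
                rv <- ceiling(r / vox)
                xs <- max(1, ci[1] - rv[1]):min(d[1], ci[1] + rv[1])
                ys <- max(1, ci[2] - rv[2]):min(d[2], ci[2] + rv[2])
                zs <- max(1, ci[3] - rv[3]):min(d[3], ci[3] + rv[3])
                box <- c(length(xs), length(ys), length(zs))
                dx2 <- ((xs - ci[1]) * vox[1])^2
                dy2 <- ((ys - ci[2]) * vox[2])^2
                dz2 <- ((zs - ci[3]) * vox[3])^2
                inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
                inside <- inside & wm[xs, ys, zs]
                if (!any(inside)) next
                les <- array(0, box)
                les[inside] <- lesions@intensityOffset
                if (lesions@heterogeneity > 0 && sum(inside) > 1)
                    les <- les + .correlatedField(box, sig_vox,
                                                  lesions@heterogeneity,
                                                  inside) * inside
                sub <- wmh[xs, ys, zs]
                clean[xs, ys, zs] <- clean[xs, ys, zs] +
                    les * !(sub & inside)  # do not double-add on overlaps
                wmh[xs, ys, zs] <- sub | inside
            }
        }

        if (lesions@penumbraHeterogeneity > 0 && any(wmh)) {
            dist <- .sliceDistance(wmh)
            ext_vox <- lesions@penumbraExtentMM / vox[1]
            shell <- dist > 0 & dist <= ext_vox & wm
            if (any(shell)) {
                sigp <- lesions@penumbraCorrelationLengthMM / vox
                clean <- clean + .correlatedField(d, sigp,
                    lesions@penumbraHeterogeneity, shell) * shell
            }
        }

        bias <- .randomBiasField(d, brain, spec@biasOrder, spec@biasAmplitude)
        img <- clean * bias
        if (spec@noiseSD > 0)
            img <- img + array(stats::rnorm(prod(d), 0, spec@noiseSD), d)
        img[!brain] <- 0
        clean[!brain] <- 0

        list(image = ImageVolume(img, vox),
             clean = ImageVolume(clean, vox),
             biasField = ImageVolume(bias, vox),
             masks = list(
                 brain = MaskVolume(brain, vox, "brain"),
                 WM = MaskVolume(wm, vox, "WM"),
                 GM = MaskVolume(gm, vox, "GM"),
                 CSF = MaskVolume(csf, vox, "CSF"),
                 WMH = MaskVolume(wmh, vox, "WMH")))
    })
}

# ---- cohort generation -----------------------------------------------

#' Generate a synthetic cohort with known texture-outcome effects
#'
#' Draws `cohort@nSubjects` phantoms from `phantom_template` with
#' per-subject lesion load, lesion brightness and lesion heterogeneity,
#' generates covariates, computes ground-truth texture features on each
#' subject's noise-free unbiased image (using the true masks), and
#' builds outcomes that are linear in the designated ground-truth
#' features plus Gaussian noise.
#'
#' @param phantom_template a [PhantomSpec-class]; its `rngSeed` is
#'   replaced per subject.
#' @param cohort a [CohortSpec-class].
#' @param out_dir optional directory; when given, per-subject NIfTI
#'   volumes and masks, `covariates.csv`, `ground_truth.csv`,
#'   `effects.csv` and a JSON parameter sidecar are written there.
#' @param keep_volumes logical; keep the per-subject volumes in the
#'   returned object (set `FALSE` to save memory when only the feature
#'   tables are needed downstream and `out_dir` is used).
#' @return a list: `subjects` (list of [generatePhantom()] results plus
#'   `subject_id`), `covariates` (data.frame, one row per subject),
#'   `ground_truth` (data.frame of ground-truth features per subject),
#'   `effects` (data.frame of planted slopes: per-SD and realized
#'   raw-scale), and `spec` echoing the two input specs.
#' @examples
#' cs <- cohortSpec(n_subjects = 3, rng_seed = 7)
#' co <- generateCohort(phantomSpec(grid_shape = c(48, 48, 9)), cs)
#' nrow(co$ground_truth)
#' @export
generateCohort <- function(phantom_template, cohort, out_dir = NULL,
                           keep_volumes = TRUE) {
    stopifnot(is(phantom_template, "PhantomSpec"), is(cohort, "CohortSpec"))
    methods::validObject(cohort)
    n <- cohort@nSubjects
    cv <- cohort@covariates
    lp <- cohort@lesionParams

    .withSeed(cohort@rngSeed, {
        subj_seed <- sample.int(.Machine$integer.max - 1L, n)
        covars <- data.frame(
            subject_id = sprintf("sub-%03d", seq_len(n)),
            age = round(stats::rnorm(n, cv$age_mean, cv$age_sd), 1),
            sex = stats::rbinom(n, 1, cv$female_prop),  # female = 1
            education_years = round(pmax(8, stats::rnorm(
                n, cv$education_mean, cv$education_sd)), 1),
            risk_score = round(pmin(14, pmax(0, stats::rnorm(
                n, cv$risk_mean, cv$risk_sd))), 1),
            etiv_mm3 = round(pmax(9e5, stats::rnorm(
                n, cv$etiv_mean_mm3, cv$etiv_sd_mm3))),
            diabetes = stats::rbinom(n, 1, cv$diabetes_prop),
            smoking = stats::rbinom(n, 1, cv$smoking_prop),
            hypertension = stats::rbinom(n, 1, cv$hypertension_prop),
            stringsAsFactors = FALSE)

        n_les <- if (!is.null(lp$centers)) rep(nrow(lp$centers), n) else
            pmax(1L, stats::rpois(n, lp$n_lesions_mean))
        offs <- stats::runif(n, lp$offset_range[1], lp$offset_range[2])
        hets <- stats::runif(n, lp$heterogeneity_range[1],
                             lp$heterogeneity_range[2])
        pens <- stats::runif(n, lp$penumbra_range[1], lp$penumbra_range[2])
        rt_noise <- stats::rnorm(n, 0, cohort@outcomeNoiseSD)
        risk_noise <- stats::rnorm(n, 0, 1)

        subjects <- vector("list", n)
        gt_rows <- vector("list", n)
        for (i in seq_len(n)) {
            ps <- phantom_template
            ps@rngSeed <- subj_seed[i]
            ls <- lesionSpec(
                n_lesions = n_les[i],
                centers = lp$centers,
                radii_mm = if (!is.null(lp$centers))
                    rep_len(lp$radii_range_mm[1], n_les[i]) else
                    stats::runif(n_les[i], lp$radii_range_mm[1],
                                 lp$radii_range_mm[2]),
                intensity_offset = offs[i],
                heterogeneity = hets[i],
                correlation_length_mm = lp$correlation_length_mm,
                penumbra_heterogeneity = pens[i],
                penumbra_extent_mm = lp$penumbra_extent_mm)
            ph <- generatePhantom(ps, ls)
            ph$subject_id <- covars$subject_id[i]
            ph$lesion_spec <- ls
            # ground-truth features: clean image, true masks, no bias stage
            gt <- processSubject(ph$clean, ph$masks$brain, ph$masks$WM,
                                 wmh = ph$masks$WMH,
                                 etiv_mm3 = covars$etiv_mm3[i],
                                 params = pipelineParams(skip_bias = TRUE))
            gt_rows[[i]] <- gt$features
            subjects[[i]] <- ph
        }
        gt <- do.call(rbind, gt_rows)
        gt <- cbind(subject_id = covars$subject_id, gt)

        # plant effects: outcome += slope * z(ground-truth feature)
        rt <- cv$rt_mean_ms + rt_noise
        risk_extra <- risk_noise * 0
        eff_rows <- list()
        for (e in cohort@effectMap) {
            if (!e$feature %in% names(gt))
                stop(sprintf(
                    "effect_map references '%s', which the pipeline does not compute",
                    e$feature))
            v <- gt[[e$feature]]
            if (all(is.na(v)))
                stop(sprintf("ground-truth feature '%s' is all-missing",
                             e$feature))
            sdv <- stats::sd(v, na.rm = TRUE)
            z <- if (sdv > 0) (v - mean(v, na.rm = TRUE)) / sdv else v * 0
            z[is.na(z)] <- 0
            contrib <- e$slope * z
            if (e$outcome == "reaction_time_ms") rt <- rt + contrib
            else if (e$outcome == "risk_score") risk_extra <- risk_extra + contrib
            else stop(sprintf("unsupported effect outcome '%s'", e$outcome))
            eff_rows[[length(eff_rows) + 1L]] <- data.frame(
                feature = e$feature, outcome = e$outcome,
                slope_per_sd = e$slope, gt_feature_sd = sdv,
                slope_raw = if (sdv > 0) e$slope / sdv else NA_real_)
        }
        covars$reaction_time_ms <- round(rt, 1)
        if (any(risk_extra != 0))
            covars$risk_score <- round(pmax(0, covars$risk_score + risk_extra), 2)
        effects <- if (length(eff_rows)) do.call(rbind, eff_rows) else
            data.frame(feature = character(), outcome = character(),
                       slope_per_sd = numeric(), gt_feature_sd = numeric(),
                       slope_raw = numeric())

        out <- list(subjects = subjects, covariates = covars,
                    ground_truth = gt, effects = effects,
                    spec = list(phantom = phantom_template, cohort = cohort,
                                subject_seeds = subj_seed))
        if (!is.null(out_dir)) .writeCohort(out, out_dir)
        if (!keep_volumes)
            out$subjects <- lapply(out$subjects, function(s)
                s[c("subject_id", "lesion_spec")])
        out
    })
}

.writeCohort <- function(co, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in co$subjects) {
        sd <- file.path(dir, s$subject_id)
        dir.create(sd, showWarnings = FALSE)
        writeNifti(s$image, file.path(sd, "flair.nii.gz"),
                   datatype = "float32")
        for (m in names(s$masks))
            writeNifti(s$masks[[m]],
                       file.path(sd, sprintf("mask_%s.nii.gz", tolower(m))))
    }
    utils::write.csv(co$covariates, file.path(dir, "covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(co$ground_truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(co$effects, file.path(dir, "effects.csv"),
                     row.names = FALSE)
    ph <- co$spec$phantom
    ch <- co$spec$cohort
    sidecar <- list(
        phantom = list(grid_shape = ph@gridShape,
                       voxel_size_mm = ph@voxelSizeMM,
                       tissue_geometry = ph@tissueGeometry,
                       tissue_means = as.list(ph@tissueMeans),
                       noise_sd = ph@noiseSD,
                       bias_amplitude = ph@biasAmplitude,
                       bias_order = ph@biasOrder),
        cohort = list(n_subjects = ch@nSubjects, covariates = ch@covariates,
                      lesion_params = ch@lesionParams,
                      effect_map = ch@effectMap,
                      outcome_noise_sd = ch@outcomeNoiseSD,
                      rng_seed = ch@rngSeed),
        subject_seeds = co$spec$subject_seeds)
    jsonlite::write_json(sidecar, file.path(dir, "simulation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
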