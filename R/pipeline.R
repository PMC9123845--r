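#' @include AllClasses.R preprocessing.R masks.R texture.R layers.R statistics.R
NULL

#' Pipeline parameter set
#'
#' All tunable parameters of the per-subject pipeline, with the study
#' defaults: 8 grey levels, WMH threshold 1.2 x median, 10 layers at a
#' 2-voxel increment, degree-2 bias polynomial, FDR at 0.05. The list
#' serializes losslessly to JSON and every run writes its resolved
#' parameters beside its outputs.
#'
#' @param levels grey levels N for quantization.
#' @param k WMH threshold multiplier.
#' @param n_layers,increment peri-WMH layer geometry (voxels).
#' @param bias_degree polynomial degree of the bias estimator.
#' @param skip_bias skip bias correction (for pre-corrected input or
#'   noise-free ground truth).
#' @param min_lesion_voxels minimum WMH component size (1 = off).
#' @param fdr_q FDR level for the model battery.
#' @return a named list.
#' @export
pipelineParams <- function(levels = 8L, k = 1.2, n_layers = 10L,
                           increment = 2L, bias_degree = 2L,
                           skip_bias = FALSE, min_lesion_voxels = 1L,
                           fdr_q = 0.05) {
    list(levels = as.integer(levels), k = k, n_layers = as.integer(n_layers),
         increment = as.integer(increment),
         bias_degree = as.integer(bias_degree), skip_bias = skip_bias,
         min_lesion_voxels = as.integer(min_lesion_voxels), fdr_q = fdr_q)
}

.naFeatures <- function() {
    c(mean = NA_real_, std = NA_real_, contrast = NA_real_,
      energy = NA_real_, entropy = NA_real_, homog = NA_real_)
}

.prefixRow <- function(f, prefix) {
    out <- as.list(as.numeric(f[c("mean", "std", "contrast", "energy",
                                  "entropy", "homog")]))
    names(out) <- paste0(prefix, c("mean", "std", "contrast", "energy",
                                   "entropy", "homog"))
    out
}

#' Process one subject end to end
#'
#' Bias correction, WMH segmentation (skipped when a WMH mask is
#' supplied, e.g. the synthetic ground truth), NAWM construction,
#' intensity normalization, quantization, texture-map generation,
#' ROI and per-layer feature extraction, volume summary and cube-root
#' transformation — one row of the cohort table.
#'
#' @param img FLAIR [ImageVolume-class] (skull-stripped).
#' @param brain,wm brain and WM [MaskVolume-class] inputs.
#' @param wmh optional WMH mask; when NULL it is segmented from `img`.
#' @param etiv_mm3 estimated total intracranial volume (mm^3).
#' @param params a [pipelineParams()] list.
#' @param keep_volumes also return the intermediate volumes (masks,
#'   normalized image, texture maps).
#' @return a list: `features` (one-row data.frame, cube-root
#'   transformed with `_raw` columns retained), and when
#'   `keep_volumes` is TRUE also `wmh`, `nawm`, `layers`, `norm`,
#'   `maps`.
#' @export
processSubject <- function(img, brain, wm, wmh = NULL, etiv_mm3 = 1485100,
                           params = pipelineParams(),
                           keep_volumes = FALSE) {
    stopifnot(is(img, "ImageVolume"))
    if (!params$skip_bias) {
        field <- estimateBiasField(img, brain, params$bias_degree)
        img <- correctBias(img, field)
    }
    if (is.null(wmh))
        wmh <- segmentWMH(img, brain, wm, k = params$k,
                          min_size = params$min_lesion_voxels)
    nawm <- buildNAWM(wm, wmh)
    norm <- normalizeIntensities(img)
    q <- quantizeVolume(norm, brain, N = params$levels)
    maps <- makeTextureMaps(q)

    fWMH <- if (sum(wmh@data) == 0L) .naFeatures() else
        suppressWarnings(extractRoiFeatures(norm, maps, wmh))
    fNAWM <- if (sum(nawm@data) == 0L) .naFeatures() else
        suppressWarnings(extractRoiFeatures(norm, maps, nawm))

    lset <- buildLayers(wmh, wm, n_layers = params$n_layers,
                        increment = params$increment)
    lf <- extractLayerFeatures(norm, maps, lset)

    vols <- summarizeVolumes(wmh, etiv_mm3)
    row <- c(.prefixRow(fWMH, "WMHT_"), .prefixRow(fNAWM, "NAWMT_"))
    for (k in seq_len(nrow(lf)))
        row <- c(row, .prefixRow(unlist(lf[k, ]), sprintf("layer%d_", k)))
    row <- as.data.frame(row)
    row <- transformFeatures(row)
    row$wmh_volume_mm3 <- vols$wmh_volume_mm3
    row$wmh_pct_eTIV <- vols$wmh_pct_eTIV
    row$wmh_pct_eTIV_cuberoot <- vols$wmh_pct_eTIV_cuberoot
    row$n_wmh_voxels <- sum(wmh@data)
    out <- list(features = row)
    if (keep_volumes)
        out <- c(out, list(wmh = wmh, nawm = nawm, layers = lset,
                           norm = norm, maps = maps))
    out
}

#' Assemble the cohort feature table from a synthetic cohort
#'
#' Runs [processSubject()] on every subject's observed image (with the
#' ground-truth brain and WM masks as inputs, segmenting WMH from the
#' image) and joins the covariate table. One row per subject; no
#' duplicated subject ids.
#'
#' @param cohort output of [generateCohort()] (with volumes kept).
#' @param params a [pipelineParams()] list.
#' @param use_true_wmh use the ground-truth WMH masks instead of
#'   segmenting (default FALSE).
#' @return a data.frame (the cohort table consumed by
#'   [runModelBattery()]).
#' @export
buildCohortTable <- function(cohort, params = pipelineParams(),
                             use_true_wmh = FALSE) {
    subs <- cohort$subjects
    cov <- cohort$covariates
    rows <- vector("list", length(subs))
    for (i in seq_along(subs)) {
        s <- subs[[i]]
        if (is.null(s$image))
            stop("cohort was generated with keep_volumes = FALSE")
        ps <- processSubject(s$image, s$masks$brain, s$masks$WM,
                             wmh = if (use_true_wmh) s$masks$WMH else NULL,
                             etiv_mm3 = cov$etiv_mm3[i], params = params)
        rows[[i]] <- cbind(subject_id = s$subject_id, ps$features)
    }
    feats <- do.call(rbind, rows)
    if (anyDuplicated(feats$subject_id))
        stop("duplicated subject_id in cohort")
    merge(cov, feats, by = "subject_id", sort = FALSE)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate -> preprocess/segment/texture/layers/extract
#' -> statistics. The configuration is a named list (or path to a JSON
#' file): `out_dir` (required), `seed`, `params` (overrides for
#' [pipelineParams()]), and either `simulate` (a list with
#' `n_subjects`, `grid_shape`, optional `effect_map`,
#' `lesion_params`, `covariates`, `noise_sd`, `bias_amplitude`) or
#' `input_dir` pointing at a directory laid out like the one
#' [generateCohort()] writes (per-subject `flair.nii.gz` +
#' `mask_*.nii.gz`, `covariates.csv`).
#'
#' Per-subject feature rows are cached under `out_dir/features/`; a
#' re-run recomputes only subjects whose cache is missing. A failing
#' subject is recorded and the run continues; the manifest reports
#' per-subject status and `any_failed`.
#'
#' @param config list or JSON path.
#' @return the run manifest (list): resolved config, per-subject
#'   status, output checksums, and the paths of `features.csv` /
#'   `results.csv`.
#' @export
runPipeline <- function(config) {
    if (is.character(config))
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.null(config$out_dir)) stop("config needs out_dir")
    out_dir <- config$out_dir
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    params <- do.call(pipelineParams, config$params %||% list())
    seed <- as.integer(config$seed %||% 1L)

    status <- list()
    if (!is.null(config$simulate)) {
        sim <- config$simulate
        ph <- phantomSpec(
            grid_shape = sim$grid_shape %||% c(96L, 96L, 27L),
            noise_sd = sim$noise_sd %||% 2,
            bias_amplitude = sim$bias_amplitude %||% 0.1,
            rng_seed = seed)
        co <- cohortSpec(
            n_subjects = sim$n_subjects %||% 10L,
            effect_map = sim$effect_map %||%
                list(list(feature = "WMHT_mean",
                          outcome = "reaction_time_ms", slope = -25)),
            lesion_params = sim$lesion_params %||% list(),
            covariates = sim$covariates %||% list(),
            rng_seed = seed)
        cohort <- generateCohort(ph, co)
        cov <- cohort$covariates
        subjects <- cohort$subjects
        utils::write.csv(cov, file.path(out_dir, "covariates.csv"),
                         row.names = FALSE)
        utils::write.csv(cohort$effects, file.path(out_dir, "effects.csv"),
                         row.names = FALSE)
    } else if (!is.null(config$input_dir)) {
        cov <- utils::read.csv(file.path(config$input_dir, "covariates.csv"),
                               stringsAsFactors = FALSE)
        subjects <- lapply(seq_len(nrow(cov)), function(i) {
            sd <- file.path(config$input_dir, cov$subject_id[i])
            list(subject_id = cov$subject_id[i], dir = sd)
        })
    } else stop("config needs either simulate or input_dir")

    fdir <- file.path(out_dir, "features")
    dir.create(fdir, showWarnings = FALSE)
    rows <- list()
    for (i in seq_along(subjects)) {
        s <- subjects[[i]]
        id <- s$subject_id
        cache <- file.path(fdir, paste0(id, ".rds"))
        if (file.exists(cache)) {
            # RDS keeps doubles bit-exact, so a resumed run reproduces
            # byte-identical features.csv output
            rows[[id]] <- readRDS(cache)
            status[[id]] <- "cached"
            next
        }
        res <- tryCatch({
            if (!is.null(s$dir)) {
                img <- readNifti(file.path(s$dir, "flair.nii.gz"))
                brain <- readMask(file.path(s$dir, "mask_brain.nii.gz"),
                                  "brain", reference = img,
                                  reference_path = file.path(s$dir,
                                                             "flair.nii.gz"))
                wm <- readMask(file.path(s$dir, "mask_wm.nii.gz"), "WM",
                               reference = img)
            } else {
                img <- s$image; brain <- s$masks$brain; wm <- s$masks$WM
            }
            ps <- processSubject(img, brain, wm, wmh = NULL,
                                 etiv_mm3 = cov$etiv_mm3[i],
                                 params = params)
            cbind(subject_id = id, ps$features)
        }, error = function(e) e)
        if (inherits(res, "error")) {
            status[[id]] <- paste("failed:", conditionMessage(res))
        } else {
            saveRDS(res, cache)
            rows[[id]] <- res
            status[[id]] <- "ok"
        }
    }
    any_failed <- any(grepl("^failed", unlist(status)))
    if (!length(rows)) stop("no subject completed")

    feats <- do.call(rbind, rows)
    table <- merge(cov, feats, by = "subject_id", sort = FALSE)
    fpath <- file.path(out_dir, "features.csv")
    utils::write.csv(table, fpath, row.names = FALSE)

    models <- tryCatch(runModelBattery(table, q = params$fdr_q,
                                      n_layers = params$n_layers),
                       error = function(e) e)
    rpath <- NULL
    if (!inherits(models, "error")) {
        rpath <- file.path(out_dir, "results.csv")
        utils::write.csv(models$tidy, rpath, row.names = FALSE)
    }

    manifest <- list(
        package_version = as.character(utils::packageVersion("wmhtexture")),
        seed = seed, params = params,
        subjects = status, any_failed = any_failed,
        stats_error = if (inherits(models, "error"))
            conditionMessage(models) else NULL,
        checksums = as.list(tools::md5sum(c(fpath, rpath))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(manifest, list(features = fpath, results = rpath,
                               table = table,
                               models = if (!inherits(models, "error"))
                                   models else NULL)))
}
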