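#' @include AllClasses.R
NULL

.F6 <- c("mean", "std", "contrast", "energy", "entropy", "homog")

#' Paired comparison of WMH vs NAWM texture
#'
#' Two-sided paired t-test between the WMH and NAWM value of one
#' textural feature, subjects with a missing member dropped pairwise.
#' Zero within-pair variance is reported as a degenerate result (all
#' differences zero: t = 0, p = 1; constant nonzero difference:
#' `degenerate = TRUE` with missing t/p) instead of erroring.
#'
#' @param table cohort data.frame (one row per subject).
#' @param feature feature base name (`"mean"`, `"std"`, `"contrast"`,
#'   `"energy"`, `"entropy"`, `"homog"`), or give full column names via
#'   `x`/`y`.
#' @param x,y explicit column names overriding the
#'   `WMHT_`/`NAWMT_` prefixes.
#' @return a list: `feature`, `n`, `mean_diff`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
pairedCompare <- function(table, feature, x = NULL, y = NULL) {
    x <- x %||% paste0("WMHT_", feature)
    y <- y %||% paste0("NAWMT_", feature)
    if (!all(c(x, y) %in% names(table)))
        stop(sprintf("columns %s / %s not found", x, y))
    dd <- table[[x]] - table[[y]]
    dd <- dd[!is.na(dd)]
    n <- length(dd)
    if (n < 3L) stop("need at least 3 complete pairs")
    md <- mean(dd)
    s <- stats::sd(dd)
    # relative guard: a constant difference vector has sd at rounding
    # level, not exactly 0
    if (s <= 1e-12 * max(abs(dd), 1)) {
        if (md == 0)
            return(list(feature = feature, n = n, mean_diff = 0, t = 0,
                        df = n - 1L, p = 1, degenerate = FALSE))
        return(list(feature = feature, n = n, mean_diff = md, t = NA_real_,
                    df = n - 1L, p = NA_real_, degenerate = TRUE))
    }
    t <- md / (s / sqrt(n))
    list(feature = feature, n = n, mean_diff = md, t = t, df = n - 1L,
         p = 2 * stats::pt(-abs(t), n - 1L), degenerate = FALSE)
}

.isBinaryCol <- function(v) {
    u <- unique(v[!is.na(v)])
    length(u) <= 2L
}

# OLS with mean-centred continuous predictors; listwise deletion.
.fitCentred <- function(table, outcome, rhs_terms, center_cols,
                        product = NULL) {
    cols <- unique(c(outcome, rhs_terms))
    if (!all(cols %in% names(table)))
        stop(sprintf("missing required columns: %s",
                     paste(setdiff(cols, names(table)), collapse = ", ")))
    df <- table[, cols, drop = FALSE]
    df <- df[stats::complete.cases(df), , drop = FALSE]
    n <- nrow(df)
    for (cn in intersect(center_cols, names(df)))
        if (!.isBinaryCol(df[[cn]]))
            df[[cn]] <- df[[cn]] - mean(df[[cn]])
    if (!is.null(product)) {
        # centre both factors (binary included) before forming the product
        a <- df[[product[1]]] - mean(df[[product[1]]])
        b <- df[[product[2]]] - mean(df[[product[2]]])
        df[[product[1]]] <- a
        df[[product[2]]] <- b
        df[["interaction"]] <- a * b
        rhs_terms <- c(rhs_terms, "interaction")
    }
    k <- length(rhs_terms)
    if (n <= k + 2L)
        stop(sprintf("too few complete cases (n = %d) for %d terms", n, k))
    fml <- stats::as.formula(paste(outcome, "~",
                                   paste(rhs_terms, collapse = " + ")))
    fit <- stats::lm(fml, data = df)
    if (anyNA(stats::coef(fit)))
        stop(sprintf("rank-deficient design: collinear terms %s",
                     paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                           collapse = ", ")))
    sm <- summary(fit)$coefficients
    terms_df <- data.frame(term = rownames(sm), estimate = sm[, 1],
                           se = sm[, 2], t_value = sm[, 3],
                           p_value = sm[, 4], row.names = NULL,
                           stringsAsFactors = FALSE)
    list(fit = fit, df = df, terms = terms_df, n = n,
         formula = paste(deparse(fml), collapse = ""))
}

#' Covariate-adjusted linear regression
#'
#' Ordinary least squares of `outcome` on `predictor`, adjusting for
#' `covariates` (age and sex by default; sex is coded female = 1).
#' Continuous predictors are mean-centred (which leaves slope t-values
#' unchanged but matches the reporting convention); missingness is
#' handled by listwise deletion with the used n reported.
#'
#' @param table cohort data.frame.
#' @param outcome,predictor column names.
#' @param covariates character vector of adjustment columns.
#' @param extra_covariates optional further covariates (e.g. WMH
#'   volume, diabetes, smoking, hypertension).
#' @return a [ModelResult-class].
#' @export
adjustedRegression <- function(table, outcome, predictor,
                               covariates = c("age", "sex"),
                               extra_covariates = NULL) {
    rhs <- c(predictor, covariates, extra_covariates)
    res <- .fitCentred(table, outcome, rhs, center_cols = rhs)
    new("ModelResult", outcome = outcome, terms = res$terms,
        nUsed = as.integer(res$n), formula = res$formula, extra = list())
}

#' Interaction of WMH volume with texture on an outcome
#'
#' Fits `outcome ~ a + b + a*b + covariates` with `a` and `b`
#' mean-centred before the product is formed, so the interaction t is
#' invariant to location shifts of either factor. A marginal-means
#' grid is attached: predicted outcome at
#' `a, b in {mean - SD, mean, mean + SD}` with covariates at their
#' means — the "high/low texture at high/low lesion burden" view.
#'
#' @param table cohort data.frame.
#' @param outcome outcome column (reaction time, typically).
#' @param a,b the two interacting predictors (e.g. cube-root WMH
#'   volume fraction and one texture feature).
#' @param covariates adjustment columns.
#' @return a [ModelResult-class]; `@extra$marginal_means` holds the
#'   3 x 3 grid.
#' @export
interactionRegression <- function(table, outcome = "reaction_time_ms",
                                  a = "wmh_pct_eTIV_cuberoot", b,
                                  covariates = c("age", "sex")) {
    res <- .fitCentred(table, outcome, c(a, b, covariates),
                       center_cols = covariates, product = c(a, b))
    sda <- stats::sd(res$df[[a]])
    sdb <- stats::sd(res$df[[b]])
    if (sdb == 0 || sda == 0)
        stop("rank-deficient design: an interaction factor is constant")
    grid <- expand.grid(a_level = c(-sda, 0, sda), b_level = c(-sdb, 0, sdb))
    nd <- as.data.frame(lapply(res$df[, c(a, b, covariates), drop = FALSE],
                               function(v) rep(mean(v), nrow(grid))))
    nd[[a]] <- grid$a_level
    nd[[b]] <- grid$b_level
    nd$interaction <- nd[[a]] * nd[[b]]
    grid$predicted <- as.numeric(stats::predict(res$fit, newdata = nd))
    grid$a_label <- rep(c("low", "moderate", "high"), 3)
    grid$b_label <- rep(c("low", "moderate", "high"), each = 3)
    new("ModelResult", outcome = outcome, terms = res$terms,
        nUsed = as.integer(res$n), formula = res$formula,
        extra = list(marginal_means = grid, a = a, b = b))
}

#' Spearman correlation matrix with p-values
#'
#' Pairwise Spearman rank correlations (tie-corrected ranks, pairwise
#' deletion) over a feature subset. Constant columns give NA with a
#' warning.
#'
#' @param table cohort data.frame.
#' @param features character vector of column names.
#' @return a list with matrices `rho`, `p`, and `n`.
#' @export
spearmanMatrix <- function(table, features) {
    if (!all(features %in% names(table)))
        stop(sprintf("missing columns: %s",
                     paste(setdiff(features, names(table)), collapse = ", ")))
    k <- length(features)
    rho <- p <- nmat <- matrix(NA_real_, k, k,
                               dimnames = list(features, features))
    diag(rho) <- 1; diag(p) <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
        if (j <= i) next
        x <- table[[features[i]]]; y <- table[[features[j]]]
        ok <- !is.na(x) & !is.na(y)
        nmat[i, j] <- nmat[j, i] <- sum(ok)
        if (sum(ok) < 3L) next
        if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
            warning(sprintf("constant column in pair (%s, %s): rho undefined",
                            features[i], features[j]))
            next
        }
        ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                               method = "spearman",
                                               exact = FALSE))
        rho[i, j] <- rho[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
    }
    list(rho = rho, p = p, n = nmat)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, applied
#' within one model family at a time (the families are defined by the
#' analysis batteries, not pooled across them).
#'
#' @param p_values numeric p-values in \[0, 1\] (NA allowed and
#'   propagated).
#' @param q FDR level for the rejection flags, default 0.05.
#' @return a list: `p_fdr` (adjusted p-values), `reject` (logical),
#'   `q`.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))$p_fdr
#' @export
fdrAdjust <- function(p_values, q = 0.05) {
    p <- as.numeric(p_values)
    if (any(!is.na(p) & (p < 0 | p > 1)))
        stop("p values must lie in [0, 1]")
    adj <- stats::p.adjust(p, method = "BH")
    list(p_fdr = adj, reject = !is.na(adj) & adj <= q, q = q)
}

# one battery of single-predictor adjusted regressions -> tidy rows for
# the predictor term, FDR-adjusted within the battery
.battery <- function(table, outcome, predictors, covariates, q,
                     family) {
    rows <- lapply(predictors, function(pr) {
        mr <- tryCatch(
            adjustedRegression(table, outcome, pr, covariates),
            error = function(e) NULL)
        if (is.null(mr))
            return(data.frame(family = family, outcome = outcome,
                              predictor = pr, estimate = NA_real_,
                              se = NA_real_, t_value = NA_real_,
                              p_value = NA_real_, n = NA_integer_,
                              stringsAsFactors = FALSE))
        tr <- mr@terms[mr@terms$term == pr, ]
        data.frame(family = family, outcome = outcome, predictor = pr,
                   estimate = tr$estimate, se = tr$se,
                   t_value = tr$t_value, p_value = tr$p_value,
                   n = mr@nUsed, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    fa <- fdrAdjust(out$p_value, q)
    out$p_fdr <- fa$p_fdr
    out$significant_fdr <- fa$reject
    out
}

#' Per-layer regression battery for one association
#'
#' Re-runs one texture-outcome association over the 11 regions of
#' interest — the WMH itself plus the 10 peri-WMH layers — with FDR
#' applied over the 11 p-values (one association at a time).
#'
#' @param table cohort data.frame with `WMHT_<feature>` and
#'   `layer<k>_<feature>` columns.
#' @param feature feature base name (e.g. `"mean"`).
#' @param outcome outcome column.
#' @param covariates adjustment columns.
#' @param n_layers number of layers present in the table.
#' @param q FDR level.
#' @return a data.frame with one row per ROI (`roi`, `t_value`,
#'   `p_value`, `p_fdr`, `significant_fdr`, `n`).
#' @export
layerBattery <- function(table, feature, outcome,
                         covariates = c("age", "sex"), n_layers = 10L,
                         q = 0.05) {
    preds <- c(paste0("WMHT_", feature),
               paste0("layer", seq_len(n_layers), "_", feature))
    out <- .battery(table, outcome, preds, covariates, q,
                    family = sprintf("layers:%s->%s", feature, outcome))
    out$roi <- c("WMH", paste0("layer", seq_len(n_layers)))
    out
}

#' Run the full cohort model battery
#'
#' Executes the study's inferential battery on a cohort table:
#' \describe{
#'   \item{wmh_volume}{each of the 12 texture features (6 within WMH,
#'     6 within NAWM) predicting cube-root normalized WMH volume,
#'     adjusted for age and sex; FDR within the 12.}
#'   \item{reaction_time}{the 12 features plus WMH volume predicting
#'     reaction time, adjusted for age and sex; FDR within the 13.}
#'   \item{interaction}{WMH volume x WMH texture interactions on
#'     reaction time (6 models); FDR over the 6 interaction terms.}
#'   \item{risk}{the 12 features predicting the dementia risk score,
#'     adjusted for age and sex; FDR within the 12.}
#'   \item{risk_factors}{each of the 12 features as outcome with sex,
#'     age, education, diabetes, smoking and hypertension as
#'     simultaneous predictors; FDR per predictor across the 12
#'     outcomes.}
#'   \item{layers}{for every FDR-significant WMH-texture association
#'     from the first two batteries, the same model over WMH + 10
#'     layers with FDR over the 11 ROIs.}
#' }
#'
#' @param table cohort data.frame (see [buildCohortTable()]).
#' @param q FDR level, default 0.05.
#' @param n_layers layers available in the table (0 disables the layer
#'   battery).
#' @return a named list of tidy data.frames plus `tidy`, their
#'   row-bound union.
#' @export
runModelBattery <- function(table, q = 0.05, n_layers = 10L) {
    if (!is.data.frame(table) || nrow(table) == 0L)
        stop("empty cohort table")
    feats12 <- c(paste0("WMHT_", .F6), paste0("NAWMT_", .F6))
    required <- c(feats12, "wmh_pct_eTIV_cuberoot", "reaction_time_ms",
                  "age", "sex", "risk_score", "education_years",
                  "diabetes", "smoking", "hypertension")
    miss <- setdiff(required, names(table))
    if (length(miss))
        stop(sprintf("missing required columns: %s",
                     paste(miss, collapse = ", ")))

    volB <- .battery(table, "wmh_pct_eTIV_cuberoot", feats12,
                     c("age", "sex"), q, "wmh_volume")
    rtB <- .battery(table, "reaction_time_ms",
                    c(feats12, "wmh_pct_eTIV_cuberoot"),
                    c("age", "sex"), q, "reaction_time")
    riskB <- .battery(table, "risk_score", feats12, c("age", "sex"), q,
                      "risk")

    intRows <- lapply(paste0("WMHT_", .F6), function(b) {
        mr <- tryCatch(
            interactionRegression(table, "reaction_time_ms",
                                  "wmh_pct_eTIV_cuberoot", b),
            error = function(e) NULL)
        if (is.null(mr))
            return(data.frame(family = "interaction",
                              outcome = "reaction_time_ms", predictor = b,
                              estimate = NA_real_, se = NA_real_,
                              t_value = NA_real_, p_value = NA_real_,
                              n = NA_integer_, stringsAsFactors = FALSE))
        tr <- mr@terms[mr@terms$term == "interaction", ]
        data.frame(family = "interaction", outcome = "reaction_time_ms",
                   predictor = paste0("wmh_volume x ", b),
                   estimate = tr$estimate, se = tr$se, t_value = tr$t_value,
                   p_value = tr$p_value, n = mr@nUsed,
                   stringsAsFactors = FALSE)
    })
    intB <- do.call(rbind, intRows)
    fa <- fdrAdjust(intB$p_value, q)
    intB$p_fdr <- fa$p_fdr
    intB$significant_fdr <- fa$reject

    # risk-factor battery: features as outcomes, simultaneous predictors
    rf_preds <- c("sex", "age", "education_years", "diabetes", "smoking",
                  "hypertension")
    rfRows <- lapply(feats12, function(f) {
        res <- tryCatch(.fitCentred(table, f, rf_preds,
                                    center_cols = rf_preds),
                        error = function(e) NULL)
        if (is.null(res)) return(NULL)
        tr <- res$terms[res$terms$term %in% rf_preds, ]
        data.frame(family = "risk_factors", outcome = f,
                   predictor = tr$term, estimate = tr$estimate, se = tr$se,
                   t_value = tr$t_value, p_value = tr$p_value, n = res$n,
                   stringsAsFactors = FALSE)
    })
    rfB <- do.call(rbind, rfRows)
    if (!is.null(rfB)) {
        rfB$p_fdr <- NA_real_
        rfB$significant_fdr <- NA
        for (pr in rf_preds) {
            sel <- rfB$predictor == pr
            fa <- fdrAdjust(rfB$p_value[sel], q)
            rfB$p_fdr[sel] <- fa$p_fdr
            rfB$significant_fdr[sel] <- fa$reject
        }
    }

    layB <- NULL
    if (n_layers > 0L) {
        sig <- rbind(volB, rtB)
        sig <- sig[sig$significant_fdr %in% TRUE &
                   grepl("^WMHT_", sig$predictor), ]
        if (nrow(sig)) {
            layRows <- lapply(seq_len(nrow(sig)), function(i) {
                layerBattery(table,
                             sub("^WMHT_", "", sig$predictor[i]),
                             sig$outcome[i], n_layers = n_layers, q = q)
            })
            layB <- do.call(rbind, layRows)
        }
    }

    batteries <- list(wmh_volume = volB, reaction_time = rtB,
                      interaction = intB, risk = riskB,
                      risk_factors = rfB, layers = layB)
    tidy <- do.call(rbind, lapply(batteries, function(b)
        if (is.null(b)) NULL else
            b[, c("family", "outcome", "predictor", "estimate", "se",
                  "t_value", "p_value", "p_fdr", "significant_fdr", "n")]))
    rownames(tidy) <- NULL
    c(batteries, list(tidy = tidy))
}
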