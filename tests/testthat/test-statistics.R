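make_table <- function(n = 60, seed = 123) {
    set.seed(seed)
    f6 <- c("mean", "std", "contrast", "energy", "entropy", "homog")
    tab <- data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                      age = rnorm(n, 52, 5), sex = rbinom(n, 1, 0.7),
                      education_years = rnorm(n, 16, 3),
                      risk_score = rnorm(n, 6, 2.5),
                      diabetes = rbinom(n, 1, 0.1),
                      smoking = rbinom(n, 1, 0.1),
                      hypertension = rbinom(n, 1, 0.15),
                      wmh_pct_eTIV_cuberoot = runif(n, 0.2, 0.6),
                      reaction_time_ms = rnorm(n, 341, 35))
    for (p in c("WMHT_", "NAWMT_", paste0("layer", 1:10, "_")))
        for (f in f6) tab[[paste0(p, f)]] <- rnorm(n)
    tab
}

test_that("paired comparison handles identical, degenerate and ordinary input", {
    tab <- make_table()
    tab$NAWMT_mean <- tab$WMHT_mean
    r <- pairedCompare(tab, "mean")
    expect_equal(r$t, 0); expect_equal(r$p, 1)

    tab$NAWMT_std <- tab$WMHT_std - 3   # constant nonzero difference
    r2 <- pairedCompare(tab, "std")
    expect_true(r2$degenerate)
    expect_true(is.na(r2$p))

    # agreement with the stock paired t-test on ordinary data
    r3 <- pairedCompare(tab, "contrast")
    ref <- t.test(tab$WMHT_contrast, tab$NAWMT_contrast, paired = TRUE)
    expect_equal(r3$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r3$p, ref$p.value, tolerance = 1e-12)

    # paired t on (x, x + d) is the one-sample t on d
    d <- rnorm(60, 1, 2)
    tab$NAWMT_energy <- tab$WMHT_energy + d
    r4 <- pairedCompare(tab, "energy")
    expect_equal(r4$t, unname(t.test(-d)$statistic), tolerance = 1e-12)

    expect_error(pairedCompare(tab[1:2, ], "mean"), "3 complete pairs")
})

test_that("adjusted regression agrees with a QR reference to 10+ figures", {
    tab <- make_table(n = 80, seed = 5)
    mr <- adjustedRegression(tab, "reaction_time_ms", "WMHT_mean")
    # independent QR solution on the centred design
    X <- cbind(1, scale(tab$WMHT_mean, scale = FALSE),
               scale(tab$age, scale = FALSE), tab$sex)
    y <- tab$reaction_time_ms
    qrX <- qr(X)
    beta <- solve(qr.R(qrX), t(qr.Q(qrX)) %*% y)
    res <- y - X %*% beta
    s2 <- sum(res^2) / (nrow(X) - ncol(X))
    se <- sqrt(diag(s2 * chol2inv(qr.R(qrX))))
    tv <- beta / se
    pv <- 2 * pt(-abs(tv), nrow(X) - ncol(X))
    row <- mr@terms[mr@terms$term == "WMHT_mean", ]
    expect_equal(row$estimate, beta[2], tolerance = 1e-11)
    expect_equal(row$se, se[2], tolerance = 1e-11)
    expect_equal(row$t_value, tv[2], tolerance = 1e-11)
    expect_equal(row$p_value, pv[2], tolerance = 1e-11)
    expect_identical(mr@nUsed, 80L)
})

test_that("regression: perfect fit, centring invariance, rank deficiency, df guard", {
    tab <- make_table(n = 40, seed = 9)
    tab$reaction_time_ms <- 2 * tab$WMHT_mean
    mr <- adjustedRegression(tab, "reaction_time_ms", "WMHT_mean",
                             covariates = NULL)
    row <- mr@terms[mr@terms$term == "WMHT_mean", ]
    expect_equal(row$estimate, 2, tolerance = 1e-10)
    expect_lt(row$p_value, 1e-20)

    # mean-centring leaves slope t-values of an ordinary fit unchanged
    tab2 <- make_table(n = 50, seed = 10)
    mrc <- adjustedRegression(tab2, "reaction_time_ms", "WMHT_contrast")
    raw <- summary(lm(reaction_time_ms ~ WMHT_contrast + age + sex,
                      data = tab2))$coefficients
    expect_equal(mrc@terms$t_value[mrc@terms$term == "WMHT_contrast"],
                 raw["WMHT_contrast", "t value"], tolerance = 1e-12)

    tab2$dup <- tab2$WMHT_contrast
    expect_error(adjustedRegression(tab2, "reaction_time_ms",
                                    "WMHT_contrast",
                                    extra_covariates = "dup"),
                 "rank-deficient")
    expect_error(adjustedRegression(tab2[1:4, ], "reaction_time_ms",
                                    "WMHT_contrast"), "too few")
    # listwise deletion reports the n actually used
    tab2$WMHT_energy[1:5] <- NA
    mrn <- adjustedRegression(tab2, "reaction_time_ms", "WMHT_energy")
    expect_identical(mrn@nUsed, 45L)
})

test_that("interaction model recovers a planted product effect and is shift-invariant", {
    set.seed(11)
    n <- 120
    tab <- make_table(n = n, seed = 11)
    a <- tab$wmh_pct_eTIV_cuberoot
    b <- tab$WMHT_homog
    tab$reaction_time_ms <- 300 +
        5 * (a - mean(a)) * (b - mean(b)) + rnorm(n, 0, 0.05)
    mr <- interactionRegression(tab, "reaction_time_ms",
                                "wmh_pct_eTIV_cuberoot", "WMHT_homog")
    tt <- mr@terms
    expect_gt(abs(tt$t_value[tt$term == "interaction"]), 10)
    expect_lt(abs(tt$t_value[tt$term == "wmh_pct_eTIV_cuberoot"]), 2)
    expect_lt(abs(tt$t_value[tt$term == "WMHT_homog"]), 2)
    mm <- mr@extra$marginal_means
    expect_identical(nrow(mm), 9L)
    expect_true(all(c("low", "moderate", "high") %in% mm$b_label))

    # shifting one factor must not change the interaction t
    tab$WMHT_homog <- tab$WMHT_homog + 100
    mr2 <- interactionRegression(tab, "reaction_time_ms",
                                 "wmh_pct_eTIV_cuberoot", "WMHT_homog")
    expect_equal(mr2@terms$t_value[mr2@terms$term == "interaction"],
                 tt$t_value[tt$term == "interaction"], tolerance = 1e-8)

    tab$flat <- 1
    expect_error(interactionRegression(tab, "reaction_time_ms",
                                       "wmh_pct_eTIV_cuberoot", "flat"),
                 "constant|rank")
})

test_that("Spearman matrix: monotone pairs, constant columns, null behaviour", {
    tab <- make_table(n = 50, seed = 12)
    tab$NAWMT_energy <- exp(tab$WMHT_energy)    # strictly monotone
    sm <- spearmanMatrix(tab, c("WMHT_energy", "NAWMT_energy", "WMHT_std"))
    expect_equal(sm$rho["WMHT_energy", "NAWMT_energy"], 1)
    ref <- cor.test(tab$WMHT_energy, tab$WMHT_std, method = "spearman",
                    exact = FALSE)
    expect_equal(sm$rho["WMHT_energy", "WMHT_std"], unname(ref$estimate))
    expect_equal(sm$p["WMHT_energy", "WMHT_std"], ref$p.value)

    tab$flat <- 1
    expect_warning(sm2 <- spearmanMatrix(tab, c("WMHT_energy", "flat")),
                   "constant")
    expect_true(is.na(sm2$rho["WMHT_energy", "flat"]))

    # independent columns: rejection rate near the nominal level
    set.seed(13)
    hits <- 0L
    for (rep in 1:200) {
        x <- rnorm(50); y <- rnorm(50)
        p <- cor.test(x, y, method = "spearman", exact = FALSE)$p.value
        hits <- hits + (p < 0.05)
    }
    expect_gt(hits / 200, 0.01); expect_lt(hits / 200, 0.12)
})

test_that("BH adjustment: worked example, edge cases, oracle agreement", {
    out <- fdrAdjust(c(0.01, 0.02, 0.03, 0.04))
    expect_equal(out$p_fdr, rep(0.04, 4))
    expect_true(all(out$reject))
    expect_equal(fdrAdjust(0.03)$p_fdr, 0.03)       # m = 1 unchanged
    all1 <- fdrAdjust(rep(1, 5))
    expect_equal(all1$p_fdr, rep(1, 5))
    expect_false(any(all1$reject))
    expect_error(fdrAdjust(c(0.2, 1.4)), "\\[0, 1\\]")

    set.seed(14)
    for (rep in 1:50) {
        p <- runif(sample(1:40, 1))
        expect_equal(fdrAdjust(p)$p_fdr, oracle_bh(p), tolerance = 1e-15)
    }
    # p_fdr >= p always
    p <- runif(30)
    expect_true(all(fdrAdjust(p)$p_fdr >= p))
})

test_that("the model battery has the stated structure and FDR families", {
    tab <- make_table(n = 60, seed = 15)
    # plant one strong association so the layer battery has work to do
    tab$wmh_pct_eTIV_cuberoot <- tab$WMHT_std * 0.2 + rnorm(60, 0, 0.02)
    res <- runModelBattery(tab)
    expect_identical(nrow(res$wmh_volume), 12L)
    expect_identical(nrow(res$reaction_time), 13L)
    expect_identical(nrow(res$interaction), 6L)
    expect_identical(nrow(res$risk), 12L)
    expect_identical(nrow(res$risk_factors), 72L)
    expect_true(all(res$tidy$p_fdr >= res$tidy$p_value - 1e-15, na.rm = TRUE))
    # the planted WMHT_std association is found and propagated to layers
    expect_true(res$wmh_volume$significant_fdr[
        res$wmh_volume$predictor == "WMHT_std"])
    expect_true(!is.null(res$layers))
    expect_identical(nrow(res$layers[res$layers$family ==
        "layers:std->wmh_pct_eTIV_cuberoot", ]), 11L)

    expect_error(runModelBattery(tab[0, ]), "empty cohort")
    expect_error(runModelBattery(tab[, setdiff(names(tab), "risk_score")]),
                 "risk_score")
})
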