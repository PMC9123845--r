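test_that("quantization follows the equal-width binning contract", {
    # values spanning [0, 1]: 0 -> 1, 0.5 -> 5, 1 -> 8
    a <- array(0, c(6, 6, 2))
    br <- array(0, c(6, 6, 2))
    a[1:3, 1, 1] <- c(0, 0.5, 1); br[1:3, 1, 1] <- 1
    q <- quantizeVolume(ImageVolume(a), MaskVolume(br), N = 8)
    expect_identical(q@data[1:3, 1, 1], c(1L, 5L, 8L))
    expect_identical(q@data[br == 0][1], 0L)

    # N = 2 on {1, 2, 3, 4} -> {1, 1, 2, 2}
    b <- array(0, c(6, 6, 2)); b2 <- array(0, c(6, 6, 2))
    b[1:4, 1, 1] <- 1:4; b2[1:4, 1, 1] <- 1
    q2 <- quantizeVolume(ImageVolume(b), MaskVolume(b2), N = 2)
    expect_identical(q2@data[1:4, 1, 1], c(1L, 1L, 2L, 2L))

    # min maps to 1 and max to N for arbitrary input
    set.seed(1)
    r <- array(runif(8 * 8 * 3, 10, 90), c(8, 8, 3))
    brn <- MaskVolume(array(1, c(8, 8, 3)))
    qr <- quantizeVolume(ImageVolume(r), brn, N = 8)
    expect_true(any(qr@data == 1L) && any(qr@data == 8L))
    expect_true(all(qr@data >= 1L & qr@data <= 8L))

    cst <- ImageVolume(array(5, c(8, 8, 3)))
    expect_error(quantizeVolume(cst, brn), "constant")
    expect_error(quantizeVolume(ImageVolume(r), brn, N = 1), "N must be")
})

test_that("quantization is invariant to increasing affine intensity transforms", {
    set.seed(2)
    a <- array(runif(10 * 10 * 2, 20, 120), c(10, 10, 2))
    br <- MaskVolume(array(1, c(10, 10, 2)))
    q1 <- quantizeVolume(ImageVolume(a), br)
    q2 <- quantizeVolume(ImageVolume(2.5 * a + 17), br)
    expect_identical(q1@data, q2@data)
})

test_that("patch GLCM: constant patch concentrates all mass on one diagonal cell", {
    q <- as_quantized(array(3L, c(5, 5, 1)))
    g <- patchGLCM(q, c(3, 3, 1))
    expect_equal(g@table[3, 3], 1)
    expect_equal(sum(g@table), 1)
    f <- haralickFeatures(g)
    expect_equal(unname(f), c(0, 1, 0, 1))
})

test_that("patch GLCM matches exhaustive pair enumeration on the checkerboard patch", {
    # patch rows: 1 2 1 / 2 1 2 / 1 2 1
    m <- array(0L, c(5, 5, 1))
    m[2:4, 2:4, 1] <- matrix(c(1, 2, 1, 2, 1, 2, 1, 2, 1), 3, 3)
    q <- as_quantized(m, N = 2)
    g <- patchGLCM(q, c(3, 3, 1))
    counts <- oracle_patch_glcm(q@data, 3, 3, 1, 2)
    expect_equal(sum(counts), 40)
    expect_equal(g@table, counts / sum(counts))
    # frozen values derived from the enumeration: 12 ordered cross pairs
    # each way, 8 ordered same-level pairs per level
    expect_equal(g@table, matrix(c(0.2, 0.3, 0.3, 0.2), 2, 2))
    f <- haralickFeatures(g)
    expect_equal(f[["contrast"]], 0.6)
    expect_equal(f[["energy"]], 0.26)
    expect_equal(f[["entropy"]], -(0.6 * log(0.3) + 0.4 * log(0.2)))
    expect_equal(f[["homogeneity"]], 0.7)
    expect_equal(unname(f), unname(oracle_haralick(counts)))
})

test_that("heterogeneous patches scatter the GLCM across more cells", {
    hom <- array(4L, c(5, 5, 1))
    het <- hom
    het[2:4, 2:4, 1] <- matrix(c(1, 5, 2, 7, 4, 8, 3, 6, 1), 3, 3)
    n_hom <- sum(patchGLCM(as_quantized(hom), c(3, 3, 1))@table > 0)
    n_het <- sum(patchGLCM(as_quantized(het), c(3, 3, 1))@table > 0)
    expect_gt(n_het, n_hom)
})

test_that("patch GLCM is symmetric and direction-order invariant", {
    set.seed(3)
    q <- as_quantized(array(sample(1:8, 7 * 7 * 2, TRUE), c(7, 7, 2)))
    dirs <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                 c(1L, 1L), c(-1L, -1L), c(1L, -1L), c(-1L, 1L))
    g1 <- patchGLCM(q, c(4, 4, 2))
    g2 <- patchGLCM(q, c(4, 4, 2), directions = rev(dirs))
    expect_identical(g1@table, g2@table)
    expect_equal(g1@table, t(g1@table))
})

test_that("patch GLCM enforces its preconditions", {
    q <- as_quantized(array(1L, c(5, 5, 2)))
    expect_error(patchGLCM(q, c(1, 3, 1)), "full 3x3")
    expect_error(patchGLCM(as_quantized(array(0L, c(5, 5, 1))), c(3, 3, 1)),
                 "no countable")
})

test_that("Haralick features: uniform table closed forms and the energy/entropy degeneracy", {
    N <- 8L
    U <- matrix(1 / N^2, N, N)
    f <- haralickFeatures(U)
    expect_equal(f[["energy"]], 1 / 64)
    expect_equal(f[["entropy"]], log(64))
    # direct-summation oracles for the two distance-weighted features
    con <- sum(outer(1:N, 1:N, function(i, j) (i - j)^2)) / N^2
    hom <- sum(outer(1:N, 1:N, function(i, j) 1 / (1 + abs(i - j)))) / N^2
    expect_equal(f[["contrast"]], con)
    expect_equal(f[["homogeneity"]], hom)

    # same entropy and energy, very different contrast and homogeneity
    P1 <- matrix(0, N, N); P1[1, 2] <- P1[2, 1] <- 0.5
    P2 <- matrix(0, N, N); P2[1, 8] <- P2[8, 1] <- 0.5
    f1 <- haralickFeatures(P1); f2 <- haralickFeatures(P2)
    expect_equal(f1[["entropy"]], f2[["entropy"]])
    expect_equal(f1[["energy"]], f2[["energy"]])
    expect_false(isTRUE(all.equal(f1[["contrast"]], f2[["contrast"]])))
    expect_false(isTRUE(all.equal(f1[["homogeneity"]], f2[["homogeneity"]])))

    expect_error(haralickFeatures(matrix(1, 4, 4)), "unnormalized")
    g <- patchGLCM(as_quantized(array(2L, c(5, 5, 1))), c(3, 3, 1),
                   normalize = FALSE)
    expect_error(haralickFeatures(g), "unnormalized")
})

test_that("texture maps equal the per-voxel patch computation exactly", {
    set.seed(4)
    arr <- array(sample(0:6, 10 * 10 * 2, TRUE, prob = c(2, rep(1, 6))),
                 c(10, 10, 2))
    q <- as_quantized(arr, N = 6)
    tm <- makeTextureMaps(q)
    for (z in 1:2) for (x in 2:9) for (y in 2:9) {
        counts <- oracle_patch_glcm(arr, x, y, z, 6)
        if (sum(counts) == 0) {
            expect_false(validMask(tm)[x, y, z])
            next
        }
        expect_true(validMask(tm)[x, y, z])
        f <- oracle_haralick(counts)
        expect_equal(textureMap(tm, "contrast")[x, y, z], f[["contrast"]])
        expect_equal(textureMap(tm, "energy")[x, y, z], f[["energy"]])
        expect_equal(textureMap(tm, "entropy")[x, y, z], f[["entropy"]])
        expect_equal(textureMap(tm, "homogeneity")[x, y, z],
                     f[["homogeneity"]])
    }
    # slice borders are never valid
    expect_false(any(validMask(tm)[1, , ]))
    expect_false(any(validMask(tm)[, 10, ]))
})

test_that("constant volumes and checkerboards give the expected map patterns", {
    cst <- as_quantized(array(5L, c(8, 8, 2)))
    tm <- makeTextureMaps(cst)
    v <- validMask(tm)
    expect_true(all(textureMap(tm, "contrast")[v] == 0))
    expect_true(all(textureMap(tm, "energy")[v] == 1))
    expect_true(all(textureMap(tm, "entropy")[v] == 0))
    expect_true(all(textureMap(tm, "homogeneity")[v] == 1))

    chk <- array(1L, c(8, 8, 1))
    chk[, , 1] <- (outer(1:8, 1:8, `+`) %% 2) * 4L + 2L
    tmc <- makeTextureMaps(as_quantized(chk))
    vc <- validMask(tmc)
    expect_true(all(textureMap(tmc, "contrast")[vc] > 0))
    expect_true(all(textureMap(tmc, "homogeneity")[vc] < 1))
})

test_that("feature bounds hold at all valid voxels across random volumes", {
    set.seed(5)
    for (rep in 1:5) {
        N <- sample(c(4L, 8L), 1)
        arr <- array(sample(0:N, 12 * 12 * 2, TRUE), c(12, 12, 2))
        tm <- makeTextureMaps(as_quantized(arr, N))
        v <- validMask(tm)
        if (!any(v)) next
        expect_true(all(textureMap(tm, "energy")[v] > 0 &
                        textureMap(tm, "energy")[v] <= 1))
        expect_true(all(textureMap(tm, "homogeneity")[v] > 0 &
                        textureMap(tm, "homogeneity")[v] <= 1))
        expect_true(all(textureMap(tm, "contrast")[v] >= 0 &
                        textureMap(tm, "contrast")[v] <= (N - 1)^2))
        expect_true(all(textureMap(tm, "entropy")[v] >= 0 &
                        textureMap(tm, "entropy")[v] <= 2 * log(N)))
    }
})

test_that("ROI extraction: single voxel, constant lesion, pooled-mean linearity", {
    set.seed(6)
    a <- array(runif(10 * 10 * 3, 0, 1), c(10, 10, 3))
    br <- MaskVolume(array(1, c(10, 10, 3)))
    img <- ImageVolume(a)
    tm <- makeTextureMaps(quantizeVolume(img, br))

    one <- array(0, c(10, 10, 3)); one[5, 5, 2] <- 1
    expect_warning(f1 <- extractRoiFeatures(img, tm, MaskVolume(one)),
                   "single-voxel")
    expect_equal(f1[["mean"]], a[5, 5, 2])
    expect_true(is.na(f1[["std"]]))

    # constant-intensity lesion: zero contrast, full homogeneity
    b <- array(0, c(12, 12, 3)); b[3:10, 3:10, ] <- 30
    b[5:8, 5:8, 2] <- 90
    brn <- MaskVolume(b > 0)
    les <- MaskVolume(array(b == 90, dim(b)))
    imgb <- ImageVolume(b)
    tmb <- makeTextureMaps(quantizeVolume(imgb, brn))
    inner <- array(FALSE, dim(b)); inner[6:7, 6:7, 2] <- TRUE
    fles <- extractRoiFeatures(normalizeIntensities(imgb), tmb,
                               MaskVolume(inner))
    expect_equal(fles[["contrast"]], 0)
    expect_equal(fles[["homog"]], 1)

    # pooled mean = voxel-count-weighted mean of disjoint ROI means
    r1 <- array(FALSE, c(10, 10, 3)); r1[2:4, 2:6, 1] <- TRUE
    r2 <- array(FALSE, c(10, 10, 3)); r2[6:9, 2:3, 3] <- TRUE
    fa <- extractRoiFeatures(img, tm, MaskVolume(r1))
    fb <- extractRoiFeatures(img, tm, MaskVolume(r2))
    fu <- extractRoiFeatures(img, tm, MaskVolume(r1 | r2))
    n1 <- sum(r1); n2 <- sum(r2)
    expect_equal(fu[["mean"]],
                 (n1 * fa[["mean"]] + n2 * fb[["mean"]]) / (n1 + n2))

    expect_warning(fe <- extractRoiFeatures(img, tm,
        MaskVolume(array(0, c(10, 10, 3)))), "empty")
    expect_true(all(is.na(fe)))
})

test_that("cube-root transform: exact cubes, fixed points, raw retention", {
    expect_equal(cubeRoot(0.125), 0.5)
    expect_identical(cubeRoot(0), 0)
    expect_equal(cubeRoot(1), 1)
    expect_equal(cubeRoot(-0.008), -0.2)

    df <- data.frame(WMHT_contrast = 0.125, NAWMT_homog = 1,
                     layer3_energy = 0.027, age = 64)
    tr <- transformFeatures(df)
    expect_equal(tr$WMHT_contrast, 0.5)
    expect_equal(tr$WMHT_contrast_raw, 0.125)
    expect_equal(tr$layer3_energy, 0.3)
    expect_identical(tr$age, 64)         # covariates untouched
    expect_false("age_raw" %in% names(tr))
})
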