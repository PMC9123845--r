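separable_phantom <- function(seed = 41L, noise_sd = 0) {
    generatePhantom(tiny_spec(noise_sd = noise_sd, bias_amplitude = 0,
                              seed = seed),
                    lesionSpec(n_lesions = 2, radii_mm = 3,
                               intensity_offset = 40, heterogeneity = 0))
}

test_that("threshold segmentation recovers separable lesions exactly", {
    ph <- separable_phantom()
    # threshold must land between GM (120, excluded by the strict >) and
    # the lesion intensity (140) for exact recovery; noise-free median
    # is exactly the WM mean, so thr = 120.0 on the boundary
    inb <- imgData(ph$image)[maskData(ph$masks$brain) > 0]
    thr <- 1.2 * median(inb[inb != 0])
    expect_gte(thr, 120); expect_lt(thr, 140)
    seg <- segmentWMH(ph$image, ph$masks$brain, ph$masks$WM, k = 1.2)
    expect_identical(maskData(seg), maskData(ph$masks$WMH))
    expect_equal(diceCoefficient(seg, ph$masks$WMH), 1.0)
})

test_that("no voxel above threshold gives an empty mask, not an error", {
    ph <- separable_phantom(seed = 42L)
    seg <- segmentWMH(ph$image, ph$masks$brain, ph$masks$WM, k = 10)
    expect_identical(sum(maskData(seg)), 0L)
})

test_that("segmentation is monotone in k and scale- but not shift-invariant", {
    ph <- separable_phantom(seed = 43L, noise_sd = 5)
    seg12 <- segmentWMH(ph$image, ph$masks$brain, ph$masks$WM, k = 1.2)
    seg15 <- segmentWMH(ph$image, ph$masks$brain, ph$masks$WM, k = 1.5)
    expect_true(all(maskData(seg15) <= maskData(seg12)))

    scaled <- ImageVolume(imgData(ph$image) * 3.7, voxelSize(ph$image))
    expect_identical(maskData(segmentWMH(scaled, ph$masks$brain,
                                         ph$masks$WM, k = 1.2)),
                     maskData(seg12))
    shifted <- imgData(ph$image)
    inb <- maskData(ph$masks$brain) > 0
    shifted[inb] <- shifted[inb] + 60
    segsh <- segmentWMH(ImageVolume(shifted, voxelSize(ph$image)),
                        ph$masks$brain, ph$masks$WM, k = 1.2)
    expect_false(identical(maskData(segsh), maskData(seg12)))
})

test_that("segmentation rejects bad parameters", {
    ph <- separable_phantom(seed = 44L)
    expect_error(segmentWMH(ph$image, ph$masks$brain, ph$masks$WM, k = 0),
                 "k must be positive")
    empty_wm <- MaskVolume(array(0, dim(imgData(ph$image))),
                           voxelSize(ph$image), "WM")
    expect_error(segmentWMH(ph$image, ph$masks$brain, empty_wm),
                 "WM mask is empty")
})

test_that("NAWM: 2x2 per-slice erosion matches the brute-force oracle", {
    # full 10x10 slice loses a 1-voxel band along two sides: area 81
    wm <- array(0, c(10, 10, 1)); wm[, , 1] <- 1
    wmh <- MaskVolume(array(0, c(10, 10, 1)), c(1, 1, 1), "WMH")
    nawm <- buildNAWM(MaskVolume(wm, c(1, 1, 1), "WM"), wmh)
    expect_identical(sum(maskData(nawm)), 81L)
    expect_identical(maskData(nawm)[, , 1],
                     array(as.integer(oracle_erode2x2(wm[, , 1] > 0)),
                           c(10, 10)))

    set.seed(9)
    for (rep in 1:5) {
        m <- array(rbinom(14 * 12 * 3, 1, 0.6), c(14, 12, 3))
        h <- array(rbinom(14 * 12 * 3, 1, 0.2), c(14, 12, 3)) & m
        nw <- buildNAWM(MaskVolume(m, c(1, 1, 1), "WM"),
                        MaskVolume(h, c(1, 1, 1), "WMH"))
        for (z in 1:3)
            expect_identical(maskData(nw)[, , z] > 0,
                             oracle_erode2x2(m[, , z] > 0 & !h[, , z]))
        # set relations + idempotence of re-subtraction
        expect_true(all(maskData(nw) <= m))
        expect_identical(sum(maskData(nw) & h), 0L)
        again <- maskData(nw); again[h > 0] <- 0L
        expect_identical(again, maskData(nw))
    }
})

test_that("NAWM degenerate cases: WMH = WM, and sub-kernel objects vanish", {
    wm <- array(1, c(8, 8, 2))
    full <- MaskVolume(wm, role = "WM")
    expect_identical(sum(maskData(buildNAWM(full,
        MaskVolume(wm, role = "WMH")))), 0L)
    single <- array(0, c(8, 8, 2)); single[4, 4, 1] <- 1
    expect_identical(sum(maskData(buildNAWM(MaskVolume(single, role = "WM"),
        MaskVolume(array(0, c(8, 8, 2)), role = "WMH")))), 0L)
})

test_that("volume summary arithmetic and degenerate cases", {
    m <- array(0, c(20, 20, 5)); m[seq_len(1000)] <- 1
    s <- summarizeVolumes(MaskVolume(m, c(0.43, 0.43, 4), "WMH"),
                          etiv_mm3 = 1485100)
    expect_equal(s$wmh_volume_mm3, 1000 * 0.43 * 0.43 * 4, tolerance = 1e-12)
    expect_equal(s$wmh_pct_eTIV, 100 * 739.6 / 1485100, tolerance = 1e-6)
    expect_equal(s$wmh_pct_eTIV, 0.0498, tolerance = 1e-3)
    expect_equal(s$wmh_pct_eTIV_cuberoot, s$wmh_pct_eTIV^(1 / 3))

    empty <- summarizeVolumes(MaskVolume(array(0, c(4, 4, 2))), 1e6)
    expect_identical(empty$wmh_volume_mm3, 0)
    expect_identical(empty$wmh_pct_eTIV, 0)
    expect_identical(empty$wmh_pct_eTIV_cuberoot, 0)

    # exact cube: pct 0.125 -> cube root 0.5
    m2 <- array(0, c(10, 10, 10)); m2[seq_len(125)] <- 1
    s2 <- summarizeVolumes(MaskVolume(m2, c(1, 1, 1), "WMH"),
                           etiv_mm3 = 1e5)
    expect_equal(s2$wmh_pct_eTIV_cuberoot, 0.5, tolerance = 1e-12)

    expect_error(summarizeVolumes(MaskVolume(m2), 0), "positive")
})

test_that("minimum-size filter removes small components only when asked", {
    ph <- separable_phantom(seed = 45L)
    img <- imgData(ph$image)
    # add a single hot WM voxel well above threshold
    wm_only <- which(maskData(ph$masks$WM) > 0 & maskData(ph$masks$WMH) == 0)
    img[wm_only[1]] <- 200
    iv <- ImageVolume(img, voxelSize(ph$image))
    seg_all <- segmentWMH(iv, ph$masks$brain, ph$masks$WM)
    seg_flt <- segmentWMH(iv, ph$masks$brain, ph$masks$WM, min_size = 5L)
    expect_identical(sum(maskData(seg_all)) - sum(maskData(seg_flt)), 1L)
    expect_identical(maskData(seg_flt), maskData(ph$masks$WMH))
})
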