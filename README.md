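# wmhtexture

Voxel-wise grey-level co-occurrence matrix (GLCM) texture analysis of
white matter hyperintensities (WMH) on FLAIR brain MRI.

WMH are the radiological hallmark of cerebral small vessel disease.
Their burden is usually summarized by lesion volume, but volume is
blind to the *internal intensity structure* of the lesions and of the
surrounding normal-appearing white matter (NAWM), where early
microstructural change may show first. This package is for
neuroimaging researchers who want quantitative texture read-outs from
ordinary clinical FLAIR scans: per-voxel texture maps, WMH/NAWM
feature extraction, peri-WMH "penumbra" layer analysis, and the
cohort-level inferential battery, plus a synthetic-cohort generator
that makes the whole pipeline testable without patient data.

## The method

Skull-stripped, bias-corrected FLAIR intensities are quantized to
N = 8 grey levels over the global in-brain range. For every voxel with
a complete 3 × 3 in-plane neighbourhood, ordered level pairs are
counted over the 8 unit directions within the patch, summed into one
co-occurrence table and normalized to p(i, j). Four Haralick features
of that table are assigned to the centre voxel:

    contrast    = Σ p(i,j) (i − j)²          energy  = Σ p(i,j)²
    homogeneity = Σ p(i,j) / (1 + |i − j|)   entropy = −Σ p(i,j) log p(i,j)

yielding voxel-wise texture maps, so ROI definition follows map
generation rather than the reverse. First-order features (mean, SD)
come from the image after min–range normalization over non-zero
voxels. ROIs:

* **WMH** — threshold segmentation at 1.2 × the median in-brain
  intensity, intersected with the WM mask;
* **NAWM** — (WM ∖ WMH) eroded per axial slice with a 2 × 2 square
  kernel;
* **layers 1–10** — concentric rings from per-slice disk dilation of
  the WMH at radii 2, 4, …, 20 voxels (0.86 mm per layer at 0.43 mm
  in-plane resolution; layer 3 reaches 2.58 mm, layer 10 reaches
  8.6 mm), each intersected with WM and exclusive of its predecessors.

All textural measures are cube-root transformed, WMH volume is
expressed as a cube-root percentage of eTIV, and associations with
lesion burden, reaction time and dementia-risk score are tested with
age- and sex-adjusted OLS (mean-centred predictors), interaction
models, Spearman correlations and Benjamini–Hochberg FDR within each
model family. See the methods vignette
(`vignettes/wmhtexture-methods.Rmd`) for every numerical convention
and design decision.

## Worked example

```r
library(wmhtexture)

# a synthetic FLAIR phantom with ground-truth masks
ph <- generatePhantom(phantomSpec(grid_shape = c(48L, 48L, 9L), rng_seed = 7L),
                      lesionSpec(n_lesions = 2, radii_mm = 2.5))

# bias correction, segmentation, texture maps, feature extraction
res <- processSubject(ph$image, ph$masks$brain, ph$masks$WM,
                      etiv_mm3 = 1485100, keep_volumes = TRUE)
round(unlist(res$features[c("WMHT_mean", "WMHT_contrast", "WMHT_homog",
                            "NAWMT_mean", "NAWMT_contrast", "NAWMT_homog",
                            "wmh_pct_eTIV_cuberoot")]), 4)
#>             WMHT_mean         WMHT_contrast            WMHT_homog
#>                0.9632                1.5458                0.9040
#>            NAWMT_mean        NAWMT_contrast           NAWMT_homog
#>                0.8381                0.8448                0.9801
#> wmh_pct_eTIV_cuberoot
#>                0.1768
diceCoefficient(res$wmh, ph$masks$WMH)
#> [1] 1
```

The lesions are brighter (higher cube-rooted normalized mean, 0.96 vs
0.84) and internally rougher (higher contrast, lower homogeneity) than
the surrounding NAWM, and the automated segmentation recovers the
ground-truth lesion mask exactly on this noise level.

A cohort run recovers a planted texture–outcome association (the
default world plants lower lesion mean intensity → slower reaction
time):

```r
co <- generateCohort(phantomSpec(grid_shape = c(48L, 48L, 9L), rng_seed = 7L),
                     cohortSpec(n_subjects = 30L,
                                lesion_params = list(radii_range_mm = c(1.5, 3),
                                                     n_lesions_mean = 3),
                                rng_seed = 7L))
tab <- buildCohortTable(co)
adjustedRegression(tab, "reaction_time_ms", "WMHT_mean")
#> ModelResult: reaction_time_ms ~ WMHT_mean + age + sex  (n = 30)
#>         term      estimate         se    t_value      p_value
#>  (Intercept)   343.3063267   8.618147 39.8352851 7.753286e-25
#>    WMHT_mean -2634.6530154 762.337225 -3.4560204 1.896384e-03
#>          age     0.2840223   1.356849  0.2093248 8.358261e-01
#>          sex    12.1711881  11.608661  1.0484575 3.040768e-01
```

The WMHT_mean slope is negative and significant — brighter lesions,
faster reaction times — matching the direction of the planted effect
(recorded, with its realized raw-scale value, in `co$effects`).

`runPipeline()` drives the same stages from a JSON-serializable
configuration with per-subject caching, failure isolation and a run
manifest; `inst/scripts/run-pipeline.R` is a command-line wrapper.

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end: it simulates a
20-subject FLAIR-like cohort, pushes every subject through bias
correction, WMH segmentation, texture-map generation, layer
construction and feature extraction, fits the full model battery, and
prints the WMH-vs-NAWM paired comparisons and the headline
texture→reaction-time regression before writing its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
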