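Package: wmhtexture
Title: Voxel-Wise GLCM Texture Analysis of White Matter Hyperintensities
    on FLAIR MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise grey-level co-occurrence matrix (GLCM) textural
    analysis of FLAIR brain MRI: per-voxel Haralick texture maps
    (contrast, energy, entropy, homogeneity) from 3x3 axial patches,
    first- and second-order feature extraction within white matter
    hyperintensity (WMH) and normal-appearing white matter (NAWM)
    masks, threshold-based WMH segmentation, concentric peri-WMH
    dilation layers, and a covariate-adjusted regression battery with
    false-discovery-rate control. Includes a synthetic FLAIR phantom
    and cohort generator with ground-truth masks, bias fields, lesion
    texture and planted covariate-texture-outcome effects, plus a
    minimal NIfTI-1 reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'texture.R'
    'layers.R'
    'masks.R'
    'nifti.R'
    'statistics.R'
    'synthetic.R'
    'preprocessing.R'
    'pipeline.R'
    'wmhtexture-package.R'
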