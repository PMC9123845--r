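#' Accessors for image-like objects
#'
#' `imgData` returns the raw 3D numeric array of an [ImageVolume-class];
#' `voxelSize` returns the voxel spacing in mm as `c(x, y, z)`;
#' `maskData` returns the binary array of a [MaskVolume-class] and
#' `maskRole` its role label.
#'
#' @param x an object.
#' @return `imgData`/`maskData`: a 3D array; `voxelSize`: numeric(3);
#'   `maskRole`: a character scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname accessors
#' @export
setGeneric("maskRole", function(x) standardGeneric("maskRole"))

#' Accessors for texture maps
#'
#' `textureMap` extracts one per-voxel feature volume
#' (`"contrast"`, `"energy"`, `"entropy"` or `"homogeneity"`) from a
#' [TextureMaps-class]; `validMask` returns the logical array flagging
#' voxels whose 3x3 in-plane neighbourhood produced a defined GLCM.
#'
#' @param x a `TextureMaps` object.
#' @param which feature name.
#' @return a 3D array.
#' @name texture-accessors
NULL

#' @rdname texture-accessors
#' @export
setGeneric("textureMap", function(x, which) standardGeneric("textureMap"))

#' @rdname texture-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Accessors for peri-WMH layer sets
#'
#' `layerMasks` returns the list of per-layer binary masks,
#' `layerDistances` the cumulative outer distance of each layer in mm
#' (layer k reaches `k * increment * in-plane voxel size`), and
#' `layerThickness` the per-layer thickness in mm.
#'
#' @param x a [LayerSet-class].
#' @return `layerMasks`: list of `MaskVolume`; the others: numeric.
#' @name layer-accessors
NULL

#' @rdname layer-accessors
#' @export
setGeneric("layerMasks", function(x) standardGeneric("layerMasks"))

#' @rdname layer-accessors
#' @export
setGeneric("layerDistances", function(x) standardGeneric("layerDistances"))

#' @rdname layer-accessors
#' @export
setGeneric("layerThickness", function(x) standardGeneric("layerThickness"))
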