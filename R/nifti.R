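#' @include AllClasses.R
NULL

# Minimal little-endian NIfTI-1 reader/writer. Only the fields the
# pipeline needs are honoured: dim, datatype, pixdim, vox_offset,
# scl_slope/inter; orientation is written as a diagonal sform. Both .nii
# and .nii.gz are handled (gzfile reads plain files transparently).

.NIFTI_DT <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
               float64 = 64L)
.NIFTI_BITPIX <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L,
                   float64 = 64L)

.padChar <- function(s, n) {
    r <- charToRaw(s)
    if (length(r) > n) r <- r[seq_len(n)]
    c(r, raw(n - length(r)))
}

#' Write a volume as NIfTI-1
#'
#' Writes an [ImageVolume-class] or [MaskVolume-class] to a `.nii` or
#' `.nii.gz` file (single-file NIfTI-1, little-endian). Masks are stored
#' as unsigned 8-bit; images default to float64 so that a write/read
#' round trip is bit-identical.
#'
#' @param vol an `ImageVolume` or `MaskVolume`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param datatype one of `"float64"`, `"float32"`, `"int16"`, `"int32"`,
#'   `"uint8"`; ignored (forced to `"uint8"`) for masks.
#' @return `path`, invisibly.
#' @seealso [readNifti()], [readMask()]
#' @export
writeNifti <- function(vol, path,
                       datatype = c("float64", "float32", "int16",
                                    "int32", "uint8")) {
    is_mask <- is(vol, "MaskVolume")
    if (!is_mask && !is(vol, "ImageVolume"))
        stop("vol must be an ImageVolume or MaskVolume")
    datatype <- if (is_mask) "uint8" else match.arg(datatype)
    dat <- vol@data
    d <- dim(dat)
    sp <- vol@spacing

    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))

    w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                                  endian = "little")
    w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                                  endian = "little")
    w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L,
                                  endian = "little")

    w_i32(348L)                                   # sizeof_hdr
    writeBin(raw(10 + 18), con)                   # data_type, db_name
    w_i32(0L); w_i16(0L); writeBin(raw(2), con)   # extents..dim_info
    w_i16(c(3L, d, rep(1L, 7 - length(d))))       # dim[8]
    w_f32(c(0, 0, 0))                             # intent_p1..3
    w_i16(0L)                                     # intent_code
    w_i16(.NIFTI_DT[[datatype]])                  # datatype
    w_i16(.NIFTI_BITPIX[[datatype]])              # bitpix
    w_i16(0L)                                     # slice_start
    w_f32(c(1, sp, rep(0, 4)))                    # pixdim[8] (qfac = 1)
    w_f32(352)                                    # vox_offset
    w_f32(c(1, 0))                                # scl_slope, scl_inter
    w_i16(0L); writeBin(raw(2), con)              # slice_end/code/xyzt
    w_f32(c(0, 0, 0, 0))                          # cal_max..toffset
    w_i32(c(0L, 0L))                              # glmax, glmin
    writeBin(.padChar("wmhtexture", 80), con)     # descrip
    writeBin(raw(24), con)                        # aux_file
    w_i16(c(0L, 1L))                              # qform_code, sform_code
    w_f32(rep(0, 6))                              # quatern, qoffset
    w_f32(c(sp[1], 0, 0, 0))                      # srow_x
    w_f32(c(0, sp[2], 0, 0))                      # srow_y
    w_f32(c(0, 0, sp[3], 0))                      # srow_z
    writeBin(raw(16), con)                        # intent_name
    writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
    writeBin(raw(4), con)                         # extension flag

    v <- as.vector(dat)
    switch(datatype,
        uint8  = ,
        int16  = ,
        int32  = writeBin(as.integer(round(v)), con,
                          size = .NIFTI_BITPIX[[datatype]] / 8L,
                          endian = "little"),
        float32 = writeBin(as.numeric(v), con, size = 4L, endian = "little"),
        float64 = writeBin(as.numeric(v), con, size = 8L, endian = "little"))
    invisible(path)
}

.readNiftiRaw <- function(path) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    r_i32 <- function(n = 1L) readBin(con, "integer", n, size = 4L,
                                      endian = "little")
    r_i16 <- function(n = 1L) readBin(con, "integer", n, size = 2L,
                                      endian = "little")
    r_f32 <- function(n = 1L) readBin(con, "numeric", n, size = 4L,
                                      endian = "little")
    skip <- function(n) invisible(readBin(con, "raw", n))

    hs <- r_i32()
    if (!identical(hs, 348L))
        stop(sprintf("'%s' is not a little-endian NIfTI-1 file", path))
    skip(36)                       # data_type..dim_info
    dims <- r_i16(8)
    ndim <- dims[1]
    if (ndim < 3L || ndim > 4L || (ndim == 4L && dims[5] != 1L))
        stop(sprintf("'%s': only 3D volumes are supported", path))
    d <- dims[2:4]
    skip(12)                       # intent_p
    skip(2)                        # intent_code
    dt <- r_i16()
    skip(2 + 2)                    # bitpix, slice_start
    pixdim <- r_f32(8)
    voff <- r_f32()
    slope <- r_f32(); inter <- r_f32()
    skip(348 - 120)                # rest of header
    skip(as.integer(round(voff)) - 348L)

    n <- prod(d)
    v <- switch(as.character(dt),
        "2"  = readBin(con, "integer", n, size = 1L, signed = FALSE),
        "4"  = readBin(con, "integer", n, size = 2L, endian = "little"),
        "8"  = readBin(con, "integer", n, size = 4L, endian = "little"),
        "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
        "64" = readBin(con, "numeric", n, size = 8L, endian = "little"),
        stop(sprintf("'%s': unsupported NIfTI datatype code %d", path, dt)))
    if (length(v) != n)
        stop(sprintf("'%s': truncated data section", path))
    v <- as.numeric(v)
    if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0))
        v <- v * slope + inter
    list(data = array(v, dim = d), spacing = pixdim[2:4])
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return an [ImageVolume-class] carrying the voxel spacing from
#'   `pixdim`.
#' @export
readNifti <- function(path) {
    x <- .readNiftiRaw(path)
    ImageVolume(x$data, spacing = x$spacing)
}

#' Read a binary mask from NIfTI-1
#'
#' Values other than 0/1 are rejected. When `reference` is given
#' (an [ImageVolume-class] or a path), grid shape and voxel spacing are
#' checked and a mismatch raises an error naming both files.
#'
#' @param path mask file.
#' @param role mask role label (see [MaskVolume-class]).
#' @param reference optional companion image (object or path) the mask
#'   must align with.
#' @param reference_path name used for the reference in error messages.
#' @return a [MaskVolume-class].
#' @export
readMask <- function(path, role = "generic", reference = NULL,
                     reference_path = NULL) {
    x <- .readNiftiRaw(path)
    vals <- unique(as.vector(x$data))
    if (!all(vals %in% c(0, 1)))
        stop(sprintf("'%s' is not a binary mask (values: %s)", path,
                     paste(utils::head(sort(vals), 5), collapse = ", ")))
    if (!is.null(reference)) {
        if (is.character(reference)) {
            reference_path <- reference_path %||% reference
            reference <- readNifti(reference)
        }
        reference_path <- reference_path %||% "<reference image>"
        if (!identical(dim(x$data), dim(reference@data)) ||
            max(abs(x$spacing - reference@spacing)) > 1e-4)
            stop(sprintf(
                "mask '%s' does not align with image '%s' (%s @ %s vs %s @ %s)",
                path, reference_path,
                paste(dim(x$data), collapse = "x"),
                paste(signif(x$spacing, 4), collapse = "x"),
                paste(dim(reference@data), collapse = "x"),
                paste(signif(reference@spacing, 4), collapse = "x")))
    }
    MaskVolume(x$data, spacing = x$spacing, role = role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
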