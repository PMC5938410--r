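# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in the deployment environment, so the small
# subset of the format the package needs is implemented here: 3-D volumes,
# the common scalar datatypes, scl_slope/scl_inter scaling, and the sform
# affine. Dimensions beyond the third must be singleton. Both byte orders
# are read; files are written little-endian with sform code 2.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE, name = "uint8"),
  `4`   = list(what = "integer", size = 2L, signed = TRUE,  name = "int16"),
  `8`   = list(what = "integer", size = 4L, signed = TRUE,  name = "int32"),
  `16`  = list(what = "double",  size = 4L, signed = TRUE,  name = "float32"),
  `64`  = list(what = "double",  size = 8L, signed = TRUE,  name = "float64"),
  `256` = list(what = "integer", size = 1L, signed = TRUE,  name = "int8"),
  `512` = list(what = "integer", size = 2L, signed = FALSE, name = "uint16")
)

nifti_connection <- function(path, open) {
  raw2 <- readBin(path, "raw", 2L)
  gz <- length(raw2) == 2L && raw2[1] == as.raw(0x1f) && raw2[2] == as.raw(0x8b)
  if (gz) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3-D single-file NIfTI-1 image (optionally gzipped). Trailing
#' singleton dimensions are dropped; higher-dimensional images are rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A list with `img` (3-D numeric array), `voxel_size` (mm, length
#'   3), `affine` (4x4 voxel-to-world matrix) and `datatype` (name).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_mlsmap("NIfTI file not found: %s", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop_mlsmap("truncated NIfTI header in %s", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L) stop_mlsmap("%s is not a NIfTI-1 file", path)
  }
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what, n, size,
            endian = endian, signed = TRUE)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop_mlsmap("%s lacks a NIfTI-1 magic string", path)
  if (magic == "ni1")
    stop_mlsmap("two-file (.hdr/.img) NIfTI is not supported: %s", path)
  dim0 <- rd(40L, "integer", 8L, 2L)
  ndim <- dim0[1]
  dims <- dim0[2:8]
  if (ndim < 1L || ndim > 7L) stop_mlsmap("bad dim[0]=%d in %s", ndim, path)
  dims <- dims[seq_len(ndim)]
  if (any(dims[-(1:min(3, ndim))] > 1L))
    stop_mlsmap("%s has non-singleton dimensions beyond the third", path)
  shape <- c(dims, 1L, 1L)[1:3]
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt))
    stop_mlsmap("unsupported NIfTI datatype code %d in %s", datatype, path)
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  srow <- matrix(rd(280L, "double", 12L, 4L), nrow = 3L, byrow = TRUE)
  voxel_size <- abs(pixdim[2:4])
  voxel_size[voxel_size == 0] <- 1
  affine <- if (sform_code > 0L) rbind(srow, c(0, 0, 0, 1)) else
    diag(c(voxel_size, 1))
  # skip to the data
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n) stop_mlsmap("truncated NIfTI data in %s", path)
  vals <- as.numeric(vals)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(img = array(vals, dim = shape), voxel_size = voxel_size,
       affine = affine, datatype = dt$name)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D array as a single-file little-endian NIfTI-1 image. A `.gz`
#' suffix triggers gzip compression. The affine is stored as the sform
#' (code 2).
#'
#' @param img 3-D numeric/logical array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size mm per axis (length 3 or 1).
#' @param affine optional 4x4 voxel-to-world matrix.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`; the default picks `uint8` for binary content and
#'   `float32` otherwise.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxel_size = c(1, 1, 1), affine = NULL,
                        datatype = NULL) {
  if (is.logical(img)) img <- array(as.integer(img), dim = dim(img))
  if (length(dim(img)) != 3L) stop_mlsmap("img must be a 3-D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  if (is.null(datatype)) {
    finite <- img[is.finite(img)]
    datatype <- if (length(finite) && all(finite %in% c(0, 1)) &&
                    !anyNA(img)) "uint8" else "float32"
  }
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop_mlsmap("unsupported write datatype %s", datatype))
  size <- switch(datatype, uint8 = 1L, int16 = 2L, int32 = 4L,
                 float32 = 4L, float64 = 8L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size, endian = "little")
  wdbl <- function(x, size) writeBin(as.numeric(x), con, size, endian = "little")
  wint(348L, 4L)                                  # sizeof_hdr
  writeBin(raw(35L), con); wint(0L, 1L)           # data_type..dim_info
  wint(c(3L, dim(img), 1L, 1L, 1L, 1L), 2L)       # dim[8]
  wdbl(c(0, 0, 0), 4L); wint(0L, 2L)              # intent_p1..intent_code
  wint(code, 2L); wint(size * 8L, 2L)             # datatype, bitpix
  wint(0L, 2L)                                    # slice_start
  wdbl(c(1, voxel_size, 1, 1, 1, 1), 4L)          # pixdim[8]
  wdbl(352, 4L)                                   # vox_offset
  wdbl(c(1, 0), 4L)                               # scl_slope, scl_inter
  wint(0L, 2L); wint(0L, 1L); wint(0L, 1L)        # slice_end, slice_code, xyzt_units
  wdbl(c(0, 0, 0, 0), 4L)                         # cal_max..toffset
  wint(c(0L, 0L), 4L)                             # glmax, glmin
  writeBin(raw(80L + 24L), con)                   # descrip, aux_file
  wint(0L, 2L); wint(2L, 2L)                      # qform_code, sform_code
  wdbl(rep(0, 6), 4L)                             # quatern b c d, qoffset x y z
  wdbl(t(affine[1:3, ]), 4L)                      # srow_x, srow_y, srow_z
  writeBin(raw(16L), con)                         # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)  # magic
  writeBin(raw(4L), con)                          # extension flag
  vals <- as.vector(img)
  if (datatype %in% c("float32", "float64")) {
    vals[is.na(vals)] <- NaN
    wdbl(vals, size)
  } else {
    if (anyNA(vals)) stop_mlsmap("NA values need a float datatype")
    wint(vals, size)
  }
  invisible(path)
}
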