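#' Read a NIfTI-1 volume
#'
#' Minimal NIfTI-1 reader for 3-D and 4-D scalar volumes (`.nii` or
#' `.nii.gz`). Handles the integer and floating-point datatypes produced by
#' common diffusion pipelines, applies `scl_slope`/`scl_inter` scaling, and
#' detects byte order from the `sizeof_hdr` field. The sform affine and the
#' `pixdim` voxel size are preserved so that a write/read cycle round-trips
#' geometry exactly.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list of class `"nifti_volume"` with elements `data` (numeric
#'   array), `voxel_size` (mm triplet, plus a fourth entry for 4-D data),
#'   `affine` (4x4 sform matrix) and `datatype` (NIfTI datatype code).
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L) {
    stop("malformed NIfTI header: only ", length(raw_hdr),
         " of 348 bytes present")
  }
  endian <- "little"
  sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) {
      stop("malformed NIfTI header: sizeof_hdr at offset 0 is not 348")
    }
  }
  rd_i16 <- function(off, n) readBin(raw_hdr[(off + 1):(off + 2 * n)],
                                     "integer", n = n, size = 2,
                                     endian = endian)
  rd_i32 <- function(off, n) readBin(raw_hdr[(off + 1):(off + 4 * n)],
                                     "integer", n = n, size = 4,
                                     endian = endian)
  rd_f32 <- function(off, n) readBin(raw_hdr[(off + 1):(off + 4 * n)],
                                     "double", n = n, size = 4,
                                     endian = endian)
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("malformed NIfTI header: bad magic at offset 344")
  }
  dim_field <- rd_i16(40, 8)
  ndim <- dim_field[1]
  if (ndim < 3 || ndim > 4) stop("unsupported dimensionality: ", ndim)
  dims <- dim_field[2:(1 + ndim)]
  datatype <- rd_i16(70, 1)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  srow <- rbind(rd_f32(280, 4), rd_f32(296, 4), rd_f32(312, 4))
  affine <- rbind(srow, c(0, 0, 0, 1))

  type <- switch(as.character(datatype),
    "2"   = list(what = "integer", size = 1, signed = FALSE),
    "4"   = list(what = "integer", size = 2, signed = TRUE),
    "8"   = list(what = "integer", size = 4, signed = TRUE),
    "16"  = list(what = "double",  size = 4, signed = TRUE),
    "64"  = list(what = "double",  size = 8, signed = TRUE),
    "256" = list(what = "integer", size = 1, signed = TRUE),
    "512" = list(what = "integer", size = 2, signed = FALSE),
    stop("unsupported NIfTI datatype code: ", datatype)
  )
  # skip from end of header to the data offset (extensions etc.)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  vals <- readBin(con, type$what, n = n_vox, size = type$size,
                  signed = type$signed, endian = endian)
  if (length(vals) < n_vox) {
    stop("truncated NIfTI file: expected ", n_vox, " voxels, read ",
         length(vals))
  }
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  structure(
    list(data = array(as.numeric(vals), dim = dims),
         voxel_size = pixdim[2:(1 + ndim)],
         affine = affine,
         datatype = as.integer(datatype)),
    class = "nifti_volume"
  )
}

#' Write a NIfTI-1 volume
#'
#' Companion writer to [read_volume()]. Data are stored as float64 by
#' default; pass `datatype = "int32"` or `"int16"` for label volumes. A
#' `.gz` suffix selects gzip compression. The affine defaults to a diagonal
#' scaling by the voxel size (sform code 1).
#'
#' @param data numeric 3-D or 4-D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size mm size per spatial axis (length 3).
#' @param affine optional 4x4 sform matrix.
#' @param datatype one of `"float64"`, `"float32"`, `"int32"`, `"int16"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, voxel_size = c(1, 1, 1), affine = NULL,
                         datatype = c("float64", "float32", "int32", "int16")) {
  datatype <- match.arg(datatype)
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L))) {
    stop("data must be a 3-D or 4-D array")
  }
  dims <- dim(data)
  ndim <- length(dims)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size[1:3], 1))
  }
  code <- switch(datatype, float64 = 64L, float32 = 16L,
                 int32 = 8L, int16 = 4L)
  bitpix <- switch(datatype, float64 = 64L, float32 = 32L,
                   int32 = 32L, int16 = 16L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4,
                                endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2,
                                endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4,
                                endian = "little")
  w_raw0 <- function(n) writeBin(raw(n), con)

  w_i32(348L)                                   # sizeof_hdr
  w_raw0(35)                                    # data_type..regular, dim_info
  w_raw0(1)
  dim_field <- c(ndim, dims, rep(1L, 7 - ndim))
  w_i16(dim_field)                              # dim[8]
  w_raw0(14)                                    # intent_p1..intent_code
  w_i16(code)                                   # datatype
  w_i16(bitpix)                                 # bitpix
  w_i16(0L)                                     # slice_start
  pix <- c(1, voxel_size[1:3], rep(1, 4))[1:8]
  if (ndim == 4) pix[5] <- 1
  w_f32(pix)                                    # pixdim[8]
  w_f32(352)                                    # vox_offset
  w_f32(1); w_f32(0)                            # scl_slope, scl_inter
  w_i16(0L); w_raw0(1); w_raw0(1)               # slice_end, slice_code, units
  w_f32(c(0, 0, 0, 0))                          # cal_max..toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  w_raw0(80); w_raw0(24)                        # descrip, aux_file
  w_i16(0L); w_i16(1L)                          # qform_code, sform_code = 1
  w_f32(rep(0, 6))                              # quatern/qoffset
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw0(16)                                    # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  w_raw0(4)                                     # extension flag
  if (code %in% c(16L, 64L)) {
    writeBin(as.double(data), con, size = bitpix / 8, endian = "little")
  } else {
    writeBin(as.integer(data), con, size = bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read FSL-style b-value / b-vector text files
#'
#' Accepts both FSL layouts (one row per volume or one column per volume)
#' and records which was detected.
#'
#' @param bval_path whitespace-delimited b-values file.
#' @param bvec_path whitespace-delimited gradient-direction file.
#' @return list with `bvals` (length n), `bvecs` (n x 3 matrix) and
#'   `layout` (`"row"` or `"column"`).
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  m <- as.matrix(utils::read.table(bvec_path))
  if (nrow(m) == 3 && ncol(m) != 3) {
    m <- t(m); layout <- "column"
  } else if (ncol(m) == 3) {
    layout <- "row"
  } else if (nrow(m) == 3) {        # 3x3 is ambiguous; FSL default is 3 rows
    m <- t(m); layout <- "column"
  } else {
    stop("bvec file is not n x 3 or 3 x n")
  }
  if (nrow(m) != length(bvals)) {
    stop("bval/bvec volume counts disagree: ", length(bvals), " vs ", nrow(m))
  }
  dimnames(m) <- NULL
  list(bvals = bvals, bvecs = m, layout = layout)
}
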