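# Minimal single-file NIfTI-1 (.nii / .nii.gz) I/O.
# Only what the pipeline needs: 3D binary masks and 4D BOLD series, with
# voxel size in pixdim[2:4] and TR in pixdim[5]. No orientation handling
# beyond identity (phantom data); qform/sform codes are written as 0.

nifti_dtypes <- list(
  "2"  = list(what = "integer", size = 1L, signed = FALSE, r = "uint8"),
  "4"  = list(what = "integer", size = 2L, signed = TRUE,  r = "int16"),
  "8"  = list(what = "integer", size = 4L, signed = TRUE,  r = "int32"),
  "16" = list(what = "double",  size = 4L, signed = TRUE,  r = "float32"),
  "64" = list(what = "double",  size = 8L, signed = TRUE,  r = "float64"))

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume or mask as NIfTI-1
#'
#' Writes a `volume_series` (4D, float32) or a 3D logical/numeric mask
#' (uint8) as a single-file NIfTI-1 image. Masks are binarised to \{0, 1\}.
#' Filenames ending in `.gz` are gzip-compressed.
#'
#' @param x a `volume_series`, or a 3D array (mask).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm voxel size for bare arrays (ignored for
#'   `volume_series`, which carries its own).
#' @param tr_s repetition time for bare 4D arrays.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size_mm = 1.5, tr_s = 3.5) {
  if (inherits(x, "volume_series")) {
    arr <- x$data; voxel_size_mm <- x$voxel_size_mm; tr_s <- x$tr_s
    dtype <- 16L
  } else if (is.array(x) && length(dim(x)) == 3L) {
    arr <- array(as.integer(as.logical(x)), dim(x))
    dtype <- 2L
  } else if (is.array(x) && length(dim(x)) == 4L) {
    arr <- x; dtype <- 16L
  } else stop("`x` must be a volume_series or a 3D/4D array")

  d <- dim(arr)
  nd <- length(d)
  dim_field <- rep(1L, 8L); dim_field[1L] <- nd; dim_field[seq_len(nd) + 1L] <- d
  pixdim <- rep(0, 8); pixdim[2:4] <- voxel_size_mm
  if (nd == 4L) pixdim[5] <- tr_s
  bitpix <- nifti_dtypes[[as.character(dtype)]]$size * 8L

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(10L + 18L + 4L + 2L + 1L + 1L), con)   # data_type..dim_info
  writeBin(as.integer(dim_field), con, size = 2)      # dim[8]
  writeBin(rep(0, 3), con, size = 4)                  # intent_p1..p3
  writeBin(0L, con, size = 2)                         # intent_code
  writeBin(as.integer(dtype), con, size = 2)          # datatype
  writeBin(as.integer(bitpix), con, size = 2)         # bitpix
  writeBin(0L, con, size = 2)                         # slice_start
  writeBin(as.numeric(pixdim), con, size = 4)         # pixdim[8]
  writeBin(352, con, size = 4)                        # vox_offset (float!)
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  writeBin(0L, con, size = 2)                         # slice_end
  writeBin(raw(2L), con)                              # slice_code, xyzt_units
  writeBin(rep(0, 3), con, size = 4)                  # cal_max, cal_min, slice_duration
  writeBin(0, con, size = 4)                          # toffset
  writeBin(c(0L, 0L), con, size = 4)                  # glmax, glmin
  writeBin(raw(80L + 24L), con)                       # descrip, aux_file
  writeBin(c(0L, 0L), con, size = 2)                  # qform_code, sform_code
  writeBin(rep(0, 6 + 12), con, size = 4)             # quatern/qoffset + srow
  writeBin(raw(16L), con)                             # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1L), con)                              # magic terminator
  writeBin(raw(4L), con)                              # extension flag
  if (dtype == 2L) {
    writeBin(as.raw(arr), con)
  } else {
    writeBin(as.numeric(arr), con, size = 4)
  }
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 image written by [write_nifti()] (or any
#' uncompressed/gzipped `.nii` with a supported datatype). 3D images are
#' returned as arrays; 4D images as `volume_series` with voxel size and TR
#' taken from `pixdim`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param session_bounds optional session partition passed through to
#'   [volume_series()] for 4D images.
#' @return a 3D array or a `volume_series`.
#' @export
read_nifti <- function(path, session_bounds = NULL) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_size <- readBin(con, "integer", 1L, size = 4, endian = endian)
  if (hdr_size != 348L)
    stop("not a little-endian NIfTI-1 file: ", path)
  readBin(con, "raw", 36L)                            # skip to dim
  dim_field <- readBin(con, "integer", 8L, size = 2, endian = endian)
  nd <- dim_field[1L]
  if (nd < 3L || nd > 4L) stop("only 3D/4D NIfTI supported, got ", nd, "D")
  d <- dim_field[2L:(nd + 1L)]
  readBin(con, "raw", 14L)                            # intent fields
  dtype <- readBin(con, "integer", 1L, size = 2, endian = endian)
  readBin(con, "raw", 4L)                             # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4, endian = endian)
  scl <- readBin(con, "numeric", 2L, size = 4, endian = endian)
  info <- nifti_dtypes[[as.character(dtype)]]
  if (is.null(info)) stop("unsupported NIfTI datatype code: ", dtype)
  readBin(con, "raw", as.integer(vox_offset) - 120L)  # rest of header + ext
  n <- prod(d)
  vals <- readBin(con, info$what, n, size = info$size,
                  signed = info$signed || info$size > 2L, endian = endian)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vals <- vals * scl[1] + scl[2]
  arr <- array(as.numeric(vals), d)
  if (nd == 3L) return(arr)
  volume_series(arr, voxel_size_mm = pixdim[2], tr_s = pixdim[5],
                session_bounds = session_bounds)
}
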