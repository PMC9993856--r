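## Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
## No NIfTI package ships with this R stack, and the format's fixed 348-byte
## header is simple enough to read and write with base connections.  Scope:
## little-endian, scalar 2D/3D volumes plus multi-component (vector-intent)
## fields; datatypes uint8/int16/int32/float32/float64 on read, float64 on
## write; geometry from the sform (written as a diagonal spacing matrix with
## an origin offset), falling back to pixdim.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

write_nifti <- function(values, spacing, origin, path, intent_vector = FALSE) {
  d <- dim(values)
  nd <- length(d)
  if (intent_vector) {
    ncomp <- d[nd]
    sdim <- d[-nd]
    dim8 <- c(5L, sdim, rep(1L, 3 - length(sdim)), 1L, ncomp, 1L, 1L)
  } else {
    dim8 <- c(nd, d, rep(1L, 7 - nd))
  }
  sp3 <- c(spacing, rep(1, 3 - length(spacing)))
  or3 <- c(origin, rep(0, 3 - length(origin)))
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(NIFTI_HDR_SIZE)                       # sizeof_hdr
  w_raw(10 + 18); w_i32(0); w_i16(0)          # data_type, db_name, extents, session_error
  writeBin(charToRaw("r"), con); w_raw(1)     # regular, dim_info
  w_i16(dim8)                                 # dim[8]
  w_f32(c(0, 0, 0))                           # intent_p1..3
  w_i16(if (intent_vector) 1007L else 0L)     # intent_code (NIFTI_INTENT_VECTOR)
  w_i16(64L); w_i16(64L); w_i16(0L)           # datatype float64, bitpix, slice_start
  w_f32(c(1, sp3, rep(1, 4)))                 # pixdim[8] (qfac 1)
  w_f32(NIFTI_VOX_OFFSET)                     # vox_offset
  w_f32(1); w_f32(0)                          # scl_slope, scl_inter
  w_i16(0); w_raw(1); writeBin(as.raw(2L), con)  # slice_end, slice_code, xyzt_units = mm
  w_f32(c(0, 0, 0, 0))                        # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0, 0))                              # glmax, glmin
  w_raw(80 + 24)                              # descrip, aux_file
  w_i16(0L); w_i16(1L)                        # qform_code 0, sform_code 1
  w_f32(rep(0, 6))                            # quaternion b,c,d + qoffset
  w_f32(c(sp3[1], 0, 0, or3[1]))              # srow_x
  w_f32(c(0, sp3[2], 0, or3[2]))              # srow_y
  w_f32(c(0, 0, sp3[3], or3[3]))              # srow_z
  w_raw(16)                                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  w_raw(4)                                    # pad to vox_offset 352
  writeBin(as.numeric(values), con, size = 8, endian = "little")
  invisible(path)
}

read_nifti <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", NIFTI_HDR_SIZE)
  if (length(hdr) < NIFTI_HDR_SIZE)
    stop("malformed NIfTI file '", path, "': truncated header")
  r_i32 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "integer",
                                        n, size = 4, endian = "little")
  r_i16 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                        n, size = 2, endian = "little")
  r_f32 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "numeric",
                                        n, size = 4, endian = "little")
  if (r_i32(0) != NIFTI_HDR_SIZE)
    stop("malformed NIfTI file '", path, "': bad sizeof_hdr (big-endian files unsupported)")
  dim8 <- r_i16(40, 8)
  datatype <- r_i16(70)
  pixdim <- r_f32(76, 8)
  vox_offset <- r_f32(108)
  scl_slope <- r_f32(112); scl_inter <- r_f32(116)
  sform_code <- r_i16(254)
  srow <- rbind(r_f32(280, 4), r_f32(296, 4), r_f32(312, 4))
  ndim_hdr <- dim8[1]
  intent_code <- r_i16(68)

  if (ndim_hdr == 5 && dim8[6] > 1) {          # vector field
    nspace <- if (dim8[4] > 1) 3L else 2L      # 2D fields stored as (nx, ny, 1)
    shape <- c(dim8[2:(1 + nspace)], dim8[6])
  } else {
    nspace <- ndim_hdr
    shape <- dim8[2:(1 + nspace)]
  }
  n <- prod(shape)
  # skip any header extension up to vox_offset
  skip <- vox_offset - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", skip)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype ", datatype, " in '", path, "'"))
  if (length(vals) < n)
    stop("malformed NIfTI file '", path, "': truncated data section")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (sform_code > 0) {
    spacing3 <- sqrt(colSums(srow[, 1:3]^2))
    origin3 <- srow[, 4]
  } else {
    spacing3 <- abs(pixdim[2:4])
    origin3 <- c(0, 0, 0)
  }
  list(values = array(vals, shape),
       spacing = spacing3[seq_len(min(nspace, 3))],
       origin = origin3[seq_len(min(nspace, 3))],
       vector = ndim_hdr == 5 && dim8[6] > 1,
       intent_code = intent_code)
}

#' Read a volume from a NIfTI-1 file
#'
#' Supports uncompressed `.nii` and gzipped `.nii.gz`, scalar 2D/3D volumes,
#' little-endian, datatypes uint8/int16/int32/float32/float64.  Spacing and
#' origin are taken from the sform when present, else from `pixdim`.
#'
#' @param path file path.
#' @return an `ImageGrid`.
#' @export
read_volume <- function(path) {
  r <- read_nifti(path)
  if (r$vector)
    stop("'", path, "' is a vector field; use read_dvf()")
  image_grid(r$values, spacing = r$spacing, origin = r$origin)
}

#' Write a volume to a NIfTI-1 file
#'
#' Float64 storage, so write/read round trips are exact.
#'
#' @param image an `ImageGrid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(image, path) {
  stopifnot(is_image_grid(image))
  invisible(write_nifti(image$values, image$spacing, image$origin, path))
}

#' Read / write a displacement field as a multi-component NIfTI
#'
#' Components are stored in mm along the physical axes with the NIfTI
#' vector intent code.
#'
#' @param dvf a `DisplacementField`.
#' @param path file path.
#' @return `read_dvf`: a `DisplacementField`; `write_dvf`: the path.
#' @export
write_dvf <- function(dvf, path) {
  invisible(write_nifti(dvf$values, dvf$spacing, dvf$origin, path,
                        intent_vector = TRUE))
}

#' @rdname write_dvf
#' @export
read_dvf <- function(path) {
  r <- read_nifti(path)
  if (!r$vector) stop("'", path, "' is not a vector field")
  displacement_field(r$values, r$spacing, r$origin)
}

#' Write a structure set as one NIfTI label mask per structure
#'
#' Files are named `<prefix>_<structure>.nii`.
#'
#' @param structures a `StructureSet`.
#' @param prefix path prefix.
#' @return named vector of written paths, invisibly.
#' @export
write_structures <- function(structures, prefix) {
  paths <- vapply(structures$names, function(nm) {
    p <- paste0(prefix, "_", nm, ".nii")
    write_nifti(structures$masks[[nm]], structures$spacing,
                structures$origin, p)
    p
  }, character(1))
  invisible(paths)
}
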