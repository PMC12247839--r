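# NIfTI-1 single-file (.nii, uncompressed) codec. The header is the fixed
# 348-byte layout; spatial units are written as micrometers (xyzt_units = 3)
# to match the package's um spacing convention. Data are stored in NIfTI's
# x-fastest order; package arrays are (z, y, x), so axes are permuted on the
# way in and out.

nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE, mode = "integer"),
  `4`   = list(what = "integer", size = 2L, signed = TRUE,  mode = "integer"),
  `8`   = list(what = "integer", size = 4L, signed = TRUE,  mode = "integer"),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE,  mode = "double"),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE,  mode = "double"),
  `512` = list(what = "integer", size = 2L, signed = FALSE, mode = "integer")
)

write_nifti <- function(data, path, spacing, origin = c(0, 0, 0),
                        datatype = 16L) {
  d <- dim(data)                       # (z, y, x)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")
  writeBin(raw(36), con)                                   # unused fields
  dimv <- c(3L, d[3], d[2], d[1], 1L, 1L, 1L, 1L)
  writeBin(as.integer(dimv), con, size = 2, endian = "little")
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")   # intent_p1..3
  writeBin(0L, con, size = 2, endian = "little")           # intent_code
  writeBin(as.integer(datatype), con, size = 2, endian = "little")
  bitpix <- dt$size * 8L
  writeBin(as.integer(bitpix), con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")           # slice_start
  pixdim <- c(1, spacing[3], spacing[2], spacing[1], 1, 1, 1, 1)
  writeBin(pixdim, con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")          # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")      # scl_slope/inter
  writeBin(0L, con, size = 2, endian = "little")           # slice_end
  writeBin(as.raw(c(0L, 3L)), con)                         # slice_code, units=micron
  writeBin(c(0, 0, 0, 0), con, size = 4, endian = "little")
  writeBin(c(0L, 0L), con, size = 4, endian = "little")    # glmax/glmin
  writeBin(pad_char("pawseg", 80), con)                    # descrip
  writeBin(raw(24), con)                                   # aux_file
  writeBin(c(1L, 0L), con, size = 2, endian = "little")    # qform, sform
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")   # quatern b,c,d
  writeBin(c(origin[3], origin[2], origin[1]), con, size = 4,
           endian = "little")
  writeBin(numeric(12), con, size = 4, endian = "little")  # srow
  writeBin(raw(16), con)                                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)           # magic
  writeBin(raw(4), con)                                    # no extensions
  v <- as.vector(aperm(data, c(3, 2, 1)))                  # x fastest
  if (dt$mode == "integer") {
    storage.mode(v) <- "integer"
    writeBin(v, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352L)
  if (length(hdr) < 348L) fmt_error(path, "truncated NIfTI header")
  if (raw_u32(hdr, 1L) != 348) fmt_error(path, "not a NIfTI-1 file")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) fmt_error(path, "bad NIfTI magic")
  dimv <- raw_u16(hdr, 41L, 8L)
  ndim <- dimv[1]
  if (ndim < 3L) fmt_error(path, "fewer than 3 dimensions")
  nx <- dimv[2]; ny <- dimv[3]; nz <- dimv[4]
  datatype <- raw_u16(hdr, 71L)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) fmt_error(path, paste("unsupported datatype", datatype))
  pixdim <- readBin(hdr[77:108], "numeric", 8L, size = 4, endian = "little")
  vox_offset <- readBin(hdr[109:112], "numeric", 1L, size = 4,
                        endian = "little")
  scl_slope <- readBin(hdr[113:116], "numeric", 1L, size = 4,
                       endian = "little")
  scl_inter <- readBin(hdr[117:120], "numeric", 1L, size = 4,
                       endian = "little")
  units <- as.integer(hdr[124]) %% 8L
  qoff <- readBin(hdr[269:280], "numeric", 3L, size = 4, endian = "little")
  seek(con, vox_offset)
  n <- as.numeric(nx) * ny * nz
  v <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
               endian = "little")
  if (length(v) < n) fmt_error(path, "truncated NIfTI data")
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  arr <- aperm(array(v, dim = c(nx, ny, nz)), c(3, 2, 1))
  sp <- pixdim[2:4]
  # spatial unit codes: 1 = m, 2 = mm, 3 = um; normalize to um
  scale <- switch(as.character(units), `1` = 1e6, `2` = 1e3, `3` = 1, 1)
  if (any(sp <= 0)) {
    warning("NIfTI spacing missing; assuming 17.5 um isotropic")
    sp <- c(17.5, 17.5, 17.5)
    scale <- 1
  }
  list(data = arr, spacing = rev(sp) * scale, origin = rev(qoff) * scale,
       datatype = datatype)
}
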