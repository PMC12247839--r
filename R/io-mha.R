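# MetaImage (.mha, local uncompressed) codec. Plain-text header followed by
# raw little-endian voxel data, x fastest. ElementSpacing/Offset are stored in
# the package's micrometer convention.

mha_types <- list(
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE)
)

write_mha <- function(data, path, spacing, origin = c(0, 0, 0),
                      element_type = "MET_FLOAT") {
  d <- dim(data)                       # (z, y, x)
  tt <- mha_types[[element_type]]
  if (is.null(tt)) stop("unsupported MHA element type ", element_type)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %s", paste(c(origin[3], origin[2], origin[1]),
                                 collapse = " ")),
    sprintf("ElementSpacing = %s", paste(c(spacing[3], spacing[2], spacing[1]),
                                         collapse = " ")),
    sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
    sprintf("ElementType = %s", element_type),
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  v <- as.vector(aperm(data, c(3, 2, 1)))
  if (tt$what == "integer") {
    if (element_type == "MET_USHORT") writeBin(u16_raw(v), con)
    else {
      storage.mode(v) <- "integer"
      writeBin(v, con, size = tt$size, endian = "little")
    }
  } else {
    writeBin(as.numeric(v), con, size = tt$size, endian = "little")
  }
  invisible(path)
}

read_mha <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  # header ends at the newline after the ElementDataFile line
  txt_end <- length(r)
  key <- charToRaw("ElementDataFile")
  pos <- which(r == key[1])
  hdr_end <- NA_integer_
  for (p in pos) {
    if (p + length(key) - 1L <= length(r) &&
        identical(r[p:(p + length(key) - 1L)], key)) {
      nl <- p + which(r[p:min(length(r), p + 200L)] == as.raw(10L))[1] - 1L
      hdr_end <- nl
      break
    }
  }
  if (is.na(hdr_end)) fmt_error(path, "no ElementDataFile key (not an MHA?)")
  lines <- strsplit(rawToChar(r[1:hdr_end]), "\n")[[1]]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  if (is.null(kv$DimSize) || is.null(kv$ElementType))
    fmt_error(path, "missing DimSize/ElementType")
  if (!is.null(kv$CompressedData) && toupper(kv$CompressedData) == "TRUE")
    fmt_error(path, "compressed MHA not supported")
  if (!is.null(kv$ElementDataFile) && kv$ElementDataFile != "LOCAL")
    fmt_error(path, "only ElementDataFile = LOCAL supported")
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])   # (x, y, z)
  tt <- mha_types[[kv$ElementType]]
  if (is.null(tt)) fmt_error(path, paste("unsupported type", kv$ElementType))
  n <- prod(dims)
  bytes <- r[(hdr_end + 1L):length(r)]
  if (length(bytes) < n * tt$size) fmt_error(path, "truncated MHA data")
  v <- if (kv$ElementType == "MET_USHORT") raw_u16(bytes, 1L, n)
       else readBin(bytes, tt$what, n, size = tt$size, signed = tt$signed,
                    endian = "little")
  arr <- aperm(array(v, dim = dims), c(3, 2, 1))
  sp <- if (!is.null(kv$ElementSpacing))
    rev(as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]))
  else {
    warning("MHA spacing missing; assuming 17.5 um isotropic")
    c(17.5, 17.5, 17.5)
  }
  org <- if (!is.null(kv$Offset))
    rev(as.numeric(strsplit(kv$Offset, "\\s+")[[1]]))
  else c(0, 0, 0)
  list(data = arr, spacing = sp, origin = org)
}
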