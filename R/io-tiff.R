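# Minimal multi-page TIFF codec (little-endian, uncompressed, single-sample
# grayscale). Volumes are stored as 32-bit IEEE float pages, label maps as
# 16-bit unsigned pages; one strip per page. TIFF carries no voxel-spacing
# metadata in this dialect, so readers fall back to the caller's default.

tiff_type <- function(kind) {
  switch(kind,
         float32 = list(bits = 32L, fmt = 3L, size = 4L),
         uint16  = list(bits = 16L, fmt = 1L, size = 2L),
         stop("unsupported TIFF sample kind ", kind))
}

tiff_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value packed into 4 bytes
  val <- if (type == 3L) c(u16_raw(value), raw(2)) else u32_raw(value)
  c(u16_raw(tag), u16_raw(type), u32_raw(count), val)
}

write_tiff_stack <- function(data, path, kind = "float32") {
  d <- dim(data)                       # (z, y, x)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  tt <- tiff_type(kind)
  page_bytes <- nx * ny * tt$size
  n_entries <- 10L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  # layout: 8-byte header | nz pages of pixel data | nz IFDs
  data_off <- 8L
  ifd0_off <- data_off + nz * page_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42L, 0L))), con)
  writeBin(u32_raw(ifd0_off), con)
  for (z in seq_len(nz)) {
    sl <- data[z, , , drop = TRUE]
    dim(sl) <- c(ny, nx)
    v <- as.vector(t(sl))              # x fastest within each row
    if (kind == "uint16") {
      writeBin(u16_raw(v), con)
    } else {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    }
  }
  for (z in seq_len(nz)) {
    strip_off <- data_off + (z - 1L) * page_bytes
    next_off <- if (z < nz) ifd0_off + z * ifd_bytes else 0L
    ifd <- c(
      u16_raw(n_entries),
      tiff_entry(256L, 4L, 1L, nx),            # ImageWidth
      tiff_entry(257L, 4L, 1L, ny),            # ImageLength
      tiff_entry(258L, 3L, 1L, tt$bits),       # BitsPerSample
      tiff_entry(259L, 3L, 1L, 1L),            # Compression: none
      tiff_entry(262L, 3L, 1L, 1L),            # Photometric: BlackIsZero
      tiff_entry(273L, 4L, 1L, strip_off),     # StripOffsets
      tiff_entry(277L, 3L, 1L, 1L),            # SamplesPerPixel
      tiff_entry(278L, 4L, 1L, ny),            # RowsPerStrip
      tiff_entry(279L, 4L, 1L, page_bytes),    # StripByteCounts
      tiff_entry(339L, 3L, 1L, tt$fmt),        # SampleFormat
      u32_raw(next_off)
    )
    writeBin(ifd, con)
  }
  invisible(path)
}

read_tiff_stack <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 8L) fmt_error(path, "truncated TIFF")
  if (rawToChar(r[1:2]) != "II") fmt_error(path, "only little-endian TIFF supported")
  if (raw_u16(r, 3L) != 42) fmt_error(path, "bad TIFF magic")
  ifd_off <- raw_u32(r, 5L)
  slices <- list()
  dims <- NULL
  while (ifd_off != 0) {
    if (ifd_off + 2 > length(r)) fmt_error(path, "IFD offset out of range")
    ne <- raw_u16(r, ifd_off + 1L)
    tags <- list()
    for (i in seq_len(ne)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- raw_u16(r, e + 1L)
      type <- raw_u16(r, e + 3L)
      count <- raw_u32(r, e + 5L)
      inline_bytes <- count * switch(as.character(type),
                                     `1` = 1, `3` = 2, `4` = 4, 4)
      voff <- if (inline_bytes <= 4) e + 9L else raw_u32(r, e + 9L) + 1L
      vals <- switch(as.character(type),
                     `3` = raw_u16(r, voff, count),
                     `4` = raw_u32(r, voff, count),
                     `1` = as.integer(r[voff + seq_len(count) - 1L]),
                     raw_u32(r, e + 9L))
      tags[[as.character(tag)]] <- vals
    }
    need <- c("256", "257", "258", "273", "279")
    if (!all(need %in% names(tags))) fmt_error(path, "missing required TIFF tags")
    if (!is.null(tags[["259"]]) && tags[["259"]][1] != 1)
      fmt_error(path, "compressed TIFF not supported")
    nx <- tags[["256"]][1]; ny <- tags[["257"]][1]
    bits <- tags[["258"]][1]
    fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
    if (is.null(dims)) dims <- c(ny, nx)
    else if (!identical(dims, c(ny, nx)))
      fmt_error(path, "pages have differing sizes")
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    bytes <- unlist(lapply(seq_along(offs), function(k)
      r[offs[k] + seq_len(cnts[k])]))        # offsets are 0-based
    if (fmt == 3L && bits == 32L) {
      v <- readBin(bytes, "numeric", nx * ny, size = 4, endian = "little")
    } else if (fmt == 1L && bits == 16L) {
      v <- raw_u16(bytes, 1L, nx * ny)
    } else if (fmt == 1L && bits == 8L) {
      v <- as.integer(bytes[seq_len(nx * ny)])
    } else {
      fmt_error(path, sprintf("unsupported sample format %d/%d bits", fmt, bits))
    }
    slices[[length(slices) + 1L]] <- t(matrix(v, nrow = nx, ncol = ny))
    ifd_off <- raw_u32(r, ifd_off + 2L + ne * 12L + 1L)
  }
  nz <- length(slices)
  arr <- array(0, dim = c(nz, dims[1], dims[2]))
  for (z in seq_len(nz)) arr[z, , ] <- slices[[z]]
  arr
}
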