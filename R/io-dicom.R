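# Minimal DICOM reader for uncompressed single-frame CT slices, covering the
# two uncompressed little-endian transfer syntaxes (explicit and implicit VR).
# Enough of the standard is implemented to import a micro-CT series: geometry
# tags, rescale slope/intercept, and raw pixel data. DICOM distances are in
# millimeters and are converted to the package's micrometer convention.

dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# parse elements from `pos` on; explicit/implicit VR; stops at end of buffer
# or when leaving the given group (if only_group given). Returns list(tags, pos).
dcm_parse <- function(r, pos, explicit, path, only_group = NULL) {
  tags <- list()
  repeat {
    if (pos + 7L > length(r)) break
    group <- raw_u16(r, pos); elem <- raw_u16(r, pos + 2L)
    if (!is.null(only_group) && group != only_group) break
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(r[pos:(pos + 1L)])
      if (vr %in% dcm_long_vrs) {
        len <- raw_u32(r, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- raw_u16(r, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      vr <- "UN"
      len <- raw_u32(r, pos)
      pos <- pos + 4L
    }
    if (len == 4294967295)
      fmt_error(path, "undefined-length element (encapsulated pixel data?)")
    if (pos + len - 1L > length(r)) fmt_error(path, "truncated DICOM element")
    val <- if (len > 0) r[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    tags[[sprintf("%04x%04x", group, elem)]] <- list(vr = vr, bytes = val)
  }
  list(tags = tags, pos = pos)
}

dcm_read_file <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 132L || rawToChar(r[129:132]) != "DICM")
    fmt_error(path, "missing DICM preamble")
  meta <- dcm_parse(r, 133L, explicit = TRUE, path, only_group = 2L)
  ts <- meta$tags[["00020010"]]
  ts_uid <- if (is.null(ts)) "1.2.840.10008.1.2.1"
            else dcm_bytes_str(ts$bytes)
  explicit <- if (ts_uid == "1.2.840.10008.1.2") FALSE
              else if (ts_uid == "1.2.840.10008.1.2.1") TRUE
              else fmt_error(path, paste("unsupported transfer syntax", ts_uid))
  body <- dcm_parse(r, meta$pos, explicit, path)
  c(meta$tags, body$tags)
}

dcm_bytes_str <- function(b) {
  trimws(rawToChar(b[b != as.raw(0L)]))
}

dcm_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  dcm_bytes_str(t$bytes)
}

dcm_num <- function(tags, key, default = NULL) {
  s <- dcm_str(tags, key)
  if (is.null(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(tags, key, default = NULL) {
  t <- tags[[key]]
  if (is.null(t) || length(t$bytes) < 2L) return(default)
  raw_u16(t$bytes, 1L)
}

dcm_slice <- function(path) {
  tags <- dcm_read_file(path)
  rows <- dcm_us(tags, "00280010")
  cols <- dcm_us(tags, "00280011")
  if (is.null(rows) || is.null(cols)) fmt_error(path, "missing Rows/Columns")
  bits <- dcm_us(tags, "00280100", 16L)
  pixrep <- dcm_us(tags, "00280103", 0L)
  slope <- dcm_num(tags, "00281053", 1)[1]
  inter <- dcm_num(tags, "00281052", 0)[1]
  pxsp <- dcm_num(tags, "00280030")          # (row = y, col = x) mm
  ipp <- dcm_num(tags, "00200032")           # mm
  thick <- dcm_num(tags, "00180050")         # mm
  px <- tags[["7fe00010"]]
  if (is.null(px)) fmt_error(path, "missing PixelData")
  n <- rows * cols
  if (bits == 16L) {
    if (length(px$bytes) < 2L * n) fmt_error(path, "truncated PixelData")
    v <- raw_u16(px$bytes, 1L, n)
    if (pixrep == 1L) v <- ifelse(v > 32767, v - 65536, v)
  } else if (bits == 8L) {
    if (length(px$bytes) < n) fmt_error(path, "truncated PixelData")
    v <- as.integer(px$bytes[seq_len(n)])
  } else fmt_error(path, paste("unsupported BitsAllocated", bits))
  v <- v * slope + inter
  sl <- t(matrix(v, nrow = cols, ncol = rows))  # stored x fastest -> (y, x)
  list(data = sl, rows = rows, cols = cols, pixel_spacing = pxsp,
       position = ipp, thickness = thick)
}

read_dicom_series <- function(dir, default_spacing = 17.5) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no DICOM files found in ", dir)
  slices <- lapply(sort(files), dcm_slice)
  rows <- unique(vapply(slices, `[[`, 0, "rows"))
  cols <- unique(vapply(slices, `[[`, 0, "cols"))
  if (length(rows) != 1L || length(cols) != 1L)
    stop("inconsistent slice geometry in DICOM series '", dir,
         "': differing matrix sizes", call. = FALSE)
  zpos <- vapply(slices, function(s)
    if (is.null(s$position) || length(s$position) < 3) NA_real_
    else s$position[3], 0)
  if (all(is.finite(zpos)) && length(zpos) > 1L) {
    ord <- order(zpos)
    slices <- slices[ord]
    zpos <- zpos[ord]
    dz <- diff(zpos)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 0.01 * max(abs(dz)))
      stop("inconsistent slice geometry in DICOM series '", dir,
           "': non-uniform slice positions", call. = FALSE)
    zsp_mm <- dz[1]
  } else {
    zsp_mm <- slices[[1]]$thickness
  }
  nz <- length(slices)
  arr <- array(0, dim = c(nz, rows, cols))
  for (z in seq_len(nz)) arr[z, , ] <- slices[[z]]$data
  pxsp <- slices[[1]]$pixel_spacing
  if (is.null(pxsp) || is.null(zsp_mm) || !all(is.finite(c(pxsp, zsp_mm)))) {
    warning("DICOM spacing missing; assuming ", default_spacing,
            " um isotropic")
    sp <- rep(default_spacing, 3L)
  } else {
    sp <- c(zsp_mm, pxsp[1], pxsp[2]) * 1000   # mm -> um
  }
  org <- if (!is.null(slices[[1]]$position) &&
             length(slices[[1]]$position) == 3)
    rev(slices[[1]]$position) * 1000
  else c(0, 0, 0)
  list(data = arr, spacing = sp, origin = org)
}
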