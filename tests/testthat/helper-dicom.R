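# Minimal DICOM writer (explicit VR little endian) used only to build test
# fixtures; byte layout is written by hand so the package reader is checked
# against an independent encoder.

dcm_u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
dcm_u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                  (x %/% 65536) %% 256,
                                  (x %/% 16777216) %% 256))

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1)
    value_raw <- c(value_raw, if (vr %in% c("UI")) as.raw(0) else charToRaw(" "))
  hdr <- c(dcm_u16le(group), dcm_u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(hdr, as.raw(c(0, 0)), dcm_u32le(length(value_raw)), value_raw)
  } else {
    c(hdr, dcm_u16le(length(value_raw)), value_raw)
  }
}

dcm_ds <- function(group, elem, values)
  dcm_element(group, elem, "DS", charToRaw(paste(values, collapse = "\\")))
dcm_us_el <- function(group, elem, value)
  dcm_element(group, elem, "US", dcm_u16le(value))

# slice: integer matrix (y, x) of STORED values; intensity = slope*v + inter
write_dicom_slice <- function(path, slice, z_mm, pixel_spacing_mm,
                              thickness_mm, slope = 1, intercept = 0) {
  ny <- nrow(slice); nx <- ncol(slice)
  v <- as.integer(t(slice))            # x fastest
  v[v < 0] <- v[v < 0] + 65536L        # two's complement, signed 16-bit
  pix <- as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
  body <- c(
    dcm_element(0x0002, 0x0010, "UI",
                charToRaw("1.2.840.10008.1.2.1")),
    dcm_ds(0x0018, 0x0050, thickness_mm),
    dcm_ds(0x0020, 0x0032, c(0, 0, z_mm)),
    dcm_us_el(0x0028, 0x0010, ny),
    dcm_us_el(0x0028, 0x0011, nx),
    dcm_ds(0x0028, 0x0030, c(pixel_spacing_mm[1], pixel_spacing_mm[2])),
    dcm_us_el(0x0028, 0x0100, 16L),
    dcm_us_el(0x0028, 0x0103, 1L),
    dcm_ds(0x0028, 0x1052, intercept),
    dcm_ds(0x0028, 0x1053, slope),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}

make_dicom_series <- function(dir, data, spacing_um = 17.5, slope = 1,
                              intercept = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(data)
  sp_mm <- spacing_um / 1000
  for (z in seq_len(d[1])) {
    stored <- round((data[z, , ] - intercept) / slope)
    write_dicom_slice(file.path(dir, sprintf("slice_%03d.dcm", z)),
                      matrix(stored, d[2], d[3]), z_mm = (z - 1) * sp_mm,
                      pixel_spacing_mm = c(sp_mm, sp_mm),
                      thickness_mm = sp_mm, slope = slope,
                      intercept = intercept)
  }
  invisible(dir)
}
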