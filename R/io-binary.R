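# Small binary helpers shared by the NIfTI / TIFF / MHA / DICOM codecs.
# All formats here are little-endian.

u16_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(as.vector(rbind(x %% 256, (x %/% 256) %% 256)))
}

u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(as.vector(rbind(x %% 256, (x %/% 256) %% 256,
                         (x %/% 65536) %% 256, (x %/% 16777216) %% 256)))
}

raw_u16 <- function(r, off = 1L, n = 1L) {
  idx <- off + rep(seq(0, by = 2, length.out = n), each = 2) + c(0, 1)
  b <- as.integer(r[idx])
  b[seq(1, by = 2, length.out = n)] + 256 * b[seq(2, by = 2, length.out = n)]
}

raw_u32 <- function(r, off = 1L, n = 1L) {
  idx <- off + rep(seq(0, by = 4, length.out = n), each = 4) + 0:3
  b <- as.numeric(r[idx])
  m <- matrix(b, nrow = 4)
  m[1, ] + 256 * m[2, ] + 65536 * m[3, ] + 16777216 * m[4, ]
}

pad_char <- function(s, n) {
  r <- raw(n)
  b <- charToRaw(s)
  if (length(b) > n) b <- b[seq_len(n)]
  r[seq_along(b)] <- b
  r
}

fmt_error <- function(path, msg) {
  stop(sprintf("cannot read '%s': %s", path, msg), call. = FALSE)
}
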