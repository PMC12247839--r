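test_that("volume and label round trips are exact in every format", {
  set.seed(1)
  arr <- array(rnorm(1000, 5000, 2000), c(10, 10, 10))
  vol <- volume3d(arr, spacing = c(17.5, 17.5, 17.5), origin = c(1, 2, 3))
  for (fmt in c("nifti", "mha", "tiff_stack")) {
    path <- tempfile(fileext = switch(fmt, nifti = ".nii", mha = ".mha",
                                      tiff_stack = ".tif"))
    write_volume(vol, path, fmt)
    back <- suppressWarnings(read_volume(path, fmt))
    # volumes are stored as float32; compare at that precision
    expect_equal(back$data, arr, tolerance = 1e-6)
    if (fmt != "tiff_stack") {
      expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    }
  }
  labs <- label_volume(array(sample.int(6, 360, TRUE) - 1L, c(4, 9, 10)))
  for (fmt in c("nifti", "mha", "tiff_stack")) {
    path <- tempfile(fileext = switch(fmt, nifti = ".nii", mha = ".mha",
                                      tiff_stack = ".tif"))
    write_labels(labs, path, fmt)
    back <- suppressWarnings(read_labels(path, fmt))
    expect_identical(back$labels, labs$labels)
  }
})

test_that("label ids up to 65535 survive, spacing survives NIfTI", {
  labs <- array(0L, c(3, 4, 5))
  labs[1, 1, 1] <- 65535L
  labs[2, 2, 2] <- 1L
  lv <- label_volume(labs, spacing = c(10, 17.5, 25))
  p <- tempfile(fileext = ".nii")
  write_labels(lv, p)
  back <- read_labels(p)
  expect_identical(back$labels, labs)
  expect_equal(back$spacing, c(10, 17.5, 25), tolerance = 1e-6)
  # tiff stores uint16
  p2 <- tempfile(fileext = ".tif")
  write_labels(lv, p2, "tiff_stack")
  expect_identical(suppressWarnings(read_labels(p2))$labels, labs)
})

test_that("a generated 3-slice TIFF stack of zeros reads as zeros", {
  p <- tempfile(fileext = ".tif")
  write_volume(volume3d(array(0, c(3, 10, 10))), p)
  v <- suppressWarnings(read_volume(p))
  expect_identical(dim(v$data), c(3L, 10L, 10L))
  expect_true(all(v$data == 0))
  expect_warning(read_volume(p), "spacing")
})

test_that("DICOM series decodes rescale slope/intercept against raw bytes", {
  set.seed(7)
  arr <- array(round(rnorm(4 * 6 * 5, 4000, 1500)), c(4, 6, 5))
  dir <- tempfile("dcm")
  make_dicom_series(dir, arr, spacing_um = 17.5, slope = 2, intercept = -1000)
  v <- read_volume(dir, "dicom_series")
  expect_identical(dim(v$data), dim(arr))
  expect_equal(v$spacing, rep(17.5, 3), tolerance = 1e-9)
  # independent byte-level decode of one pixel of slice 2:
  # find the PixelData tag (7FE0,0010), VR OW, 2-byte reserved + 4-byte len
  f <- file.path(dir, "slice_002.dcm")
  r <- readBin(f, "raw", file.info(f)$size)
  tagpos <- NA
  for (i in seq_len(length(r) - 3)) {
    if (r[i] == as.raw(0xe0) && r[i + 1] == as.raw(0x7f) &&
        r[i + 2] == as.raw(0x10) && r[i + 3] == as.raw(0x00)) {
      tagpos <- i
      break
    }
  }
  expect_false(is.na(tagpos))
  data_off <- tagpos + 12              # tag(4) + VR(2) + reserved(2) + len(4)
  # pixel (y = 3, x = 2) is element (3-1)*nx + 2 = 12 in x-fastest order
  k <- (3 - 1) * 5 + 2
  lo <- as.integer(r[data_off + 2 * (k - 1)])
  hi <- as.integer(r[data_off + 2 * (k - 1) + 1])
  stored <- lo + 256 * hi
  if (stored > 32767) stored <- stored - 65536
  expect_equal(v$data[2, 3, 2], 2 * stored - 1000)
  expect_equal(v$data[2, 3, 2], arr[2, 3, 2])
})

test_that("inconsistent DICOM slice geometry raises a geometry error", {
  dir <- tempfile("dcm_bad")
  dir.create(dir)
  sl <- matrix(0L, 4, 4)
  write_dicom_slice(file.path(dir, "a.dcm"), sl, 0, c(0.0175, 0.0175), 0.0175)
  write_dicom_slice(file.path(dir, "b.dcm"), sl, 0.0175, c(0.0175, 0.0175), 0.0175)
  write_dicom_slice(file.path(dir, "c.dcm"), sl, 0.09, c(0.0175, 0.0175), 0.0175)
  expect_error(read_volume(dir, "dicom_series"), "geometry")
})

test_that("corrupt files raise format errors naming the file", {
  p <- tempfile(fileext = ".nii")
  writeBin(as.raw(1:50), p)
  expect_error(read_volume(p), basename(p), fixed = TRUE)
  p2 <- tempfile(fileext = ".mha")
  writeBin(charToRaw("garbage with no header"), p2)
  expect_error(read_volume(p2), "MHA|ElementDataFile")
})

test_that("window_mask applies a closed HU interval", {
  v <- volume3d(array(c(0, 2500, 20000, 30000, 3000, 100, 2499.5, 20000.5),
                      c(2, 2, 2)))
  m <- window_mask(v, 2500, 20000)
  expect_identical(as.vector(m),
                   c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(window_mask(volume3d(array(3000, c(3, 3, 3))))))
  expect_false(any(window_mask(volume3d(array(100, c(3, 3, 3))))))
  expect_error(window_mask(v, 5, 5), "lo")
})

test_that("window_mask widening is monotone", {
  set.seed(11)
  v <- volume3d(array(runif(27 * 8, 0, 25000), c(6, 6, 6)))
  m1 <- window_mask(v, 3000, 15000)
  m2 <- window_mask(v, 2500, 20000)
  expect_true(all(m2[m1]))
})

test_that("volume3d and label_volume enforce their invariants", {
  expect_error(volume3d(array(c(1, NA), c(1, 1, 2))), "finite")
  expect_error(volume3d(array(1, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
  expect_error(label_volume(array(-1L, c(2, 2, 2))), "non-negative")
  expect_error(bone_table(c(1, 1)), "unique")
  expect_error(bone_table(1, compartment = "femur"), "compartment")
})
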