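test_that("black top-hat matches the brute-force closing oracle", {
  set.seed(31)
  for (rep in 1:6) {
    d <- sample(6:16, 3, replace = TRUE)
    x <- array(runif(prod(d), 0, 10000), d)
    r <- sample(1:3, 1)
    got <- black_top_hat(volume3d(x), r)
    expect_equal(as.vector(got), as.vector(oracle_black_top_hat(x, r)),
                 tolerance = 1e-10)
  }
})

test_that("black top-hat basics: constants, embedded dark plane, positivity", {
  expect_true(all(black_top_hat(volume3d(array(5000, c(8, 8, 8))), 2) == 0))
  # bright block with an embedded 1-voxel dark plane
  x <- array(8000, c(11, 11, 11))
  x[6, , ] <- 0
  r <- black_top_hat(volume3d(x), 2)
  expect_true(all(r[6, , ] == 8000))
  expect_true(all(r[c(1, 2, 10, 11), , ] == 0))     # deep inside the block
  set.seed(33)
  xr <- array(runif(512, 0, 1), c(8, 8, 8))
  expect_true(all(black_top_hat(volume3d(xr), 3) >= 0))
})

test_that("sheetness prefers a dark plane over a dark ball and is polarity-selective", {
  bright <- 8000
  plane <- array(bright, c(24, 24, 24))
  plane[12:13, , ] <- 0                  # thickness-2 dark plate
  ball <- array(bright, c(24, 24, 24))
  co <- arrayInd(seq_len(24^3), c(24, 24, 24))
  d2 <- (co[, 1] - 12.5)^2 + (co[, 2] - 12.5)^2 + (co[, 3] - 12.5)^2
  ball[d2 <= 16] <- 0                    # radius-4 dark ball
  sp <- sheetness(plane)
  sb <- sheetness(ball)
  expect_gt(max(sp[12:13, 5:20, 5:20]), max(sb[10:15, 10:15, 10:15]))
  # intensity inversion: a bright plate in dark surround must not respond
  inv <- bright - plane
  si <- sheetness(inv)
  expect_lt(max(si[12:13, 5:20, 5:20]), 0.05 * max(sp[12:13, 5:20, 5:20]))
  # constant volume -> zero
  expect_true(all(sheetness(array(3000, c(10, 10, 10))) == 0))
})

test_that("sheetness is invariant to additive intensity shifts", {
  set.seed(37)
  x <- array(runif(14^3, 0, 8000), c(14, 14, 14))
  s1 <- sheetness(x)
  s2 <- sheetness(x + 12345)
  expect_equal(as.vector(s1), as.vector(s2), tolerance = 1e-8)
})

test_that("tensor voting bridges a hole in a plane of tokens", {
  sal <- array(0, c(13, 25, 25))
  co <- expand.grid(y = 1:25, x = 1:25)
  hole <- (co$y - 13)^2 + (co$x - 13)^2 <= 4   # diameter-4 hole
  for (k in seq_len(nrow(co)))
    if (!hole[k]) sal[7, co$y[k], co$x[k]] <- 1
  out <- tensor_voting(response_volume(sal, "sheetness"), sigma_v = 6,
                       threshold = 0.5)
  on_plane <- out[7, , ][!hole & (co$y - 13)^2 + (co$x - 13)^2 > 25]
  expect_gt(out[7, 13, 13], 0.5 * median(on_plane))
  # empty input -> all zero
  z <- tensor_voting(response_volume(array(0, c(8, 8, 8)), "sheetness"),
                     sigma_v = 2, threshold = 0.1)
  expect_true(all(z == 0))
})

test_that("tensor voting is equivariant under 90-degree rotations", {
  set.seed(41)
  sal <- array(0, c(12, 12, 12))
  sal[6, 3:10, 3:10] <- 1                # a plate normal to z
  rot <- aperm(sal, c(2, 1, 3))          # swap z and y axes
  a <- tensor_voting(response_volume(sal, "sheetness"), 2, threshold = 0.5)
  b <- tensor_voting(response_volume(rot, "sheetness"), 2, threshold = 0.5)
  expect_equal(as.vector(aperm(unclass(a), c(2, 1, 3))), as.vector(unclass(b)),
               tolerance = 1e-8)
})

test_that("tensor voting saliency vanishes beyond the kernel support", {
  sal <- array(0, c(30, 8, 8))
  sal[3, 4, 4] <- 1
  out <- tensor_voting(response_volume(sal, "sheetness"), sigma_v = 1.5,
                       threshold = 0.5)
  expect_true(all(out >= 0))
  expect_true(all(out[(3 + 7):30, , ] == 0))   # beyond 4 * sigma_v
})

test_that("dilate_mask implements cubic dilation", {
  m <- array(FALSE, c(9, 9, 9))
  m[5, 5, 5] <- TRUE
  d <- dilate_mask(m, 2)
  expect_identical(sum(d), 125L)
  expect_true(all(which(d) %in% which(oracle_bin_dilate(m, 2))))
  expect_identical(sum(dilate_mask(array(FALSE, c(5, 5, 5)), 2)), 0L)
  set.seed(43)
  mr <- array(runif(343) > 0.8, c(7, 7, 7))
  expect_true(all(dilate_mask(mr, 1)[mr]))     # extensivity
  # ball variant is a subset of the cube variant
  db <- dilate_mask(m, 2, "ball")
  expect_true(all(which(db) %in% which(d)))
  expect_lt(sum(db), sum(d))
})

test_that("combine_responses unions binarized sources then dilates", {
  z <- array(0, c(11, 11, 11))
  expect_true(all(combine_responses(response_volume(z, "bth"),
                                    thresholds = list(bth = 0.5)) == FALSE))
  # single supra-threshold dl voxel -> its 5x5x5 dilation
  dl <- z
  dl[6, 6, 6] <- 0.9
  out <- combine_responses(dl_prob = dl)
  expect_identical(sum(out), 125L)
  # union monotonicity: adding a source never removes a voxel
  b <- z; b[2, 2, 2] <- 10
  out2 <- combine_responses(response_volume(b, "bth"), dl_prob = dl,
                            thresholds = list(bth = 5))
  expect_true(all(which(out) %in% which(out2)))
  expect_error(combine_responses(response_volume(z, "bth"),
                                 response_volume(array(0, c(3, 3, 3)), "sheetness")),
               "shape")
})

test_that("joint mask on the default phantom covers gaps, not bone cores", {
  ph <- default_phantom()
  run <- default_pipeline_run()
  labs <- ph$truth$labels
  # true gap voxels: background within reach of two different labels
  gap_r <- as.integer(ceiling(ph$spec$gap_width / ph$spec$spacing))
  cover <- array(0L, dim(labs))
  for (id in label_ids(ph$truth))
    cover <- cover + (pawseg:::cpp_dilate_cube(
      pawseg:::as_dbl_arr(labs == id), gap_r) > 0)
  gap <- cover >= 2L & labs == 0L
  expect_gt(mean(run$joint[gap]), 0.95)
  # bone interior: truth eroded by 3 (inverse of background dilation)
  interior <- !(pawseg:::cpp_dilate_cube(pawseg:::as_dbl_arr(labs == 0L), 3L) > 0)
  expect_lt(mean(run$joint[interior]), 0.05)
})

test_that("otsu_threshold separates a bimodal sample", {
  set.seed(47)
  x <- c(rnorm(500, 10, 2), rnorm(500, 100, 10))
  thr <- otsu_threshold(x)
  expect_gt(thr, 20)
  expect_lt(thr, 80)
  expect_identical(otsu_threshold(numeric(0)), Inf)
})
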