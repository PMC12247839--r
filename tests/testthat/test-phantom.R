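test_that("default phantom has exactly 22 bones and is seed-deterministic", {
  ph <- default_phantom()
  expect_identical(length(label_ids(ph$truth)), 22L)
  expect_identical(nrow(ph$table), 22L)
  expect_setequal(ph$table$id, label_ids(ph$truth))
  ph2 <- generate_phantom(phantom_spec(seed = 101))
  expect_identical(ph$volume$data, ph2$volume$data)
  expect_identical(ph$truth$labels, ph2$truth$labels)
})

test_that("noise- and blur-free phantom is exactly two-valued", {
  sp <- phantom_spec(n_digits = 2, bones_per_digit = 2, cluster_bones = 2,
                     noise_sd = 0, blur_sigma = 0, seed = 3)
  ph <- generate_phantom(sp)
  bone <- ph$truth$labels > 0
  expect_true(all(ph$volume$data[bone] == sp$bone_intensity))
  expect_true(all(ph$volume$data[!bone] == sp$background_intensity))
})

test_that("thresholding a low-noise phantom recovers the exact bone count", {
  # gap >= 2 voxels, blur <= spacing/2, no noise: gaps survive discretization
  sp <- phantom_spec(noise_sd = 0, blur_sigma = 8, seed = 9)
  ph <- generate_phantom(sp)
  m <- window_mask(ph$volume)
  cc <- pawseg:::cpp_label_components(pawseg:::as_dbl_arr(m), 26L)
  expect_identical(max(cc), 22L)
})

test_that("truth labels are separated by at least the requested gap", {
  ph <- default_phantom()
  labs <- ph$truth$labels
  gap_vox <- ceiling(ph$spec$gap_width / ph$spec$spacing)
  # dilating every label by gap_vox - 1 must not make distinct labels touch
  r <- gap_vox - 1L
  ids <- label_ids(ph$truth)
  if (r > 0) {
    cover <- array(0L, dim(labs))
    for (id in ids)
      cover <- cover + (pawseg:::cpp_dilate_cube(
        pawseg:::as_dbl_arr(labs == id), r) > 0)
    expect_true(all(cover <= 1L))
  } else succeed()
})

test_that("fusion bridges the image but keeps truth labels distinct", {
  sp <- phantom_spec(seed = 13, noise_sd = 0)
  ph <- generate_phantom(sp)
  fused <- apply_fusion(ph, c(8L, 9L))
  expect_identical(label_ids(fused$truth), label_ids(ph$truth))
  m <- window_mask(fused$volume)
  cc <- pawseg:::cpp_label_components(pawseg:::as_dbl_arr(m), 26L)
  comp_a <- unique(cc[fused$truth$labels == 8L])
  comp_b <- unique(cc[fused$truth$labels == 9L])
  expect_true(length(intersect(comp_a, comp_b)) > 0)
  # only voxels between the pair changed, and only to bone intensity
  changed <- which(fused$volume$data != ph$volume$data)
  expect_true(length(changed) > 0)
  expect_true(all(fused$volume$data[changed] == sp$bone_intensity))
  expect_true(all(ph$truth$labels[changed] == 0L))
  # unrelated gap (digit 5 chain, bones 20/21) untouched: fusing it still works
  expect_error(apply_fusion(ph, c(1L, 22L)), "not adjacent")
})

test_that("erosion removes the requested voxel fraction surface-first", {
  sp <- phantom_spec(seed = 17, noise_sd = 0)
  ph <- generate_phantom(sp)
  n0 <- sum(ph$truth$labels == 10L)
  half <- apply_erosion(ph, 10L, 0.5)
  n1 <- sum(half$truth$labels == 10L)
  expect_true(abs(n1 - (n0 - round(0.5 * n0))) <= 1)
  # removed voxels are set to background in the image too
  removed <- ph$truth$labels == 10L & half$truth$labels == 0L
  expect_true(all(half$volume$data[removed] == sp$background_intensity))
  # surface-first: the surviving half contains the bone's deepest voxel
  d2 <- pawseg:::cpp_edt_sq(pawseg:::as_dbl_arr(ph$truth$labels == 10L))
  deepest <- which.max(d2)
  expect_identical(half$truth$labels[deepest], 10L)
  # fraction 1 deletes; fraction 0 is the identity
  gone <- apply_erosion(ph, 10L, 1)
  expect_false(10L %in% label_ids(gone$truth))
  same <- apply_erosion(ph, 10L, 0)
  expect_identical(same$truth$labels, ph$truth$labels)
  expect_error(apply_erosion(ph, 99L, 0.5), "unknown")
})

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(n_digits = 10, bones_per_digit = 3,
                            cluster_bones = 7), "33")
  expect_error(phantom_spec(gap_width = 0), "gap_width")
  expect_error(phantom_spec(bone_intensity = 2000), "2500")
  expect_error(generate_phantom(phantom_spec(shape = c(10, 10, 10))),
               "does not fit")
})

test_that("narrower gaps reduce the minimum inter-label separation", {
  sep_of <- function(gap) {
    ph <- generate_phantom(phantom_spec(seed = 23, gap_width = gap,
                                        noise_sd = 0))
    labs <- ph$truth$labels
    ids <- label_ids(ph$truth)
    # minimum background thickness between distinct labels, probed by dilation
    for (r in 1:6) {
      cover <- array(0L, dim(labs))
      for (id in ids)
        cover <- cover + (pawseg:::cpp_dilate_cube(
          pawseg:::as_dbl_arr(labs == id), r) > 0)
      if (any(cover >= 2L)) return(r)
    }
    7L
  }
  expect_lte(sep_of(35), sep_of(70))
})

test_that("phantom spec serialization round-trips", {
  sp <- phantom_spec(seed = 9, gap_width = 52.5,
                     fusion_pairs = list(c(8L, 9L)),
                     erosion_fraction = c(`3` = 0.25),
                     missing_bones = 22L, shape = c(50, 120, 80))
  p <- tempfile(fileext = ".cfg")
  write_phantom_spec(sp, p)
  back <- read_phantom_spec(p)
  expect_equal(back, sp)
  writeLines("blorp: 1", p)
  expect_error(read_phantom_spec(p), "unknown phantom spec key")
})
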