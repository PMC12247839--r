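test_that("derive_joint_truth matches the double-dilation oracle", {
  set.seed(201)
  for (rep in 1:5) {
    d <- sample(10:16, 3, replace = TRUE)
    lab <- random_label_map(d, sample(2:5, 1), seed = 200 + rep)
    ds <- sample(2:4, 1)
    got <- derive_joint_truth(lab, ds)
    want <- oracle_joint_truth(lab, ds)
    expect_identical(as.vector(got), as.vector(want))
  }
})

test_that("derive_joint_truth on two separated cubes yields a centered slab", {
  lab <- array(0L, c(20, 32, 20))
  lab[6:15, 6:15, 6:15] <- 1L
  lab[6:15, 18:27, 6:15] <- 2L            # 2-voxel gap at y = 16:17
  m <- derive_joint_truth(lab, 5L)
  expect_identical(as.vector(m), as.vector(oracle_joint_truth(lab, 5L)))
  expect_true(all(m[8:12, 16:17, 8:12]))   # the gap itself is covered
  # slab thickness: gap(2) + boundary(2) + 2*dilation(5) = 14 around y=16.5
  expect_true(all(m[10, 10:23, 10]))
  expect_false(any(m[10, c(1:7, 26:32), 10]))
  # single label -> empty with warning
  one <- array(0L, c(6, 6, 6)); one[2:4, 2:4, 2:4] <- 1L
  expect_warning(e <- derive_joint_truth(one), "fewer than 2")
  expect_false(any(e))
  # any background voxel next to two labels is included
  touch <- array(0L, c(5, 7, 5))
  touch[2:4, 2:3, 2:4] <- 1L
  touch[2:4, 5:6, 2:4] <- 2L
  mt <- derive_joint_truth(touch, 1L)
  expect_true(all(mt[2:4, 4, 2:4]))
})

test_that("tile extraction returns aligned, placement-ordered tiles", {
  ph <- default_phantom()
  jt <- derive_joint_truth(ph$truth, 5L)
  tiles <- extract_training_tiles(ph$volume, jt, n_tiles = 3, edge = 24)
  expect_length(tiles, 3L)
  for (tl in tiles) {
    expect_identical(dim(tl$image), c(24L, 24L, 24L))
    expect_identical(dim(tl$mask), c(24L, 24L, 24L))
    # image/mask from identical index ranges: re-extract and compare
    o <- tl$origin
    expect_identical(tl$image,
                     ph$volume$data[o[1]:(o[1] + 23), o[2]:(o[2] + 23),
                                    o[3]:(o[3] + 23)])
  }
  fg <- function(tl) mean(tl$image >= 2500)
  expect_gt(fg(tiles[[1]]), fg(tiles[[3]]))   # cluster denser than background
  # a volume smaller than the tile is padded
  small <- volume3d(array(3000, c(10, 10, 10)))
  tl <- extract_training_tiles(small, array(FALSE, c(10, 10, 10)),
                               n_tiles = 1, edge = 16)
  expect_identical(dim(tl[[1]]$image), c(16L, 16L, 16L))
})

test_that("validation split is deterministic, disjoint and correctly sized", {
  tiles <- as.list(1:120)
  sp <- split_validation(tiles, 0.25, seed = 5)
  expect_length(sp$val, 30L)
  expect_length(sp$train, 90L)
  expect_length(intersect(unlist(sp$train), unlist(sp$val)), 0L)
  sp2 <- split_validation(tiles, 0.25, seed = 5)
  expect_identical(unlist(sp$val), unlist(sp2$val))
  expect_length(split_validation(as.list(1:8), 0.25, seed = 1)$val, 2L)
  expect_error(split_validation(as.list(1:3), 0.25, 1), "at least 4")
})

test_that("unet forward pass has the right shape, range and determinism", {
  cfg <- net_config(base_channels = 2, depth = 3, patch = 12)
  m <- build_unet(cfg, seed = 4)
  expect_gt(m$n_parameters, 0)
  x <- array(rnorm(12^3, 5000, 2000), c(12, 12, 12))
  p <- pawseg:::unet_forward(m, x)$prob
  expect_identical(dim(p)[1:3], c(12L, 12L, 12L))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(is.finite(pawseg:::unet_forward(m, array(0, c(12, 12, 12)))$prob)))
  m2 <- build_unet(cfg, seed = 4)
  expect_identical(m$params, m2$params)
  m3 <- build_unet(cfg, seed = 5)
  expect_false(identical(m$params, m3$params))
  expect_error(net_config(depth = 3, patch = 50), "divisible")
})

test_that("dice and IoU agree with set arithmetic on hand-built masks", {
  p <- array(0, c(4, 4, 4)); t <- array(0, c(4, 4, 4))
  p[1:2, , ] <- 1; t[2:3, , ] <- 1
  # |P| = 32, |T| = 32, |P & T| = 16
  expect_equal(dice_coef(p, t, smooth = 0), 2 * 16 / 64, tolerance = 1e-6)
  expect_equal(iou(p, t), 16 / 48, tolerance = 1e-6)
  expect_equal(iou(t, t), 1)
  expect_equal(iou(array(0, c(4, 4, 4)), t), 0)
  expect_equal(iou(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))), 1)
  # loss/grad consistency at a point
  set.seed(7)
  pr <- array(runif(64), c(4, 4, 4))
  dl <- pawseg:::dice_loss_grad(pr, t)
  expect_equal(dl$loss, 1 - dice_coef(pr, t), tolerance = 1e-12)
})

test_that("lr = 0 leaves weights unchanged; degenerate masks warn", {
  tiles <- list(list(image = array(3000, c(8, 8, 8)),
                     mask = array(c(TRUE, FALSE), c(8, 8, 8))))
  cfg <- net_config(base_channels = 2, depth = 2, patch = 8)
  m <- build_unet(cfg, seed = 1)
  fit <- train_unet(m, tiles, cfg = train_config(lr = 0, epochs = 2,
                                                 patches_per_epoch = 1))
  expect_identical(fit$model$params, m$params)
  empty <- list(list(image = array(3000, c(8, 8, 8)),
                     mask = array(FALSE, c(8, 8, 8))))
  expect_warning(train_unet(m, empty,
                            cfg = train_config(lr = 0, epochs = 1,
                                               patches_per_epoch = 1)),
                 "degenerate")
})

test_that("tiled inference is shape-preserving and seam-free", {
  cfg <- net_config(base_channels = 2, depth = 2, patch = 8)
  m <- build_unet(cfg, seed = 2)
  # constant-output net: zero weights, bias -> sigmoid(b)
  for (nm in names(m$params)) m$params[[nm]]$W[] <- 0
  m$params$head$b[] <- 0.37
  x <- array(rnorm(40 * 30 * 25, 5000, 2000), c(40, 30, 25))
  out <- predict_tiled(m, x, tile_spec(16, 0))
  expect_identical(dim(out$prob), dim(x))
  expect_identical(out$n_tiles, 3L * 2L * 2L)
  expect_equal(max(abs(out$prob - pawseg:::sigmoid(0.37))), 0, tolerance = 1e-12)
  # a real net: output in [0,1], deterministic, mask consistent
  m2 <- build_unet(cfg, seed = 3)
  o1 <- predict_tiled(m2, x, tile_spec(16, 0))
  o2 <- predict_tiled(m2, x, tile_spec(16, 0))
  expect_identical(o1$prob, o2$prob)
  expect_true(all(o1$prob >= 0 & o1$prob <= 1))
  expect_identical(o1$mask, o1$prob > 0.5)
  expect_error(predict_tiled(m2, x, tile_spec(15, 0)), "divisible")
})

test_that("model save/load round trip preserves weights and sidecar", {
  cfg <- net_config(base_channels = 2, depth = 2, patch = 8)
  m <- build_unet(cfg, seed = 9)
  p <- tempfile(fileext = ".rds")
  hist <- data.frame(epoch = 1:2, dice_loss = c(0.9, 0.5), val_iou = c(0.1, 0.2))
  save_model(m, p, train_config(), hist)
  m2 <- load_model(p)
  expect_identical(m2$params, m$params)
  expect_true(file.exists(paste0(p, ".json")))
  expect_true(file.exists(paste0(p, ".history.csv")))
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(side$net$base_channels, 2)
})
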