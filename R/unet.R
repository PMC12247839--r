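#' 3D U-Net configuration
#'
#' Encoder-decoder with skip connections; encoder stages follow the
#' ResNet-18 pattern (two 2-convolution residual blocks per resolution
#' level) in 3D. Channel width doubles per level. The output is a
#' single-channel sigmoid probability.
#'
#' @param base_channels channels at the finest level (full-scale nets are
#'   wider; the desk-scale default is 8).
#' @param depth number of resolution levels (default 3).
#' @param patch training patch edge in voxels; must be divisible by
#'   `2^(depth - 1)` (canonical protocol: 96).
#' @param norm_center,norm_scale input normalization `(HU - center)/scale`
#'   applied before the first convolution.
#' @return a `net_config`.
#' @export
net_config <- function(base_channels = 8L, depth = 3L, patch = 96L,
                       norm_center = 2500, norm_scale = 17500) {
  if (depth < 1L) stop("depth must be >= 1")
  if (patch %% 2^(depth - 1) != 0)
    stop("patch (", patch, ") must be divisible by 2^(depth-1) = ",
         2^(depth - 1))
  structure(list(base_channels = as.integer(base_channels),
                 depth = as.integer(depth), patch = as.integer(patch),
                 norm_center = norm_center, norm_scale = norm_scale),
            class = "net_config")
}

#' Training configuration
#'
#' Dice training loss, IoU validation metric, Adam optimization with initial
#' learning rate 1e-4, randomly initialized weights; the canonical protocol
#' runs 500 epochs on GPU, the desk-scale default is 50.
#'
#' @param lr Adam learning rate (default 1e-4).
#' @param epochs training epochs (default 50; set 500 for the full-scale
#'   protocol).
#' @param val_fraction validation tile fraction (default 0.25).
#' @param patches_per_epoch gradient steps per epoch (default 4).
#' @param batch_size patches whose gradients are averaged per step
#'   (default 1).
#' @param fg_fraction fraction of patches forced to contain at least one
#'   joint voxel (default 0.5).
#' @param subvolume_edge,subvolumes_per_paw tile extraction protocol
#'   defaults (200, 3).
#' @param early_stop_loss optional: stop once the epoch-mean training Dice
#'   loss drops below this.
#' @param early_stop_iou optional: stop once the validation IoU reaches
#'   this level (the best-IoU weights are retained either way).
#' @param val_every validate every this many epochs (default 1); epochs
#'   without validation report `NA` IoU.
#' @param seed RNG seed for initialization, patch sampling and the split.
#' @return a `train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 50L, val_fraction = 0.25,
                         patches_per_epoch = 4L, batch_size = 1L,
                         fg_fraction = 0.5,
                         subvolume_edge = 200L, subvolumes_per_paw = 3L,
                         early_stop_loss = NULL, early_stop_iou = NULL,
                         val_every = 1L, seed = 1L) {
  if (lr < 0) stop("lr must be >= 0")
  if (!(val_fraction > 0 && val_fraction < 1))
    stop("val_fraction must be in (0, 1)")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 val_fraction = val_fraction,
                 patches_per_epoch = as.integer(patches_per_epoch),
                 batch_size = as.integer(batch_size),
                 fg_fraction = fg_fraction,
                 subvolume_edge = as.integer(subvolume_edge),
                 subvolumes_per_paw = as.integer(subvolumes_per_paw),
                 early_stop_loss = early_stop_loss,
                 early_stop_iou = early_stop_iou,
                 val_every = as.integer(val_every), seed = as.integer(seed)),
            class = "train_config")
}

he_init <- function(k, cin, cout) {
  sd <- sqrt(2 / (k^3 * cin))
  array(rnorm(k^3 * cin * cout, 0, sd), dim = c(k, k, k, cin, cout))
}

new_conv <- function(k, cin, cout, norm = TRUE) {
  out <- list(W = he_init(k, cin, cout), b = numeric(cout))
  if (norm) {
    out$gamma <- rep(1, cout)
    out$beta <- numeric(cout)
  }
  out
}

#' Build a 3D U-Net with a ResNet-18-style encoder
#'
#' Every convolution except the output head is followed by instance
#' normalization (batch size is one, so this is the batch-norm slot of the
#' ResNet block pattern) and ReLU; without normalization the sigmoid head
#' saturates on class-imbalanced Dice training.
#'
#' @param cfg a [net_config()].
#' @param seed RNG seed; identical seeds give identical initial weights.
#' @return a `unet` model handle (parameter list + config).
#' @export
build_unet <- function(cfg = net_config(), seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  with_seed(seed, {
    C <- cfg$base_channels
    D <- cfg$depth
    ch <- C * 2^(seq_len(D) - 1)
    p <- list(stem = new_conv(3, 1, ch[1]))
    for (l in seq_len(D)) {
      for (bl in 1:2) {
        p[[sprintf("enc%d_b%d_c1", l, bl)]] <- new_conv(3, ch[l], ch[l])
        p[[sprintf("enc%d_b%d_c2", l, bl)]] <- new_conv(3, ch[l], ch[l])
      }
      if (l < D) p[[sprintf("down%d", l)]] <- new_conv(3, ch[l], ch[l + 1])
    }
    if (D > 1) {
      for (l in (D - 1):1) {
        p[[sprintf("up%d_reduce", l)]] <- new_conv(3, ch[l + 1], ch[l])
        p[[sprintf("up%d_m1", l)]] <- new_conv(3, 2 * ch[l], ch[l])
        p[[sprintf("up%d_m2", l)]] <- new_conv(3, ch[l], ch[l])
      }
    }
    p$head <- new_conv(1, ch[1], 1, norm = FALSE)
    n_par <- sum(vapply(p, function(q) sum(lengths(q)), 0))
    structure(list(cfg = cfg, params = p, n_parameters = n_par),
              class = "unet")
  })
}

#' @export
print.unet <- function(x, ...) {
  cat(sprintf("<unet> depth %d, base %d channels, %s parameters\n",
              x$cfg$depth, x$cfg$base_channels,
              format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

# convolution via im2col + GEMM (BLAS); keep = TRUE retains the unfolded
# input matrix for the backward pass. Large inputs (inference on big tiles)
# are unfolded in slabs along x so the im2col matrix stays bounded.
conv_fwd <- function(pq, x, stride = 1L, pad = 1L, keep = FALSE,
                     max_unfold = 3e7) {
  k <- dim(pq$W)[1]
  cin <- dim(pq$W)[4]
  cout <- dim(pq$W)[5]
  d <- dim(x)
  zo <- (d[1] + 2 * pad - k) %/% stride + 1L
  yo <- (d[2] + 2 * pad - k) %/% stride + 1L
  xo <- (d[3] + 2 * pad - k) %/% stride + 1L
  if (keep || prod(c(zo, yo, xo)) * k^3 * cin <= max_unfold) {
    X2 <- cpp_im2col(x, k, stride, pad)
    Ym <- X2 %*% matrix(pq$W, ncol = cout)
    if (any(pq$b != 0)) Ym <- Ym + rep(pq$b, each = nrow(Ym))
    dim(Ym) <- c(zo, yo, xo, cout)
    return(list(out = Ym, X2 = if (keep) X2, in_dim = d))
  }
  # large tiles: direct C++ convolution, no unfolded matrix
  out <- cpp_conv3d_direct(x, pq$W, pq$b, stride, pad)
  list(out = out, X2 = NULL, in_dim = d)
}

conv_bwd <- function(pq, cc, gy, stride = 1L, pad = 1L) {
  k <- dim(pq$W)[1]
  cout <- dim(pq$W)[5]
  GYm <- matrix(gy, ncol = cout)
  gW <- crossprod(cc$X2, GYm)
  dim(gW) <- dim(pq$W)
  gb <- colSums(GYm)
  gXm <- tcrossprod(GYm, matrix(pq$W, ncol = cout))
  gx <- cpp_col2im(gXm, cc$in_dim, k, stride, pad)
  list(W = gW, b = gb, gx = gx)
}

# instance normalization, inference path: no cached normalized activations,
# channel-scalar arithmetic to limit temporaries on large tiles
in_f_light <- function(a, gamma, beta, eps = 1e-5) {
  d <- dim(a)
  n <- prod(d[1:3]); C <- d[4]
  mu <- .colMeans(a, n, C)
  v <- .colMeans(a * a, n, C) - mu^2
  istd <- 1 / sqrt(pmax(v, 0) + eps)
  sc <- gamma * istd
  sh <- beta - mu * sc
  if (C == 1L) {
    y <- a * sc + sh
  } else {
    y <- a * rep(sc, each = n) + rep(sh, each = n)
  }
  dim(y) <- d
  y
}

# instance normalization (per channel over the spatial dims)
in_f <- function(a, gamma, beta, eps = 1e-5) {
  d <- dim(a)
  n <- prod(d[1:3]); C <- d[4]
  m <- matrix(a, nrow = n, ncol = C)
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu^2
  istd <- 1 / sqrt(pmax(v, 0) + eps)
  xh <- (m - rep(mu, each = n)) * rep(istd, each = n)
  y <- xh * rep(gamma, each = n) + rep(beta, each = n)
  dim(y) <- d
  list(y = y, xhat = xh, istd = istd)
}

in_b <- function(gy, xhat, istd, gamma) {
  d <- dim(gy)
  n <- prod(d[1:3]); C <- d[4]
  gm <- matrix(gy, nrow = n, ncol = C)
  dgamma <- colSums(gm * xhat)
  dbeta <- colSums(gm)
  gxh <- gm * rep(gamma, each = n)
  mg <- colMeans(gxh)
  mgx <- colMeans(gxh * xhat)
  ga <- (gxh - rep(mg, each = n) - xhat * rep(mgx, each = n)) *
    rep(istd, each = n)
  dim(ga) <- d
  list(ga = ga, dgamma = dgamma, dbeta = dbeta)
}

as_t4 <- function(x) {                  # (Z,Y,X) -> (Z,Y,X,1)
  dim(x) <- c(dim(x), 1L)
  x
}

# Forward pass. keep = TRUE caches intermediates for backprop.
unet_forward <- function(model, x, keep = FALSE) {
  cfg <- model$cfg
  p <- model$params
  D <- cfg$depth
  if (length(dim(x)) == 3L) x <- as_t4(x)
  x <- (x - cfg$norm_center) / cfg$norm_scale
  cache <- if (keep) list(x0 = x) else NULL
  # large inference tiles: collect eagerly so transient feature maps do not
  # pile up (a 352^3 map is ~350 MB)
  maybe_gc <- if (!keep && prod(dim(x)) > 2e7) function() gc(FALSE)
              else function() invisible(NULL)
  # conv -> instance norm -> relu
  cnr_f <- function(nm, h, stride = 1L) {
    cf <- conv_fwd(p[[nm]], h, stride = stride, keep = keep)
    if (!keep) return(relu(in_f_light(cf$out, p[[nm]]$gamma, p[[nm]]$beta)))
    nf <- in_f(cf$out, p[[nm]]$gamma, p[[nm]]$beta)
    out <- relu(nf$y)
    cache[[nm]] <<- list(X2 = cf$X2, in_dim = cf$in_dim,
                         xhat = nf$xhat, istd = nf$istd, out = out)
    out
  }
  res_f <- function(nm, h) {
    r1 <- cnr_f(paste0(nm, "_c1"), h)
    nm2 <- paste0(nm, "_c2")
    cf2 <- conv_fwd(p[[nm2]], r1, keep = keep)
    if (!keep) {
      y <- in_f_light(cf2$out, p[[nm2]]$gamma, p[[nm2]]$beta)
      y <- y + h
      return(relu(y))
    }
    nf2 <- in_f(cf2$out, p[[nm2]]$gamma, p[[nm2]]$beta)
    out <- relu(nf2$y + h)
    cache[[nm2]] <<- list(X2 = cf2$X2, in_dim = cf2$in_dim,
                          xhat = nf2$xhat, istd = nf2$istd,
                          out = out)
    out
  }
  h <- cnr_f("stem", x)
  if (!keep) rm(x)
  maybe_gc()
  skips <- vector("list", D)
  for (l in seq_len(D)) {
    h <- res_f(sprintf("enc%d_b1", l), h)
    if (l == 1L) maybe_gc()
    h <- res_f(sprintf("enc%d_b2", l), h)
    if (l == 1L) maybe_gc()
    if (l < D) {
      skips[[l]] <- h
      h <- cnr_f(sprintf("down%d", l), h, stride = 2L)
      maybe_gc()
    }
  }
  if (D > 1) {
    for (l in (D - 1):1) {
      hu <- cpp_upsample_nn(h, 2L)
      hr <- cnr_f(sprintf("up%d_reduce", l), hu)
      dm <- dim(hr)
      hc <- array(0, c(dm[1:3], dm[4] + dim(skips[[l]])[4]))
      hc[, , , seq_len(dm[4])] <- hr
      hc[, , , dm[4] + seq_len(dim(skips[[l]])[4])] <- skips[[l]]
      rm(hr)
      skips[l] <- list(NULL)
      maybe_gc()
      m1 <- cnr_f(sprintf("up%d_m1", l), hc)
      rm(hc)
      maybe_gc()
      m2 <- cnr_f(sprintf("up%d_m2", l), m1)
      rm(m1)
      maybe_gc()
      if (keep) cache[[sprintf("up%d_dims", l)]] <- list(nr = dm[4])
      h <- m2
    }
  }
  cfh <- conv_fwd(p$head, h, pad = 0L, keep = keep)
  prob <- sigmoid(cfh$out)
  if (keep) {
    cache$head <- cfh
    cache$prob <- prob
  }
  list(prob = prob, cache = cache)
}

# Backward pass from d(loss)/d(prob); returns gradient list shaped like params.
unet_backward <- function(model, fwd, gprob) {
  cfg <- model$cfg
  p <- model$params
  D <- cfg$depth
  cache <- fwd$cache
  g <- list()
  gz <- gprob * cache$prob * (1 - cache$prob)
  bwh <- conv_bwd(p$head, cache$head, gz, pad = 0L)
  g$head <- list(W = bwh$W, b = bwh$b)
  gh <- bwh$gx
  # backward through a conv-IN-relu unit; returns gradient wrt its input
  cnr_b <- function(nm, gout, stride = 1L) {
    cc <- cache[[nm]]
    gy <- gout * (cc$out > 0)
    ib <- in_b(gy, cc$xhat, cc$istd, p[[nm]]$gamma)
    bw <- conv_bwd(p[[nm]], cc, ib$ga, stride = stride)
    g[[nm]] <<- list(W = bw$W, b = bw$b, gamma = ib$dgamma,
                     beta = ib$dbeta)
    bw$gx
  }
  res_b <- function(nm, gout) {
    nm2 <- paste0(nm, "_c2")
    cc2 <- cache[[nm2]]
    gs <- gout * (cc2$out > 0)
    ib2 <- in_b(gs, cc2$xhat, cc2$istd, p[[nm2]]$gamma)
    bw2 <- conv_bwd(p[[nm2]], cc2, ib2$ga)
    g[[nm2]] <<- list(W = bw2$W, b = bw2$b, gamma = ib2$dgamma,
                      beta = ib2$dbeta)
    gs + cnr_b(paste0(nm, "_c1"), bw2$gx)
  }
  if (D > 1) {
    for (l in seq_len(D - 1)) {
      gm1 <- cnr_b(sprintf("up%d_m2", l), gh)
      ghc <- cnr_b(sprintf("up%d_m1", l), gm1)
      nr <- cache[[sprintf("up%d_dims", l)]]$nr
      ghr <- ghc[, , , seq_len(nr), drop = FALSE]
      cache[[sprintf("gskip%d", l)]] <-
        ghc[, , , nr + seq_len(dim(ghc)[4] - nr), drop = FALSE]
      ghu <- cnr_b(sprintf("up%d_reduce", l), ghr)
      gh <- cpp_upsample_nn_bwd(ghu, 2L)
    }
  }
  # gh now sits at the bottleneck; walk the encoder backwards
  for (l in D:1) {
    if (l < D) {
      gh <- cnr_b(sprintf("down%d", l), gh, stride = 2L)
      gh <- gh + cache[[sprintf("gskip%d", l)]]
    }
    gh <- res_b(sprintf("enc%d_b2", l), gh)
    gh <- res_b(sprintf("enc%d_b1", l), gh)
  }
  cnr_b("stem", gh)
  g
}

#' Dice coefficient and IoU
#'
#' Set-overlap measures between a predicted mask/probability map and a
#' reference mask. `dice_coef` uses soft probabilities with an additive
#' smoothing term; `iou` is computed on the binarized prediction. A perfect
#' prediction has IoU 1; an all-background prediction against a non-empty
#' reference has IoU 0.
#'
#' @param pred numeric probabilities or binary mask.
#' @param truth binary mask.
#' @param smooth additive smoothing (default 1).
#' @return scalar in `[0, 1]`.
#' @export
dice_coef <- function(pred, truth, smooth = 1) {
  p <- as.numeric(pred); t <- as.numeric(truth != 0)
  (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

#' @rdname dice_coef
#' @param threshold binarization level for probabilities (default 0.5).
#' @export
iou <- function(pred, truth, threshold = 0.5) {
  p <- as.numeric(pred) > threshold
  t <- as.numeric(truth) != 0
  u <- sum(p | t)
  if (u == 0) return(1)
  sum(p & t) / u
}

dice_loss_grad <- function(prob, truth, smooth = 1) {
  p <- as.numeric(prob); t <- as.numeric(truth != 0)
  denom <- sum(p) + sum(t) + smooth
  num <- 2 * sum(p * t) + smooth
  loss <- 1 - num / denom
  gp <- -(2 * t * denom - num) / denom^2
  dim(gp) <- dim(prob)
  list(loss = loss, grad = gp)
}

adam_init <- function(params) {
  lapply(params, function(q)
    lapply(q, function(a) list(m = a * 0, v = a * 0)))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    for (pn in names(params[[nm]])) {
      gr <- grads[[nm]][[pn]]
      if (is.null(gr)) next
      st <- state[[nm]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * gr
      st$v <- beta2 * st$v + (1 - beta2) * gr^2
      params[[nm]][[pn]] <- params[[nm]][[pn]] - lr * (st$m / bc1) /
        (sqrt(st$v / bc2) + eps)
      state[[nm]][[pn]] <- st
    }
  }
  list(params = params, state = state)
}

sample_patch <- function(tile, patch, force_fg) {
  d <- dim(tile$image)
  if (any(d < patch)) stop("tile smaller than patch")
  pick <- function() vapply(1:3, function(a)
    if (d[a] == patch) 1L else sample.int(d[a] - patch + 1L, 1L), 0L)
  o <- pick()
  if (force_fg && any(tile$mask)) {
    for (try in 1:20) {
      sl <- lapply(1:3, function(a) o[a]:(o[a] + patch - 1L))
      if (any(tile$mask[sl[[1]], sl[[2]], sl[[3]]])) break
      o <- pick()
    }
  }
  sl <- lapply(1:3, function(a) o[a]:(o[a] + patch - 1L))
  list(image = tile$image[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
       mask = tile$mask[sl[[1]], sl[[2]], sl[[3]], drop = FALSE])
}

eval_iou_tiles <- function(model, tiles) {
  if (length(tiles) == 0L) return(NA_real_)
  f <- 2^(model$cfg$depth - 1)
  vals <- vapply(tiles, function(tl) {
    d <- dim(tl$image)
    dcrop <- (d %/% f) * f
    sl <- lapply(1:3, function(a) seq_len(dcrop[a]))
    img <- tl$image[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    msk <- tl$mask[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    pr <- unet_forward(model, img, keep = FALSE)$prob
    iou(pr, msk)
  }, 0)
  mean(vals)
}

#' Train the joint-space U-Net
#'
#' Random `patch`-sized crops are sampled from the training tiles each epoch
#' (half forced to contain joint voxels), optimized with Adam on the Dice
#' loss; validation IoU is tracked per epoch and the best-IoU weights are
#' retained.
#'
#' @param model a [build_unet()] handle.
#' @param train_tiles,val_tiles lists of `list(image, mask)` tiles.
#' @param cfg a [train_config()].
#' @return `list(model, history)`; `history` is a per-epoch data frame with
#'   columns `epoch`, `dice_loss`, `val_iou`.
#' @export
train_unet <- function(model, train_tiles, val_tiles = list(),
                       cfg = train_config()) {
  stopifnot(inherits(model, "unet"), inherits(cfg, "train_config"))
  if (length(train_tiles) == 0L) stop("empty training set")
  if (!any(vapply(train_tiles, function(t) any(t$mask), TRUE)))
    warning("no joint voxels in any training tile; Dice is degenerate ",
            "(smoothing term only)")
  patch <- model$cfg$patch
  with_seed(cfg$seed, {
    state <- adam_init(model$params)
    hist <- data.frame(epoch = integer(0), dice_loss = numeric(0),
                       val_iou = numeric(0))
    best <- list(iou = -Inf, params = model$params)
    t_adam <- 0L
    for (ep in seq_len(cfg$epochs)) {
      losses <- numeric(0)
      for (s in seq_len(cfg$patches_per_epoch)) {
        acc <- NULL
        for (bi in seq_len(cfg$batch_size)) {
          tl <- train_tiles[[sample.int(length(train_tiles), 1L)]]
          force_fg <- runif(1) < cfg$fg_fraction
          pt <- sample_patch(tl, patch, force_fg)
          fwd <- unet_forward(model, pt$image, keep = TRUE)
          dl <- dice_loss_grad(fwd$prob, pt$mask)
          losses <- c(losses, dl$loss)
          if (cfg$lr > 0) {
            grads <- unet_backward(model, fwd, dl$grad)
            acc <- if (is.null(acc)) grads else
              mapply(function(a, g) Map(`+`, a, g), acc, grads,
                     SIMPLIFY = FALSE)
          }
        }
        if (cfg$lr > 0) {
          acc <- lapply(acc, function(a)
            lapply(a, function(x) x / cfg$batch_size))
          t_adam <- t_adam + 1L
          up <- adam_step(model$params, acc, state, cfg$lr, t_adam)
          model$params <- up$params
          state <- up$state
        }
      }
      vi <- if (ep %% cfg$val_every == 0L || ep == cfg$epochs)
        eval_iou_tiles(model, val_tiles) else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, dice_loss = mean(losses),
                                     val_iou = vi))
      if (!is.na(vi) && vi > best$iou)
        best <- list(iou = vi, params = model$params)
      if (!is.null(cfg$early_stop_loss) &&
          mean(losses) < cfg$early_stop_loss) break
      if (!is.null(cfg$early_stop_iou) && !is.na(vi) &&
          vi >= cfg$early_stop_iou) break
    }
    if (length(val_tiles) > 0L && is.finite(best$iou))
      model$params <- best$params
    list(model = model, history = hist)
  })
}

#' Tile specification for inference
#'
#' @param tile_edge tile edge in voxels (default 352, the canonical
#'   inference tiling).
#' @param overlap overlap between adjacent tiles (default 0).
#' @param pad_mode `"edge"` (replicate border) or `"zero"` for partial edge
#'   tiles.
#' @return a `tile_spec`.
#' @export
tile_spec <- function(tile_edge = 352L, overlap = 0L, pad_mode = "edge") {
  if (!(tile_edge > overlap && overlap >= 0))
    stop("need tile_edge > overlap >= 0")
  structure(list(tile_edge = as.integer(tile_edge),
                 overlap = as.integer(overlap), pad_mode = pad_mode),
            class = "tile_spec")
}

#' Tiled (sliding-window) inference
#'
#' Partitions a volume into tiles (non-overlapping by default), runs a
#' forward pass per tile, and stitches the probability output back to the
#' input shape; edge tiles are padded to the tile size and the padding is
#' cropped from the output. Overlapping configurations average the
#' overlapped predictions.
#'
#' @param model a trained [build_unet()] handle.
#' @param volume a [volume3d()] or 3D array.
#' @param tiles a [tile_spec()].
#' @param threshold binarization level (default 0.5).
#' @return `list(prob, mask, n_tiles)`: probability array in `[0, 1]`,
#'   logical mask, and the number of tiles processed.
#' @export
predict_tiled <- function(model, volume, tiles = tile_spec(),
                          threshold = 0.5) {
  x <- if (inherits(volume, "volume3d")) volume$data else volume
  d <- dim(x)
  te <- tiles$tile_edge
  f <- 2^(model$cfg$depth - 1)
  if (te %% f != 0)
    stop("tile_edge (", te, ") must be divisible by the net's downsampling ",
         "factor ", f)
  step <- te - tiles$overlap
  starts <- lapply(1:3, function(a) {
    s <- seq(1L, max(1L, d[a] - tiles$overlap), by = step)
    s[s <= max(1L, d[a])]
  })
  prob <- array(0, d)
  # overlap-free tiling writes each voxel once; skip the weight accumulator
  wsum <- if (tiles$overlap > 0L) array(0, d)
  n_tiles <- 0L
  for (oz in starts[[1]]) for (oy in starts[[2]]) for (ox in starts[[3]]) {
    n_tiles <- n_tiles + 1L
    ez <- min(d[1], oz + te - 1L); ey <- min(d[2], oy + te - 1L)
    ex <- min(d[3], ox + te - 1L)
    sub <- x[oz:ez, oy:ey, ox:ex, drop = FALSE]
    ds <- dim(sub)
    if (any(ds < te)) {
      padded <- array(0, c(te, te, te))
      padded[seq_len(ds[1]), seq_len(ds[2]), seq_len(ds[3])] <- sub
      if (tiles$pad_mode == "edge") {
        if (ds[1] < te) padded[(ds[1] + 1):te, , ] <-
            padded[rep(ds[1], te - ds[1]), , ]
        if (ds[2] < te) padded[, (ds[2] + 1):te, ] <-
            padded[, rep(ds[2], te - ds[2]), ]
        if (ds[3] < te) padded[, , (ds[3] + 1):te] <-
            padded[, , rep(ds[3], te - ds[3])]
      }
      sub <- padded
    }
    pr <- unet_forward(model, sub, keep = FALSE)$prob
    rm(sub)
    if (te^3 > 2e7) gc(FALSE)
    dim(pr) <- c(te, te, te)
    pr <- pr[seq_len(ds[1]), seq_len(ds[2]), seq_len(ds[3]), drop = FALSE]
    if (is.null(wsum)) {
      prob[oz:ez, oy:ey, ox:ex] <- pr
    } else {
      prob[oz:ez, oy:ey, ox:ex] <- prob[oz:ez, oy:ey, ox:ex] + pr
      wsum[oz:ez, oy:ey, ox:ex] <- wsum[oz:ez, oy:ey, ox:ex] + 1
    }
  }
  if (!is.null(wsum)) prob <- prob / wsum
  list(prob = prob, mask = prob > threshold, n_tiles = n_tiles)
}

#' Save / load a trained model
#'
#' Weights go into an RDS container; a JSON sidecar records the network and
#' (optionally) training configuration plus seeds for provenance.
#'
#' @param model a `unet`.
#' @param path checkpoint path (`.rds`).
#' @param train_cfg optional [train_config()] stored in the sidecar.
#' @param history optional training history, written as CSV next to the
#'   checkpoint.
#' @return the path, invisibly.
#' @export
save_model <- function(model, path, train_cfg = NULL, history = NULL) {
  saveRDS(model, path)
  side <- list(net = unclass(model$cfg), n_parameters = model$n_parameters)
  if (!is.null(train_cfg)) side$train <- unclass(train_cfg)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  if (!is.null(history))
    utils::write.csv(history, paste0(path, ".history.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "unet")) stop("not a unet checkpoint: ", path)
  m
}
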