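#' Derive ground-truth joint space from bone labels
#'
#' The joint space is the peri-articular negative space: voxels where the
#' dilations (half-kernel `dilation_size`) of two DIFFERENT labels intersect,
#' restricted to background and bone-boundary voxels, then grown by a further
#' dilation of the same size (thickness and lateral extent).
#'
#' @param labels a [label_volume()] or integer 3D array.
#' @param dilation_size dilation half-size in voxels (default 5).
#' @param include_surface include bone-surface (boundary) voxels in the
#'   interface set (default `TRUE`); `FALSE` restricts to pure background.
#' @return logical joint-space mask; empty (with a warning) when fewer than
#'   two labels are present.
#' @export
derive_joint_truth <- function(labels, dilation_size = 5L,
                               include_surface = TRUE) {
  labs <- if (inherits(labels, "label_volume")) labels$labels else labels
  ids <- label_ids(labs)
  if (length(ids) < 2L) {
    warning("fewer than 2 labels; joint-truth mask is empty")
    return(array(FALSE, dim(labs)))
  }
  cover <- array(0, dim(labs))
  for (id in ids)
    cover <- cover + (cpp_dilate_cube(as_dbl_arr(labs == id),
                                      as.integer(dilation_size)) > 0)
  interface <- cover >= 2
  bg <- labs == 0L
  keep <- if (include_surface) {
    boundary <- !bg & (cpp_dilate_cube(as_dbl_arr(bg), 1L) > 0)
    bg | boundary
  } else bg
  dim(keep) <- dim(labs)
  m <- interface & keep
  dim(m) <- dim(labs)
  dilate_mask(m, dilation_size, "cube")
}

# 3D summed-area table; S[i,j,k] = sum of x[1:i,1:j,1:k]
sat3 <- function(x) {
  s <- apply(x, c(2, 3), cumsum)
  s <- aperm(apply(s, c(1, 3), cumsum), c(2, 1, 3))
  aperm(apply(s, c(1, 2), cumsum), c(2, 3, 1))
}

sat3_count <- function(s, lo, hi) {
  # sum over x[lo1:hi1, lo2:hi2, lo3:hi3] with 1-based inclusive bounds
  g <- function(i, j, k) if (i < 1 || j < 1 || k < 1) 0 else s[i, j, k]
  g(hi[1], hi[2], hi[3]) - g(lo[1] - 1, hi[2], hi[3]) -
    g(hi[1], lo[2] - 1, hi[3]) - g(hi[1], hi[2], lo[3] - 1) +
    g(lo[1] - 1, lo[2] - 1, hi[3]) + g(lo[1] - 1, hi[2], lo[3] - 1) +
    g(hi[1], lo[2] - 1, lo[3] - 1) - g(lo[1] - 1, lo[2] - 1, lo[3] - 1)
}

pad_volume <- function(x, pad, value = 0) {
  if (all(pad == 0)) return(x)
  d <- dim(x)
  out <- array(value, d + 2 * pad)
  out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])] <- x
  out
}

#' Extract training subvolumes
#'
#' Cuts aligned (image, joint-mask) tile pairs of edge `edge` from a volume.
#' The canonical three placements mirror how training subvolumes are
#' positioned on paw datasets: the densest-foreground region (the packed
#' tarsal/carpal cluster), the foreground extreme farthest from the
#' foreground centroid (digit tips), and the emptiest region (background).
#' Additional tiles (`n_tiles > 3`) are placed at seeded random origins.
#' Volumes smaller than the tile are zero-padded.
#'
#' @param volume a [volume3d()].
#' @param joint_truth logical joint mask, same shape.
#' @param n_tiles number of tiles (default 3).
#' @param edge tile edge in voxels (default 200).
#' @param fg_threshold HU level defining foreground (default 2500).
#' @return list of `list(image, mask, origin)` tiles.
#' @export
extract_training_tiles <- function(volume, joint_truth, n_tiles = 3L,
                                   edge = 200L, fg_threshold = 2500) {
  stopifnot(inherits(volume, "volume3d"))
  x <- volume$data
  jt <- joint_truth
  if (!identical(dim(x), dim(jt))) stop("volume/joint shapes differ")
  d <- dim(x)
  pad <- pmax(0L, as.integer(edge) - d)
  if (any(pad > 0)) {
    x <- pad_volume(x, ceiling(pad / 2))
    # keep shapes equal: pad may be odd
    x <- x[seq_len(max(d[1], edge)), seq_len(max(d[2], edge)),
           seq_len(max(d[3], edge)), drop = FALSE]
    jt <- pad_volume(jt * 1, ceiling(pad / 2))
    jt <- jt[seq_len(max(d[1], edge)), seq_len(max(d[2], edge)),
             seq_len(max(d[3], edge)), drop = FALSE] > 0
    d <- dim(x)
  }
  fg <- x >= fg_threshold
  dim(fg) <- d
  s <- sat3(fg * 1)
  stride <- pmax(1L, as.integer(edge) %/% 4L)
  cand <- expand.grid(z = unique(c(seq(1L, d[1] - edge + 1L, by = stride),
                                   d[1] - edge + 1L)),
                      y = unique(c(seq(1L, d[2] - edge + 1L, by = stride),
                                   d[2] - edge + 1L)),
                      x = unique(c(seq(1L, d[3] - edge + 1L, by = stride),
                                   d[3] - edge + 1L)))
  counts <- vapply(seq_len(nrow(cand)), function(i) {
    lo <- as.integer(cand[i, ])
    sat3_count(s, lo, lo + edge - 1L)
  }, 0)
  clamp_origin <- function(ctr) {
    pmin(pmax(1L, as.integer(round(ctr - edge / 2))), d - edge + 1L)
  }
  origins <- list()
  origins[[1]] <- as.integer(cand[which.max(counts), ])   # cluster
  fg_idx <- which(fg)
  if (length(fg_idx)) {
    co <- arrayInd(fg_idx, d)
    ctr <- colMeans(co)
    far <- co[which.max((co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 +
                          (co[, 3] - ctr[3])^2), ]
    origins[[2]] <- clamp_origin(far)                     # distal extreme
  } else origins[[2]] <- clamp_origin(d / 2)
  origins[[3]] <- as.integer(cand[which.min(counts), ])   # background
  if (n_tiles > 3L) {
    for (k in seq_len(n_tiles - 3L))
      origins[[3L + k]] <- vapply(seq_len(3), function(a)
        sample.int(d[a] - edge + 1L, 1L), 0L)
  }
  lapply(origins[seq_len(n_tiles)], function(o) {
    zi <- o[1]:(o[1] + edge - 1L)
    yi <- o[2]:(o[2] + edge - 1L)
    xi <- o[3]:(o[3] + edge - 1L)
    list(image = x[zi, yi, xi, drop = FALSE],
         mask = jt[zi, yi, xi, drop = FALSE], origin = o)
  })
}

#' Randomized validation split
#'
#' Deterministically (for a fixed seed) holds out `round(fraction * n)` tiles
#' for validation; the canonical protocol holds out 25% of subvolumes.
#'
#' @param tiles list of tiles (as from [extract_training_tiles()]).
#' @param fraction validation fraction (default 0.25).
#' @param seed RNG seed.
#' @return `list(train = ..., val = ...)`, disjoint.
#' @export
split_validation <- function(tiles, fraction = 0.25, seed = 1L) {
  n <- length(tiles)
  if (n < 4L) stop("need at least 4 tiles to split")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n_val <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, n_val))
  list(train = tiles[setdiff(seq_len(n), idx)], val = tiles[sort(idx)])
}
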