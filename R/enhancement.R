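#' Response volume
#'
#' Non-negative scalar response of an enhancement stage, tagged with its
#' provenance (`"bth"`, `"sheetness"`, `"voting"`).
#'
#' @param data non-negative 3D array.
#' @param provenance character tag.
#' @return a `response_volume` (3D array with a provenance attribute).
#' @export
response_volume <- function(data, provenance = "bth") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(!is.finite(data)) || any(data < 0))
    stop("response values must be finite and >= 0")
  structure(data, provenance = provenance, class = c("response_volume", "array"))
}

#' @export
print.response_volume <- function(x, ...) {
  cat(sprintf("<response_volume> %s, %s voxels, max %.3g\n",
              attr(x, "provenance"), paste(dim(x), collapse = " x "), max(x)))
  invisible(x)
}

resp_data <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Black top-hat filter
#'
#' Grayscale morphological closing minus the image, with a cubic structuring
#' element of half-size `radius` (edge `2*radius + 1`). Highlights dark
#' structures narrower than the element against brighter surroundings — here,
#' the thin joint spaces between high-density bones. The element is cropped
#' at volume borders.
#'
#' @param volume a [volume3d()] or 3D array.
#' @param radius structuring-element half-size in voxels (default 3,
#'   about the widest joint gap at 17.5 um).
#' @return a `response_volume` tagged `"bth"`.
#' @export
black_top_hat <- function(volume, radius = 3L) {
  x <- if (inherits(volume, "volume3d")) volume$data else volume
  if (radius < 1L) stop("radius must be >= 1")
  closing <- cpp_erode_cube(cpp_dilate_cube(as_dbl_arr(x), radius), radius)
  out <- closing - x
  out[out < 0] <- 0                      # guard fp noise; closing >= id
  response_volume(out, "bth")
}

# Hessian of a volume at Gaussian scale sigma (voxels), gamma-normalized by
# sigma^2. Returns the 6 unique components as a named list.
hessian_at_scale <- function(x, sigma) {
  g0 <- gauss_kernel(sigma, 0)
  g1 <- gauss_kernel(sigma, 1)
  g2 <- gauss_kernel(sigma, 2)
  conv3 <- function(kz, ky, kx) {
    out <- cpp_convolve_axis(x, kz, 1L)
    out <- cpp_convolve_axis(out, ky, 2L)
    cpp_convolve_axis(out, kx, 3L)
  }
  s2 <- sigma^2
  list(zz = s2 * conv3(g2, g0, g0), yy = s2 * conv3(g0, g2, g0),
       xx = s2 * conv3(g0, g0, g2), zy = s2 * conv3(g1, g1, g0),
       zx = s2 * conv3(g1, g0, g1), yx = s2 * conv3(g0, g1, g1))
}

#' Multi-scale Hessian dark-sheet enhancement
#'
#' Structure-enhancement filter selecting thin dark plates (joint spaces) in
#' a bright surround. Per scale, the gamma-normalized Gaussian Hessian is
#' eigen-analyzed; a dark sheet has one dominant positive eigenvalue and two
#' near-zero ones. A Frangi-form score combines plate/blob geometric ratios
#' (`alpha`, `beta`) with a structureness term whose scale `c` is
#' `c_frac` times the maximum Frobenius norm at that scale. The output is
#' the voxelwise maximum over scales.
#'
#' @param volume a [volume3d()] or 3D array.
#' @param scales Gaussian sigmas in voxels (default `c(1, 1.5, 2)`).
#' @param alpha,beta geometric ratio sensitivities (default 0.5).
#' @param c_frac structureness cutoff as a fraction of the per-scale maximum
#'   Frobenius norm (default 0.5).
#' @return a `response_volume` tagged `"sheetness"`.
#' @export
sheetness <- function(volume, scales = c(1, 1.5, 2), alpha = 0.5, beta = 0.5,
                      c_frac = 0.5) {
  x <- if (inherits(volume, "volume3d")) volume$data else volume
  if (length(scales) == 0L || any(scales <= 0))
    stop("scales must be a non-empty vector of positive sigmas")
  x <- as_dbl_arr(x)
  best <- NULL
  for (s in scales) {
    h <- hessian_at_scale(x, s)
    r <- cpp_sheet_score(h$zz, h$yy, h$xx, h$zy, h$zx, h$yx,
                         alpha, beta, c_frac)
    best <- if (is.null(best)) r else pmax(best, r)
  }
  dim(best) <- dim(x)
  response_volume(best, "sheetness")
}

#' Tensor-voting membrane reinforcement
#'
#' Sparsifies a saliency map into tokens, estimates each token's plate
#' normal from the local Hessian of the smoothed saliency, casts closed-form
#' stick votes with a decaying curvature-penalized kernel, and returns the
#' surface saliency of the accumulated tensor field. Voting propagates
#' orientation across gaps, closing holes in an incomplete joint-space
#' membrane.
#'
#' @param saliency a `response_volume` (or non-negative 3D array).
#' @param sigma_v voting scale in voxels; votes reach about `3 * sigma_v`.
#' @param threshold sparsification level; tokens are voxels with saliency
#'   strictly above it. Default: Otsu on the positive saliency values.
#' @param saliency_out `"plate"` (eigen-gap `lambda1 - lambda2`, default) or
#'   `"surface"` (`lambda2 - lambda3`).
#' @return a `response_volume` tagged `"voting"`.
#' @export
tensor_voting <- function(saliency, sigma_v = 2, threshold = NULL,
                          saliency_out = c("plate", "surface")) {
  saliency_out <- match.arg(saliency_out)
  x <- as_dbl_arr(resp_data(saliency))
  if (sigma_v <= 0) stop("sigma_v must be > 0")
  if (is.null(threshold)) threshold <- otsu_threshold(x[x > 0])
  idx <- which(x > threshold)
  if (length(idx) == 0L)
    return(response_volume(array(0, dim(x)), "voting"))
  # token normals from the Hessian of the lightly smoothed saliency field
  h <- hessian_at_scale(x, 1)
  normals <- cpp_plate_normals(h$zz, h$yy, h$xx, h$zy, h$zx, h$yx,
                               as.integer(idx))
  acc <- cpp_tensor_vote(as.integer(idx), x[idx], normals, dim(x), sigma_v)
  out <- cpp_eig_gap(acc$zz, acc$yy, acc$xx, acc$zy, acc$zx, acc$yx,
                     if (saliency_out == "plate") 1L else 2L)
  out[out < 0] <- 0
  dim(out) <- dim(x)
  response_volume(out, "voting")
}

#' Binary mask dilation
#'
#' Dilation by a cubic structuring element of edge `2 * half_kernel + 1`
#' (default), or a Euclidean ball of radius `half_kernel`.
#'
#' @param mask logical/binary 3D array.
#' @param half_kernel half-size in voxels (>= 0).
#' @param shape `"cube"` (default) or `"ball"`.
#' @return logical 3D array.
#' @export
dilate_mask <- function(mask, half_kernel = 2L, shape = c("cube", "ball")) {
  shape <- match.arg(shape)
  if (half_kernel < 0) stop("half_kernel must be >= 0")
  if (half_kernel == 0) return(mask != 0)
  if (shape == "cube") {
    out <- cpp_dilate_cube(as_dbl_arr(mask != 0), as.integer(half_kernel)) > 0
  } else {
    inv <- as_dbl_arr(mask == 0)           # distance from non-mask to mask
    d2 <- cpp_edt_sq(inv)
    out <- d2 <= half_kernel^2
  }
  dim(out) <- dim(mask)
  out
}

#' Combine enhancement responses into a joint-space mask
#'
#' Binarizes each available response at its threshold, takes the voxelwise
#' union, and dilates the union (half-kernel 2 by default). Union is the
#' most permissive composition: missed joint space is the dominant failure
#' mode (it over-connects bones), so any single detector may close a gap.
#'
#' @param bth,sef,mef `response_volume`s (any may be `NULL`).
#' @param dl_prob optional deep-learning probability volume in `[0, 1]`.
#' @param thresholds named list/vector with elements `bth`, `sef`, `mef`,
#'   `dl`; missing entries default to per-volume Otsu (0.5 for `dl`).
#' @param half_kernel final dilation half-size (default 2).
#' @param dilate_shape `"cube"` or `"ball"`.
#' @return logical joint-space mask.
#' @export
combine_responses <- function(bth = NULL, sef = NULL, mef = NULL,
                              dl_prob = NULL, thresholds = list(),
                              half_kernel = 2L,
                              dilate_shape = c("cube", "ball")) {
  dilate_shape <- match.arg(dilate_shape)
  srcs <- list(bth = bth, sef = sef, mef = mef, dl = dl_prob)
  srcs <- srcs[!vapply(srcs, is.null, TRUE)]
  if (length(srcs) == 0L) stop("at least one response must be supplied")
  dms <- lapply(srcs, function(s) dim(resp_data(s)))
  if (length(unique(vapply(dms, paste, "", collapse = "x"))) != 1L)
    stop("response shapes differ")
  acc <- array(FALSE, dms[[1]])
  for (nm in names(srcs)) {
    x <- as_dbl_arr(resp_data(srcs[[nm]]))
    thr <- thresholds[[nm]]
    if (is.null(thr))
      thr <- if (nm == "dl") 0.5 else otsu_threshold(x[x > 0])
    acc <- acc | (x > thr)
  }
  dilate_mask(acc, half_kernel, dilate_shape)
}

#' Otsu threshold
#'
#' Maximizes between-class variance on a 256-bin histogram. Used as the
#' default binarization level for enhancement responses.
#'
#' @param x numeric values (typically the positive responses).
#' @param bins histogram resolution.
#' @return threshold on the scale of `x`; `Inf` for empty input (nothing
#'   passes).
#' @export
otsu_threshold <- function(x, bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(Inf)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  h <- tabulate(pmin(bins, 1L + floor((x - rng[1]) / diff(rng) * bins)), bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(bins) - 0.5) / bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  # the criterion plateaus across empty histogram gaps; take the middle
  best <- which(sb >= max(sb) - 1e-12 * max(sb))
  mids[floor(mean(range(best)))]
}
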