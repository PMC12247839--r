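#' Synthetic multi-bone phantom specification
#'
#' Parametric description of a synthetic micro-CT paw-like volume: digit
#' chains of capsule-shaped bones plus a packed cluster of ellipsoidal bodies
#' emulating the tarsal/carpal region, separated by thin dark joint gaps.
#' Defaults emulate the targeted acquisition: 17.5 um isotropic voxels,
#' mineralized bone around 8000 HU on a 0 HU background, 35 um (2 voxel)
#' joint spaces, mild partial-volume blur and additive Gaussian noise.
#'
#' @param n_digits number of digit chains.
#' @param bones_per_digit bones per chain (proximal to distal).
#' @param cluster_bones number of packed cluster bodies.
#' @param gap_width joint-space thickness in micrometers.
#' @param bone_intensity bone HU (must exceed 2500, the lower bone window).
#' @param background_intensity background HU (below 2500).
#' @param blur_sigma partial-volume Gaussian sigma in micrometers.
#' @param noise_sd additive Gaussian noise standard deviation in HU.
#' @param fusion_pairs list of length-2 integer vectors: adjacent bone id
#'   pairs whose joint gap is bridged at bone intensity (image-level
#'   pathology; ground-truth labels stay distinct).
#' @param erosion_fraction named numeric vector (names = bone ids): fraction
#'   of each bone's volume removed surface-first.
#' @param missing_bones integer ids deleted entirely (erosion fraction 1).
#' @param seed RNG seed; fixed seed gives bitwise-identical output.
#' @param shape grid dimensions `(z, y, x)`; computed from the layout when
#'   `NULL`.
#' @param spacing isotropic voxel size in micrometers.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(n_digits = 5, bones_per_digit = 3, cluster_bones = 7,
                         gap_width = 35, bone_intensity = 8000,
                         background_intensity = 0, blur_sigma = 8,
                         noise_sd = 300, fusion_pairs = list(),
                         erosion_fraction = numeric(0),
                         missing_bones = integer(0), seed = 1L, shape = NULL,
                         spacing = 17.5) {
  n_total <- n_digits * bones_per_digit + cluster_bones
  if (n_total < 1L) stop("phantom must contain at least one bone")
  if (n_total > 33L)
    stop("phantom holds at most 33 bones (paw scope); requested ", n_total)
  if (gap_width <= 0) stop("gap_width must be > 0 (use fusion_pairs to close joints)")
  if (!(bone_intensity > 2500 && 2500 > background_intensity &&
        background_intensity >= 0))
    stop("need bone_intensity > 2500 HU > background_intensity >= 0")
  if (length(erosion_fraction) &&
      (is.null(names(erosion_fraction)) ||
       any(erosion_fraction <= 0 | erosion_fraction > 1)))
    stop("erosion_fraction must be a named vector with values in (0, 1]")
  structure(list(n_digits = as.integer(n_digits),
                 bones_per_digit = as.integer(bones_per_digit),
                 cluster_bones = as.integer(cluster_bones),
                 gap_width = gap_width, bone_intensity = bone_intensity,
                 background_intensity = background_intensity,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 fusion_pairs = fusion_pairs,
                 erosion_fraction = erosion_fraction,
                 missing_bones = as.integer(missing_bones),
                 seed = as.integer(seed), shape = shape, spacing = spacing),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d digits x %d bones + %d cluster = %d bones\n",
    x$n_digits, x$bones_per_digit, x$cluster_bones,
    x$n_digits * x$bones_per_digit + x$cluster_bones))
  cat(sprintf("  gap %.1f um, bone %g HU, noise sd %g HU, seed %d\n",
              x$gap_width, x$bone_intensity, x$noise_sd, x$seed))
  invisible(x)
}

# --- geometry -----------------------------------------------------------

# capsule and ellipsoid primitives in voxel units; voxel centers at 1..n
phantom_layout <- function(spec) {
  g <- spec$gap_width / spec$spacing
  # primitive sizes emulate the scale of real paw bones relative to the
  # processing kernels: enhancement responses hug every bone surface, so the
  # joint-mask dilation (half-kernel 2) erodes markers by 2-3.5 voxels from
  # all sides and cores must still clear the 27-voxel seed filter
  r_d <- 5.0; h_d <- 5.0                      # digit capsule radius / half-cyl
  len <- 2 * (h_d + r_d)
  a_max <- 8.0                                # cluster semi-axis bound
  pitch_x <- 2 * r_d + g + 0.6
  pitch_c <- 2 * a_max + g + 0.6
  margin <- 4.5
  prims <- list()
  # cluster grid just large enough for cluster_bones
  if (spec$cluster_bones > 0) {
    gdim <- c(1, 1, 1)
    while (prod(gdim) < spec$cluster_bones) {
      i <- which.min(gdim)
      gdim[i] <- gdim[i] + 1
    }
    slots <- expand.grid(z = seq_len(gdim[1]), y = seq_len(gdim[2]),
                         x = seq_len(gdim[3]))
    slots <- slots[seq_len(spec$cluster_bones), , drop = FALSE]
  } else {
    gdim <- c(0, 0, 0)
    slots <- NULL
  }
  clus_ext <- ifelse(gdim > 0, (gdim - 1) * pitch_c + 2 * a_max, 0)
  digit_band <- if (spec$n_digits > 0)
    (spec$n_digits - 1) * pitch_x + 2 * r_d else 0
  chain_len <- if (spec$bones_per_digit > 0)
    spec$bones_per_digit * len + (spec$bones_per_digit - 1) * g else 0
  nx <- ceiling(2 * margin + max(digit_band, clus_ext[3]))
  ny <- ceiling(2 * margin + clus_ext[2] +
                  (if (spec$cluster_bones > 0 && chain_len > 0) g + 1 else 0) +
                  chain_len)
  nz <- ceiling(2 * margin + max(2 * r_d, clus_ext[1]))
  cz <- (nz + 1) / 2
  cx_mid <- (nx + 1) / 2
  id <- 0L
  comp <- character(0); name <- character(0)
  if (spec$cluster_bones > 0) {
    for (k in seq_len(spec$cluster_bones)) {
      id <- id + 1L
      ctr <- c(cz - clus_ext[1] / 2 + a_max + (slots$z[k] - 1) * pitch_c,
               margin + a_max + (slots$y[k] - 1) * pitch_c,
               cx_mid - clus_ext[3] / 2 + a_max + (slots$x[k] - 1) * pitch_c)
      prims[[id]] <- list(kind = "ellipsoid", center = ctr, a_max = a_max)
      comp[id] <- "tarsal_carpal"
      name[id] <- sprintf("cluster_%02d", k)
    }
  }
  y_chain0 <- margin + clus_ext[2] +
    (if (spec$cluster_bones > 0 && chain_len > 0) g + 1 else 0)
  if (spec$n_digits > 0 && spec$bones_per_digit > 0) {
    for (d in seq_len(spec$n_digits)) {
      cx <- cx_mid - digit_band / 2 + r_d + (d - 1) * pitch_x
      for (b in seq_len(spec$bones_per_digit)) {
        id <- id + 1L
        y1 <- y_chain0 + (b - 1) * (len + g) + r_d + h_d
        prims[[id]] <- list(kind = "capsule",
                            p = c(cz, y1 - h_d, cx), q = c(cz, y1 + h_d, cx),
                            r = r_d)
        comp[id] <- if (b == 1L) "metatarsal_metacarpal"
                    else if (b == spec$bones_per_digit) "distal_phalanx"
                    else "proximal_phalanx"
        name[id] <- sprintf("digit%d_bone%d", d, b)
      }
    }
  }
  list(prims = prims, shape = c(nz, ny, nx),
       table = bone_table(seq_len(id), name, comp))
}

rasterize_primitive <- function(truth, prim, id, rng) {
  d <- dim(truth)
  if (prim$kind == "capsule") {
    lo <- floor(pmin(prim$p, prim$q) - prim$r - 1)
    hi <- ceiling(pmax(prim$p, prim$q) + prim$r + 1)
  } else {
    lo <- floor(prim$center - prim$a_max - 1)
    hi <- ceiling(prim$center + prim$a_max + 1)
  }
  if (any(lo < 1) || any(hi > d))
    stop(sprintf("phantom layout does not fit in shape (%s): bone %d extends to [%s]-[%s]",
                 paste(d, collapse = "x"), id,
                 paste(lo, collapse = ","), paste(hi, collapse = ",")),
         call. = FALSE)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  gz <- array(zi, dim = c(length(zi), length(yi), length(xi)))
  gy <- aperm(array(yi, dim = c(length(yi), length(zi), length(xi))), c(2, 1, 3))
  gx <- aperm(array(xi, dim = c(length(xi), length(zi), length(yi))), c(2, 3, 1))
  if (prim$kind == "capsule") {
    ycl <- pmin(pmax(gy, prim$p[2]), prim$q[2])
    d2 <- (gz - prim$p[1])^2 + (gy - ycl)^2 + (gx - prim$p[3])^2
    inside <- d2 <= prim$r^2
  } else {
    axes <- prim$axes; rot <- prim$rot
    pz <- gz - prim$center[1]; py <- gy - prim$center[2]
    px <- gx - prim$center[3]
    u <- rot[1, 1] * pz + rot[2, 1] * py + rot[3, 1] * px
    v <- rot[1, 2] * pz + rot[2, 2] * py + rot[3, 2] * px
    w <- rot[1, 3] * pz + rot[2, 3] * py + rot[3, 3] * px
    inside <- (u / axes[1])^2 + (v / axes[2])^2 + (w / axes[3])^2 <= 1
  }
  sub <- truth[zi, yi, xi]
  sub[inside] <- id
  truth[zi, yi, xi] <- sub
  truth
}

random_rotation <- function() {
  # uniform-ish rotation from a random unit quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multi-bone phantom
#'
#' Rasterizes the layout described by a [phantom_spec()] into an exact
#' ground-truth label volume, assigns intensities, applies Gaussian
#' partial-volume blur and additive noise, then applies any requested
#' pathologies (fusion bridges, surface-first erosion, deleted bones).
#' Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_output` list with elements `volume` ([volume3d()]),
#'   `truth` ([label_volume()]), `table` ([bone_table()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    layout <- phantom_layout(spec)
    shape <- if (is.null(spec$shape)) layout$shape else as.integer(spec$shape)
    # realize cluster ellipsoid axes/orientations (seeded)
    prims <- lapply(layout$prims, function(p) {
      if (p$kind == "ellipsoid") {
        p$axes <- runif(3, 6.5, p$a_max)
        p$rot <- random_rotation()
      }
      p
    })
    truth <- array(0L, dim = shape)
    for (i in seq_along(prims))
      truth <- rasterize_primitive(truth, prims[[i]], i, NULL)
    vol <- spec$background_intensity +
      (spec$bone_intensity - spec$background_intensity) * (truth > 0)
    dim(vol) <- shape
    if (spec$blur_sigma > 0) {
      sig <- spec$blur_sigma / spec$spacing
      k <- gauss_kernel(sig, 0)
      for (ax in 1:3) vol <- cpp_convolve_axis(vol, k, ax)
    }
    if (spec$noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dim = shape)
    out <- structure(list(volume = volume3d(vol, spacing = spec$spacing),
                          truth = label_volume(truth, spacing = spec$spacing),
                          table = layout$table, spec = spec),
                     class = "phantom_output")
    for (pair in spec$fusion_pairs) out <- apply_fusion(out, pair)
    for (id in spec$missing_bones) out <- apply_erosion(out, id, 1)
    if (length(spec$erosion_fraction)) {
      ids <- as.integer(names(spec$erosion_fraction))
      for (i in seq_along(ids))
        out <- apply_erosion(out, ids[i], spec$erosion_fraction[[i]])
    }
    out
  })
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf("<phantom_output> %s voxels, %d truth labels\n",
              paste(dim(x$truth$labels), collapse = " x "),
              length(label_ids(x$truth))))
  invisible(x)
}

#' Bridge the joint gap between two adjacent bones (image-level fusion)
#'
#' Fills the inter-bone gap with bone-intensity voxels, emulating joint
#' fusion from chronic erosive damage. Ground-truth labels remain distinct by
#' design, so a separation run on the fused image is countable as an
#' over-connection error.
#'
#' @param out a `phantom_output`.
#' @param pair length-2 integer vector of adjacent bone ids.
#' @return the modified `phantom_output`.
#' @export
apply_fusion <- function(out, pair) {
  stopifnot(inherits(out, "phantom_output"), length(pair) == 2L)
  spec <- out$spec
  truth <- out$truth$labels
  ids <- label_ids(out$truth)
  if (!all(pair %in% ids)) stop("unknown bone id(s): ",
                                paste(setdiff(pair, ids), collapse = ", "))
  k <- as.integer(ceiling(spec$gap_width / spec$spacing)) + 1L
  da <- cpp_dilate_cube(as_dbl_arr(truth == pair[1]), k) > 0
  db <- cpp_dilate_cube(as_dbl_arr(truth == pair[2]), k) > 0
  bridge <- da & db & truth == 0L
  if (!any(bridge))
    stop("bones ", pair[1], " and ", pair[2], " are not adjacent")
  vol <- out$volume$data
  vol[bridge] <- spec$bone_intensity
  out$volume <- volume3d(vol, spacing = out$volume$spacing,
                         origin = out$volume$origin)
  out$spec$fusion_pairs <- unique(c(out$spec$fusion_pairs, list(as.integer(pair))))
  out
}

#' Erode a bone surface-first (pathology operator)
#'
#' Removes the given fraction of a bone's voxels from the surface inward in
#' BOTH the image and the ground truth; `fraction = 1` deletes the bone,
#' producing a "missing" ground-truth outcome.
#'
#' @param out a `phantom_output`.
#' @param id bone label id.
#' @param fraction fraction of the bone's voxel volume to remove, in (0, 1].
#'   `0` is accepted as a no-op.
#' @return the modified `phantom_output`.
#' @export
apply_erosion <- function(out, id, fraction) {
  stopifnot(inherits(out, "phantom_output"))
  if (fraction == 0) return(out)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  truth <- out$truth$labels
  vox <- which(truth == id)
  if (length(vox) == 0L) stop("unknown bone id: ", id)
  n_rm <- round(length(vox) * fraction)
  if (n_rm > 0L) {
    d2 <- cpp_edt_sq(as_dbl_arr(truth == id))
    ord <- order(d2[vox], vox)           # surface first, scan-order ties
    rm_idx <- vox[ord[seq_len(n_rm)]]
    truth[rm_idx] <- 0L
    vol <- out$volume$data
    vol[rm_idx] <- out$spec$background_intensity
    out$volume <- volume3d(vol, spacing = out$volume$spacing,
                           origin = out$volume$origin)
    out$truth <- label_volume(truth, spacing = out$truth$spacing)
  }
  out
}

gauss_kernel <- function(sigma, order = 0) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) {
    k <- -x / sigma^2 * g
    return(k - mean(k))                 # zero-sum first derivative
  }
  if (order == 2) {
    k <- (x^2 - sigma^2) / sigma^4 * g
    return(k - mean(k))
  }
  stop("unsupported derivative order")
}

#' Write / read a phantom specification file
#'
#' Plain-text `key: value` serialization; vectors are comma-separated,
#' fusion pairs as `a-b` tokens, erosion fractions as `id:fraction`.
#' Reading rejects unknown keys; write -> read is the identity.
#'
#' @param spec a [phantom_spec()].
#' @param path file path.
#' @return `write_phantom_spec`: the path, invisibly; `read_phantom_spec`:
#'   a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  fmt <- function(v) paste(vapply(v, function(e)
    format(e, digits = 15), ""), collapse = ", ")
  lines <- character(0)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (nm == "fusion_pairs") {
      if (length(v))
        lines <- c(lines, sprintf("fusion_pairs: %s",
                                  paste(vapply(v, function(p)
                                    paste(p, collapse = "-"), ""),
                                    collapse = ", ")))
    } else if (nm == "erosion_fraction") {
      if (length(v))
        lines <- c(lines, sprintf("erosion_fraction: %s",
                                  paste(sprintf("%s:%s", names(v),
                                                format(v, digits = 15)),
                                        collapse = ", ")))
    } else if (is.null(v)) {
      next
    } else {
      lines <- c(lines, sprintf("%s: %s", nm, fmt(v)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  known <- names(unclass(phantom_spec()))
  int_keys <- c("n_digits", "bones_per_digit", "cluster_bones", "seed",
                "missing_bones", "shape")
  vals <- list()
  for (ln in lines) {
    sep <- regexpr(":", ln, fixed = TRUE)
    if (sep < 0) stop("malformed phantom spec line: ", ln)
    key <- trimws(substr(ln, 1, sep - 1))
    val <- trimws(substr(ln, sep + 1, nchar(ln)))
    if (!key %in% known) stop("unknown phantom spec key: ", key)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    vals[[key]] <- if (key == "fusion_pairs") {
      lapply(parts, function(p) as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
    } else if (key == "erosion_fraction") {
      kv <- strsplit(parts, ":", fixed = TRUE)
      stats::setNames(vapply(kv, function(e) as.numeric(e[2]), 0),
                      vapply(kv, `[[`, "", 1))
    } else if (key %in% int_keys) as.integer(parts)
    else as.numeric(parts)
  }
  do.call(phantom_spec, vals)
}
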