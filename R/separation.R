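#' Generate bone seed markers
#'
#' Seeds are the connected components of the bone mask with the joint-space
#' mask subtracted — an eroded version of each individual bone — after
#' discarding dust components below `min_voxels`. Component ids are assigned
#' in scan order, so marker generation is deterministic.
#'
#' @param bone_mask logical bone mask (HU window).
#' @param joint logical joint-space mask.
#' @param min_voxels minimum seed size (default 27 = 3^3).
#' @param connectivity 26 (default) or 6.
#' @return integer `MarkerSet` array; 0 outside seeds.
#' @export
make_markers <- function(bone_mask, joint, min_voxels = 27L,
                         connectivity = 26L) {
  if (!any(bone_mask)) stop("bone mask is empty")
  seed_mask <- bone_mask & !joint
  dim(seed_mask) <- dim(bone_mask)
  comp <- cpp_label_components(as_dbl_arr(seed_mask), as.integer(connectivity))
  if (max(comp) > 0L) {
    sizes <- tabulate(comp[comp > 0L])
    keep <- which(sizes >= min_voxels)
    if (length(keep) > 0L) {
      remap <- integer(length(sizes))
      remap[keep] <- seq_along(keep)
      comp[comp > 0L] <- remap[comp[comp > 0L]]
    } else comp[] <- 0L
  }
  if (max(comp) == 0L)
    stop("no seed markers survive; inspect the HU threshold and the ",
         "joint mask (it may cover entire bones)")
  dim(comp) <- dim(bone_mask)
  comp
}

#' Marker-based watershed separation
#'
#' Priority-flood watershed restricted to the bone mask: treating the
#' topography as local elevation, basins grow from the markers until every
#' bone-mask voxel is claimed by exactly one marker. The default topography
#' is the negated Euclidean distance to background (robust to intra-bone
#' texture); inverted intensity is available. Ties are broken by lower
#' marker id, then scan order.
#'
#' @param volume a [volume3d()] (used for the intensity topography).
#' @param bone_mask logical bone mask.
#' @param markers integer marker array from [make_markers()].
#' @param topography `"edt"` (default) or `"intensity"`.
#' @param connectivity 26 (default) or 6.
#' @return a [label_volume()]; labels = marker ids, 0 = background.
#' @export
watershed_separate <- function(volume, bone_mask, markers,
                               topography = c("edt", "intensity"),
                               connectivity = 26L) {
  topography <- match.arg(topography)
  stopifnot(identical(dim(bone_mask), dim(markers)))
  if (any(markers > 0 & !bone_mask)) stop("markers must lie inside bone_mask")
  topo <- if (topography == "edt") {
    -sqrt(cpp_edt_sq(as_dbl_arr(bone_mask != 0)))
  } else {
    x <- if (inherits(volume, "volume3d")) volume$data else volume
    -as_dbl_arr(x)
  }
  dim(topo) <- dim(bone_mask)
  storage.mode(markers) <- "integer"
  lab <- cpp_watershed(topo, as_dbl_arr(bone_mask != 0), markers,
                       as.integer(connectivity))
  sp <- if (inherits(volume, "volume3d")) volume$spacing else 17.5
  label_volume(lab, spacing = sp)
}

#' Run the full separation pipeline
#'
#' End-to-end classical chain with optional deep-learning joint prediction:
#' HU window -> black top-hat + sheetness + tensor voting (+ DL probability)
#' -> union + dilation into the joint mask -> seed markers -> marker-based
#' watershed into bone-specific labels.
#'
#' @param volume a [volume3d()].
#' @param config a [pipeline_config()].
#' @param model optional trained [build_unet()] handle (classical-only when
#'   `NULL`).
#' @return `list(labels, joint, log)`: a [label_volume()], the logical joint
#'   mask, and a run log (parameters, per-stage voxel counts and timings).
#' @export
run_pipeline <- function(volume, config = pipeline_config(), model = NULL) {
  stopifnot(inherits(volume, "volume3d"))
  t0 <- proc.time()[["elapsed"]]
  log <- list(config = unclass(config), stages = list())
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - ts, 3))
    out
  }
  bone <- stage("window", window_mask(volume, config$hu_lo, config$hu_hi))
  log$stages$window$voxels <- sum(bone)
  bth <- stage("bth", black_top_hat(volume, config$bth_radius))
  sef <- stage("sheetness",
               sheetness(volume, config$sheet_scales, config$sheet_alpha,
                         config$sheet_beta, config$sheet_c_frac))
  mef <- stage("voting",
               tensor_voting(sef, config$vote_sigma,
                             saliency_out = config$vote_saliency))
  dl <- NULL
  if (!is.null(model)) {
    pred <- stage("dl_predict",
                  predict_tiled(model, volume,
                                tile_spec(config$tile_edge, config$tile_overlap)))
    dl <- pred$prob
  }
  joint <- stage("combine",
                 combine_responses(bth, sef, mef, dl,
                                   thresholds = config$thresholds,
                                   half_kernel = config$dilate_half_kernel,
                                   dilate_shape = config$dilate_shape))
  log$stages$combine$voxels <- sum(joint)
  markers <- stage("markers",
                   make_markers(bone, joint, config$min_voxels,
                                config$connectivity))
  log$stages$markers$n_markers <- max(markers)
  labels <- stage("watershed",
                  watershed_separate(volume, bone, markers,
                                     config$topography, config$connectivity))
  log$stages$watershed$n_labels <- length(label_ids(labels))
  log$seconds_total <- round(proc.time()[["elapsed"]] - t0, 3)
  log$seed <- config$seed
  list(labels = labels, joint = joint, log = log)
}
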