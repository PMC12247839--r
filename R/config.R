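#' Pipeline configuration
#'
#' All tunable parameters of the separation recipe, serializable to a
#' plain-text `key: value` file. Unknown keys in a file are rejected.
#'
#' @param hu_lo,hu_hi bone HU window (default 2500--20000).
#' @param bth_radius black top-hat structuring-element half-size (voxels).
#' @param sheet_scales sheetness Gaussian sigmas (voxels).
#' @param sheet_alpha,sheet_beta,sheet_c_frac sheetness score parameters.
#' @param vote_sigma tensor-voting scale (voxels).
#' @param vote_saliency `"plate"` or `"surface"`.
#' @param thresholds named list of per-source binarization levels
#'   (`bth`, `sef`, `mef`, `dl`); `NULL` entries use Otsu (0.5 for dl).
#' @param dilate_half_kernel final joint-mask dilation half-size (default 2).
#' @param dilate_shape `"cube"` or `"ball"`.
#' @param model path to a model checkpoint, or `"classical-only"`.
#' @param tile_edge,tile_overlap inference tiling (default 352, 0).
#' @param topography watershed landscape: `"edt"` or `"intensity"`.
#' @param connectivity 26 or 6.
#' @param min_voxels minimum marker size (default 27).
#' @param overlap_min evaluation overlap threshold (default 0.5).
#' @param include_missing count missing bones as false negatives.
#' @param out_dir output directory for batch runs.
#' @param seed RNG seed recorded in run logs.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(hu_lo = 2500, hu_hi = 20000, bth_radius = 3L,
                            sheet_scales = c(1, 1.5, 2), sheet_alpha = 0.5,
                            sheet_beta = 0.5, sheet_c_frac = 0.5,
                            vote_sigma = 2, vote_saliency = "plate",
                            thresholds = list(), dilate_half_kernel = 2L,
                            dilate_shape = "cube", model = "classical-only",
                            tile_edge = 352L, tile_overlap = 0L,
                            topography = "edt", connectivity = 26L,
                            min_voxels = 27L, overlap_min = 0.5,
                            include_missing = TRUE, out_dir = ".",
                            seed = 1L) {
  if (!(hu_lo < hu_hi)) stop("need hu_lo < hu_hi")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  if (!topography %in% c("edt", "intensity"))
    stop("topography must be 'edt' or 'intensity'")
  if (!vote_saliency %in% c("plate", "surface"))
    stop("vote_saliency must be 'plate' or 'surface'")
  if (!dilate_shape %in% c("cube", "ball"))
    stop("dilate_shape must be 'cube' or 'ball'")
  structure(list(hu_lo = hu_lo, hu_hi = hu_hi,
                 bth_radius = as.integer(bth_radius),
                 sheet_scales = as.numeric(sheet_scales),
                 sheet_alpha = sheet_alpha, sheet_beta = sheet_beta,
                 sheet_c_frac = sheet_c_frac, vote_sigma = vote_sigma,
                 vote_saliency = vote_saliency, thresholds = thresholds,
                 dilate_half_kernel = as.integer(dilate_half_kernel),
                 dilate_shape = dilate_shape, model = model,
                 tile_edge = as.integer(tile_edge),
                 tile_overlap = as.integer(tile_overlap),
                 topography = topography,
                 connectivity = as.integer(connectivity),
                 min_voxels = as.integer(min_voxels),
                 overlap_min = overlap_min,
                 include_missing = include_missing, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration file
#'
#' Plain-text `key: value` format; vector values are comma-separated, the
#' `thresholds` list is flattened to `thresholds.<source>`. Reading a file
#' with unknown keys is an error; write -> read is the identity.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_config`: the path, invisibly; `read_config`: a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  lines <- character(0)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (nm == "thresholds") {
      for (tn in names(v))
        lines <- c(lines, sprintf("thresholds.%s: %s", tn,
                                  format(v[[tn]], digits = 15)))
    } else {
      lines <- c(lines, sprintf("%s: %s", nm,
                                paste(vapply(v, function(e)
                                  if (is.numeric(e)) format(e, digits = 15)
                                  else as.character(e), ""),
                                  collapse = ", ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- pipeline_config()
  numeric_keys <- c("hu_lo", "hu_hi", "bth_radius", "sheet_scales",
                    "sheet_alpha", "sheet_beta", "sheet_c_frac",
                    "vote_sigma", "dilate_half_kernel", "tile_edge",
                    "tile_overlap", "connectivity", "min_voxels",
                    "overlap_min", "seed")
  logical_keys <- "include_missing"
  vals <- list()
  thresholds <- list()
  for (ln in lines) {
    sep <- regexpr(":", ln, fixed = TRUE)
    if (sep < 0) stop("malformed config line (no ':'): ", ln)
    key <- trimws(substr(ln, 1, sep - 1))
    val <- trimws(substr(ln, sep + 1, nchar(ln)))
    if (startsWith(key, "thresholds.")) {
      src <- sub("^thresholds\\.", "", key)
      if (!src %in% c("bth", "sef", "mef", "dl"))
        stop("unknown threshold source in config: ", src)
      thresholds[[src]] <- as.numeric(val)
      next
    }
    if (key == "thresholds" && !nzchar(val)) next
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    vals[[key]] <- if (key %in% numeric_keys) as.numeric(parts)
                   else if (key %in% logical_keys) as.logical(parts)
                   else parts
  }
  vals$thresholds <- thresholds
  do.call(pipeline_config, vals)
}
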