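#' @useDynLib pawseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif median quantile
#' @importFrom utils head read.csv write.csv
NULL

#' 3D micro-CT volume
#'
#' A scalar 3D image with voxel spacing and Hounsfield-unit intensity
#' semantics. Arrays are indexed `[z, y, x]` throughout the package.
#'
#' @param data numeric 3D array, intensities in HU.
#' @param spacing numeric length-3 voxel size in micrometers `(z, y, x)`, or a
#'   scalar recycled isotropically. Default 17.5 um, the scanner resolution
#'   the pipeline targets.
#' @param origin numeric length-3 physical offset in micrometers.
#' @return A `volume3d` object.
#' @export
volume3d <- function(data, spacing = 17.5, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (um)")
  if (length(origin) != 3L) stop("`origin` must have length 3")
  storage.mode(data) <- "double"
  if (any(!is.finite(data))) stop("intensities must be finite at every voxel")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels (z,y,x), spacing %s um\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.1f, %.1f] HU\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Integer-labeled 3D segmentation
#'
#' Non-negative integer labels on the same grid as a paired [volume3d()];
#' id 0 is background, each positive id one bone "material".
#'
#' @param labels integer 3D array of label ids.
#' @param spacing voxel spacing in micrometers as in [volume3d()].
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, spacing = 17.5) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers")
  structure(list(labels = labels, spacing = as.numeric(spacing)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  ids <- label_ids(x)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d labels\n",
              d[1], d[2], d[3], length(ids)))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Non-background label ids present in a label volume
#' @param x a `label_volume` or integer array.
#' @return sorted integer vector of positive ids.
#' @export
label_ids <- function(x) {
  labs <- if (inherits(x, "label_volume")) x$labels else x
  ids <- sort(unique(as.integer(labs)))
  ids[ids > 0L]
}

#' Bone lookup table
#'
#' Associates label ids with bone names and anatomical compartment tags
#' (tarsal/carpal cluster, metatarsals/metacarpals, proximal and distal
#' phalanges, sesamoids). Anatomically fused structures are represented as a
#' single id, which changes the per-compartment denominator accordingly.
#'
#' @param id integer label ids (unique, positive).
#' @param name character bone names.
#' @param compartment character tags; one of `"tarsal_carpal"`,
#'   `"metatarsal_metacarpal"`, `"proximal_phalanx"`, `"distal_phalanx"`,
#'   `"sesamoid"`, `"other"`.
#' @return A `bone_table` data frame.
#' @export
bone_table <- function(id, name = paste0("bone_", id),
                       compartment = "other") {
  id <- as.integer(id)
  if (anyDuplicated(id)) stop("label ids must be unique")
  if (any(id <= 0L)) stop("label ids must be positive")
  compartment <- rep_len(as.character(compartment), length(id))
  ok <- c("tarsal_carpal", "metatarsal_metacarpal", "proximal_phalanx",
          "distal_phalanx", "sesamoid", "other")
  if (!all(compartment %in% ok))
    stop("unknown compartment tag(s): ",
         paste(setdiff(compartment, ok), collapse = ", "))
  out <- data.frame(id = id, name = rep_len(as.character(name), length(id)),
                    compartment = compartment, stringsAsFactors = FALSE)
  class(out) <- c("bone_table", "data.frame")
  out
}

#' Hounsfield-window bone mask
#'
#' Thresholds a volume on a closed HU interval; the default window
#' 2500--20000 HU is the mineralized-bone range used for paw datasets.
#' Boundaries are inclusive on both ends.
#'
#' @param volume a [volume3d()].
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return logical 3D array, `TRUE` where `lo <= intensity <= hi`.
#' @export
window_mask <- function(volume, lo = 2500, hi = 20000) {
  stopifnot(inherits(volume, "volume3d"))
  if (!(lo < hi)) stop("`lo` must be < `hi`")
  m <- volume$data >= lo & volume$data <= hi
  dim(m) <- dim(volume$data)
  m
}

# internal: coerce logical/numeric mask to a double array (C++ entry points)
as_dbl_arr <- function(x) {
  storage.mode(x) <- "double"
  x
}
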