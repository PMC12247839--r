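#' Read a 3D volume
#'
#' Imports a grayscale 3D volume from one of the supported on-disk formats.
#' Voxel spacing is taken from file metadata when present; formats without
#' spacing metadata (TIFF stacks) fall back to `default_spacing` with a
#' warning. NIfTI is the pipeline's canonical interchange format.
#'
#' @param path file (NIfTI/TIFF/MHA) or directory (DICOM series).
#' @param format one of `"dicom_series"`, `"nifti"`, `"tiff_stack"`, `"mha"`;
#'   inferred from the path when omitted.
#' @param default_spacing fallback isotropic voxel size in micrometers
#'   (default 17.5, the targeted scanner resolution).
#' @return A [volume3d()] with `(z, y, x)` axis order.
#' @export
read_volume <- function(path, format = NULL, default_spacing = 17.5) {
  format <- format %||% infer_format(path)
  if (!format %in% c("dicom_series", "nifti", "tiff_stack", "mha"))
    stop("unknown format: ", format)
  if (format == "dicom_series") {
    if (!dir.exists(path)) stop("DICOM series path must be a directory: ", path)
  } else if (!file.exists(path)) stop("no such file: ", path)
  raw <- switch(format,
    nifti = read_nifti(path),
    mha = read_mha(path),
    dicom_series = read_dicom_series(path, default_spacing),
    tiff_stack = {
      arr <- read_tiff_stack(path)
      warning("TIFF carries no spacing metadata; assuming ", default_spacing,
              " um isotropic")
      list(data = arr, spacing = rep(default_spacing, 3L), origin = c(0, 0, 0))
    })
  volume3d(raw$data, spacing = raw$spacing, origin = raw$origin)
}

#' Write a 3D volume
#'
#' @param volume a [volume3d()].
#' @param path output file.
#' @param format one of `"nifti"`, `"tiff_stack"`, `"mha"`; inferred from the
#'   file extension when omitted.
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path, format = NULL) {
  stopifnot(inherits(volume, "volume3d"))
  format <- format %||% infer_format(path)
  switch(format,
    nifti = write_nifti(volume$data, path, volume$spacing, volume$origin,
                        datatype = 16L),
    mha = write_mha(volume$data, path, volume$spacing, volume$origin,
                    element_type = "MET_FLOAT"),
    tiff_stack = write_tiff_stack(volume$data, path, kind = "float32"),
    stop("unsupported output format: ", format))
  invisible(path)
}

#' Write an integer label volume
#'
#' Label maps round-trip integer-exactly: NIfTI stores 32-bit integers,
#' TIFF and MHA 16-bit unsigned (ids up to 65535).
#'
#' @param labels a [label_volume()].
#' @param path output file.
#' @param format one of `"nifti"`, `"tiff_stack"`, `"mha"`.
#' @return the path, invisibly.
#' @export
write_labels <- function(labels, path, format = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  format <- format %||% infer_format(path)
  arr <- labels$labels
  switch(format,
    nifti = write_nifti(arr, path, labels$spacing, datatype = 8L),
    mha = write_mha(arr, path, labels$spacing, element_type = "MET_USHORT"),
    tiff_stack = write_tiff_stack(arr, path, kind = "uint16"),
    stop("unsupported output format: ", format))
  invisible(path)
}

#' Read an integer label volume
#'
#' @inheritParams read_volume
#' @return A [label_volume()].
#' @export
read_labels <- function(path, format = NULL, default_spacing = 17.5) {
  v <- read_volume(path, format, default_spacing)
  arr <- v$data
  if (any(arr != round(arr)) || any(arr < 0))
    stop("file does not contain a non-negative integer label map: ", path)
  storage.mode(arr) <- "integer"
  label_volume(arr, spacing = v$spacing)
}

infer_format <- function(path) {
  if (dir.exists(path)) return("dicom_series")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         nii = "nifti",
         mha = "mha",
         tif = ,
         tiff = "tiff_stack",
         dcm = "dicom_series",
         stop("cannot infer format from extension '", ext,
              "'; pass `format` explicitly"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
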