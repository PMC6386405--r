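#' Read a segmented label stack into cell masks
#'
#' Reads a multi-page TIFF of integer labels (0 = background) such as
#' produced by watershed segmentation of confocal stacks, and returns
#' one [cell_mask()] per distinct nonzero label, all sharing the same
#' grid and calibration. Calibration is taken from a sidecar JSON file
#' `<path>.json` with field `voxel_size_um` when present, otherwise
#' from the `calibration` argument.
#'
#' @param path Path to a TIFF stack (single- or multi-page; a single
#'   page is read as a 2D label image).
#' @param calibration Optional [calibration()]; required when no
#'   sidecar JSON is found.
#' @return Named list of `voxdiv_mask` objects, names are the label
#'   values. An all-zero stack returns an empty list with a warning.
#' @seealso [write_label_stack()]
#' @export
read_label_stack <- function(path, calibration = NULL) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size_um))
      calibration <- calibration(as.numeric(meta$voxel_size_um))
  }
  if (is.null(calibration))
    stop("no calibration metadata found; supply `calibration`")

  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, function(p) all(p == round(p)), TRUE)))
    stop("label stack must have an integer pixel type")
  # TIFF pages come in row-major (y, x); transpose to (x, y) grid axes
  arr <- vapply(pages, function(p) t(p), matrix(0, ncol(pages[[1]]),
                                                nrow(pages[[1]])))
  if (length(pages) == 1) arr <- arr[, , 1]
  labels <- sort(unique(as.integer(arr[arr != 0])))
  if (length(labels) == 0) {
    warning("label stack contains no nonzero labels")
    return(list())
  }
  out <- lapply(labels, function(l)
    suppressWarnings(cell_mask(arr == l, calibration)))
  names(out) <- labels
  out
}

#' Write a label image (or stack) to TIFF
#'
#' Inverse of [read_label_stack()]: writes an integer label array as a
#' multi-page TIFF (16-bit) plus a `<path>.json` sidecar carrying the
#' voxel calibration, so a write-then-read round trip reproduces the
#' grid, the labels and the calibration exactly.
#'
#' @param labels Integer 2D or 3D array, 0 = background.
#' @param path Output TIFF path.
#' @param calibration A [calibration()] recorded in the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_label_stack <- function(labels, path, calibration) {
  if (max(labels) > 65535 || min(labels) < 0)
    stop("labels must fit an unsigned 16-bit range")
  nd <- length(dim(labels))
  pages <- if (nd == 3) {
    lapply(seq_len(dim(labels)[3]), function(k) t(labels[, , k]) / 65535)
  } else {
    list(t(labels) / 65535)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(voxel_size_um = calibration$voxel_size),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# read back the raw integer label array (used in tests and the CLI)
read_label_array <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(p) t(p), matrix(0, ncol(pages[[1]]),
                                                nrow(pages[[1]])))
  if (length(pages) == 1) arr <- arr[, , 1]
  storage.mode(arr) <- "integer"
  arr
}
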