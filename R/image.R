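#' Construct a multichannel image
#'
#' Container for one IMC acquisition: a named list of per-marker intensity
#' grids sharing a single shape, plus the physical pixel size.  Coordinates
#' follow one convention throughout the package: micrometers, origin at the
#' center of the top-left pixel, x increasing with columns (rightward) and y
#' increasing with rows (downward).
#'
#' @param channels Named list of nonnegative numeric matrices, one per
#'   marker, all with identical dimensions.
#' @param pixel_size_um Positive scalar; physical edge length of one pixel in
#'   micrometers (1 for typical laser-ablation rasters).
#' @return An `imc_image` object.
#' @export
imc_image <- function(channels, pixel_size_um = 1) {
  if (!is.list(channels) || length(channels) == 0)
    stop("channels must be a nonempty named list of matrices")
  if (is.null(names(channels)) || anyNA(names(channels)) || any(names(channels) == ""))
    stop("every channel must be named")
  if (anyDuplicated(names(channels)))
    stop("duplicated channel names")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("every channel must be a matrix")
  d1 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d1), logical(1))))
    stop("all channels must share the same dimensions")
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    stop("channel intensities must be nonnegative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "imc_image")
}

#' @export
dim.imc_image <- function(x) dim(x$channels[[1]])

#' @export
print.imc_image <- function(x, ...) {
  d <- dim(x)
  cat("imc_image:", length(x$channels), "channels,", d[1], "x", d[2],
      "pixels,", x$pixel_size_um, "um/pixel\n")
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a segmentation mask
#'
#' Integer label grid in which 0 is background and each positive label is one
#' segmented cell.  Labels are required to be consecutive 1..n.
#'
#' @param labels Integer matrix of labels.
#' @param pixel_size_um Positive scalar, micrometers per pixel.
#' @return An `imc_mask` object.
#' @export
imc_mask <- function(labels, pixel_size_um = 1) {
  if (is.null(dim(labels))) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be nonnegative")
  pos <- sort(unique(labels[labels > 0]))
  if (length(pos) && !identical(pos, seq_len(max(pos))))
    stop("positive labels must be consecutive 1..n")
  structure(labels, class = "imc_mask", pixel_size_um = pixel_size_um)
}

#' Number of cells in a segmentation mask
#'
#' @param mask An `imc_mask`.
#' @return Integer count of distinct positive labels.
#' @export
n_cells <- function(mask) {
  length(unique(mask[mask > 0]))
}

#' @export
print.imc_mask <- function(x, ...) {
  cat("imc_mask:", nrow(x), "x", ncol(x), "pixels,", n_cells(x), "cells\n")
  invisible(x)
}
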