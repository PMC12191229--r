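#' Write a multichannel image as multi-page TIFF
#'
#' One TIFF page per channel, in panel/channel order.  Because baseline TIFF
#' pages written here are fixed-point, each channel is stored rescaled by its
#' maximum; the per-channel scales, channel names and pixel size go to a JSON
#' sidecar (`<path>.json`) that [read_image()] uses to restore intensities
#' and names.  Round-tripping reproduces float grids to better than 1e-6 of
#' the channel maximum and integer-valued grids essentially exactly.
#'
#' @param image An `imc_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "imc_image"))
  scales <- vapply(image$channels, function(m) max(m, 1e-300), numeric(1))
  pages <- mapply(function(m, s) m / s, image$channels, scales, SIMPLIFY = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "deflate")
  jsonlite::write_json(
    list(channels = names(image$channels),
         scale = unname(scales),
         pixel_size_um = image$pixel_size_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multichannel image from multi-page TIFF
#'
#' Pages are matched to panel entries: by name when the JSON sidecar written
#' by [write_image()] is present, otherwise 1:1 by order against the panel.
#' A page-count/panel mismatch is an error.
#'
#' @param path TIFF path.
#' @param panel A `marker_panel`; channel names must be a subset of its
#'   marker names.
#' @return An `imc_image`.
#' @export
read_image <- function(path, panel) {
  validate_panel(panel)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (length(meta$channels) != length(pages))
      stop("sidecar lists ", length(meta$channels), " channels but TIFF has ",
           length(pages), " pages")
    channels <- mapply(function(m, s) m * s, pages, meta$scale, SIMPLIFY = FALSE)
    names(channels) <- meta$channels
    unknown <- setdiff(meta$channels, panel$marker)
    if (length(unknown))
      stop("channel(s) not in panel: ", paste(unknown, collapse = ", "))
    px <- meta$pixel_size_um
  } else {
    if (length(pages) != nrow(panel))
      stop("TIFF has ", length(pages), " pages but panel has ", nrow(panel),
           " entries")
    channels <- pages
    names(channels) <- panel$marker
    px <- 1
  }
  imc_image(channels, pixel_size_um = px)
}

#' Write a label mask as 16-bit TIFF
#'
#' Labels are stored as 16-bit unsigned integers with 0 = background, so at
#' most 65535 cells per mask.
#'
#' @param mask An `imc_mask` (or integer matrix).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- unclass(mask)
  if (max(m) > 65535L) stop("label mask exceeds 16-bit range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L, reduce = FALSE,
                  compression = "deflate")
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param path TIFF path.
#' @param pixel_size_um Micrometers per pixel to attach to the mask.
#' @return An `imc_mask`.
#' @export
read_mask <- function(path, pixel_size_um = 1) {
  m <- tiff::readTIFF(path)
  imc_mask(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)),
           pixel_size_um = pixel_size_um)
}

.cell_table_required <- c("cell_id", "x_um", "y_um", "sample_id", "condition")

#' Read a cell table from TSV
#'
#' The cell table is the pipeline's unit of analysis: one row per segmented
#' cell with columns `cell_id`, `x_um`, `y_um`, `sample_id`, `condition`, one
#' numeric column per marker, and any extra columns (`area_px`, `cluster`,
#' `annotation`, ...) preserved verbatim.  Missing mandatory columns are an
#' error naming the column.
#'
#' @param path TSV path (UTF-8, Unix newlines, decimal point).
#' @return A data frame.
#' @export
read_cell_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing <- setdiff(.cell_table_required, names(tab))
  if (length(missing))
    stop("cell table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  tab
}

#' Write a cell table to TSV
#'
#' @param table Cell-table data frame (see [read_cell_table()] for the
#'   schema).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  missing <- setdiff(.cell_table_required, names(table))
  if (length(missing))
    stop("cell table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
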