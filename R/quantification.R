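#' Quantify per-cell total marker intensities
#'
#' Builds the cell-by-protein matrix: for every segmented cell (positive
#' label in the mask) and every panel marker present in the image, the total
#' (summed) pixel intensity over the cell's region, together with the cell's
#' area-weighted centroid in micrometers and its area in pixels.
#'
#' @param image An `imc_image`.
#' @param mask An `imc_mask` of the same shape.
#' @param panel A `marker_panel`; markers are quantified in panel order.
#' @param sample_id,condition Metadata attached to every row.
#' @return Cell-table data frame: `cell_id`, `x_um`, `y_um`, `area_px`,
#'   `sample_id`, `condition`, then one column per marker.
#' @export
quantify <- function(image, mask, panel, sample_id = "sample1",
                     condition = "control") {
  stopifnot(inherits(image, "imc_image"))
  validate_panel(panel)
  lab <- unclass(mask)
  if (!identical(dim(lab), dim(image)))
    stop("image and mask dimensions differ")
  markers <- intersect(panel$marker, names(image$channels))
  psz <- image$pixel_size_um
  idx <- which(lab > 0)
  empty <- data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_px = integer(0),
                      sample_id = character(0), condition = character(0),
                      stringsAsFactors = FALSE, check.names = FALSE)
  empty[markers] <- lapply(markers, function(m) numeric(0))
  if (length(idx) == 0) return(empty)

  g <- lab[idx]
  nr <- nrow(lab)
  px_row <- (idx - 1) %% nr            # 0-based row
  px_col <- (idx - 1) %/% nr           # 0-based col
  intens <- do.call(cbind, lapply(image$channels[markers], function(ch) ch[idx]))
  totals <- rowsum(intens, group = g)
  area <- as.integer(rowsum(rep(1, length(idx)), group = g))
  cent <- rowsum(cbind(x = px_col * psz, y = px_row * psz), group = g) / area
  ids <- as.integer(rownames(totals))

  tab <- data.frame(cell_id = ids, x_um = cent[, "x"], y_um = cent[, "y"],
                    area_px = area, sample_id = sample_id,
                    condition = condition, stringsAsFactors = FALSE,
                    check.names = FALSE)
  tab[markers] <- as.data.frame(totals, check.names = FALSE)
  rownames(tab) <- NULL
  tab
}

.cell_table_meta <- c("cell_id", "x_um", "y_um", "area_px", "sample_id",
                      "condition", "cluster", "annotation", "phenotype")

#' Marker columns of a cell table
#'
#' @param table Cell-table data frame.
#' @param markers Optional explicit marker names; defaults to all numeric
#'   columns that are not metadata (`cell_id`, coordinates, `area_px`,
#'   `sample_id`, `condition`, `cluster`, `annotation`, `phenotype`).
#' @return Character vector of marker column names.
#' @export
marker_columns <- function(table, markers = NULL) {
  if (!is.null(markers)) {
    missing <- setdiff(markers, names(table))
    if (length(missing))
      stop("marker column(s) not in table: ", paste(missing, collapse = ", "))
    return(markers)
  }
  cand <- setdiff(names(table), .cell_table_meta)
  cand[vapply(table[cand], is.numeric, logical(1))]
}

.zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Log plus double z-score normalization of a cell-by-protein matrix
#'
#' The transform applied before clustering: (1) `ln(1 + x)` on the total
#' intensities; (2) z-scoring of each marker column over cells (the
#' "across cells" pass); (3) z-scoring of each cell row over markers (the
#' "across markers" pass).  Constant vectors at any standardization step map
#' to zero rather than dividing by zero.  The pass order is switchable
#' because either reading of a column-then-row recipe can be defended; the
#' applied sequence is recorded in the `transform` attribute.
#'
#' @param x Cell-table data frame or numeric matrix (cells x markers).
#' @param markers Optional marker column names when `x` is a data frame.
#' @param order `"cells_first"` (default: across-cells column pass, then
#'   across-markers row pass) or `"markers_first"` (reversed).
#' @return Numeric matrix (cells x markers) with attribute `transform`
#'   listing the applied steps in order.
#' @export
normalize_intensities <- function(x, markers = NULL,
                                  order = c("cells_first", "markers_first")) {
  order <- match.arg(order)
  if (is.data.frame(x)) {
    markers <- marker_columns(x, markers)
    m <- as.matrix(x[markers])
  } else {
    m <- as.matrix(x)
  }
  if (nrow(m) < 2)
    stop("normalization needs at least 2 cells (got ", nrow(m), ")")
  m <- log1p(m)
  zcols <- function(m) apply(m, 2, .zscore)
  zrows <- function(m) t(apply(m, 1, .zscore))
  if (order == "cells_first") {
    m <- zrows(zcols(m))
    steps <- c("log1p", "zscore_across_cells", "zscore_across_markers")
  } else {
    m <- zcols(zrows(m))
    steps <- c("log1p", "zscore_across_markers", "zscore_across_cells")
  }
  dimnames(m) <- list(NULL, markers %||% colnames(m))
  attr(m, "transform") <- steps
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
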