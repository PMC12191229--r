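# Bucketed nearest-neighbor search: reference points are hashed into a
# square grid and queries scan outward ring by ring, stopping once the
# closest ring that could still improve on the current best is exhausted.
# Independent of (and much faster than) the exhaustive pairwise scan used as
# its oracle in the tests.
.nn_bucket <- function(qx, qy, rx, ry, exclude = NULL) {
  nq <- length(qx)
  nr <- length(rx)
  if (nq == 0) return(numeric(0))
  if (nr == 0) return(rep(NA_real_, nq))
  ext <- max(diff(range(rx, qx)), diff(range(ry, qy)))
  cell <- ext / max(1, ceiling(sqrt(nr)))
  if (!is.finite(cell) || cell <= 0) cell <- 1
  bx <- floor(rx / cell); by <- floor(ry / cell)
  buckets <- split(seq_len(nr), paste(bx, by))
  max_ring <- ceiling(ext / cell) + 2L
  out <- numeric(nq)
  for (i in seq_len(nq)) {
    qbx <- floor(qx[i] / cell); qby <- floor(qy[i] / cell)
    best <- Inf
    ring <- 0L
    repeat {
      idx <- integer(0)
      if (ring == 0L) {
        b <- buckets[[paste(qbx, qby)]]
        if (!is.null(b)) idx <- b
      } else {
        span <- -ring:ring
        for (dx in span) {
          dys <- if (abs(dx) == ring) span else c(-ring, ring)
          for (dy in dys) {
            b <- buckets[[paste(qbx + dx, qby + dy)]]
            if (!is.null(b)) idx <- c(idx, b)
          }
        }
      }
      if (!is.null(exclude) && !is.na(exclude[i]) && length(idx))
        idx <- idx[idx != exclude[i]]
      if (length(idx)) {
        d2 <- (rx[idx] - qx[i])^2 + (ry[idx] - qy[i])^2
        best <- min(best, sqrt(min(d2)))
      }
      # a ring at Chebyshev index r holds no point closer than (r-1)*cell
      if (is.finite(best) && (ring - 1) * cell > best) break
      ring <- ring + 1L
      if (ring > max_ring && is.finite(best)) break
      if (ring > 4L * max_ring) break
    }
    out[i] <- best
  }
  out
}

#' Per-cell nearest-neighbor distances to a reference cell type
#'
#' For every cell of `query_type`, the Euclidean centroid-to-centroid
#' distance in micrometers to the nearest cell of `reference_type` within
#' the same sample (no cross-sample neighbors).  A cell belonging to both
#' types excludes itself.  Samples with no reference cells yield `NA`
#' distances.
#'
#' @param table Cell-table data frame with an annotation column.
#' @param query_type,reference_type Cell-type labels in `type_col`.
#' @param type_col Name of the annotation column (default `"annotation"`).
#' @param allow_missing If `FALSE` (default), a `query_type` absent from the
#'   whole table is an error (it usually indicates a typo); `TRUE` returns
#'   an empty result instead.
#' @return Data frame `sample_id`, `cell_id`, `distance_um`, one row per
#'   query cell.
#' @export
nn_distances <- function(table, query_type, reference_type,
                         type_col = "annotation", allow_missing = FALSE) {
  if (!type_col %in% names(table))
    stop("table is missing annotation column '", type_col, "'")
  types <- table[[type_col]]
  if (!reference_type %in% types)
    if (!allow_missing)
      stop("unknown reference type label '", reference_type, "'")
  if (!query_type %in% types) {
    if (!allow_missing)
      stop("unknown query type label '", query_type, "'")
    return(data.frame(sample_id = character(0), cell_id = integer(0),
                      distance_um = numeric(0), stringsAsFactors = FALSE))
  }
  out <- list()
  for (s in unique(table$sample_id)) {
    sub <- table[table$sample_id == s, , drop = FALSE]
    q <- sub[sub[[type_col]] == query_type, , drop = FALSE]
    if (nrow(q) == 0) next
    r <- sub[sub[[type_col]] == reference_type, , drop = FALSE]
    exclude <- if (query_type == reference_type)
      match(q$cell_id, r$cell_id) else rep(NA_integer_, nrow(q))
    d <- .nn_bucket(q$x_um, q$y_um, r$x_um, r$y_um, exclude = exclude)
    d[!is.finite(d)] <- NA_real_
    out[[length(out) + 1L]] <- data.frame(sample_id = s, cell_id = q$cell_id,
                                          distance_um = d,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), cell_id = integer(0),
                      distance_um = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Median distance of immune cell types from tumor cells, per sample
#'
#' Summarizes [nn_distances()] per sample and cell type: the median
#' nearest-reference distance over cells of that type.  Rows are omitted
#' (reported missing) for samples without reference cells or without cells
#' of the type.
#'
#' @param table Cell-table data frame with an annotation column.
#' @param immune_types Cell-type labels to summarize (default the CD8, CD4,
#'   neutrophil and macrophage annotations).
#' @param reference_type Reference label (default `"tumor cells"`).
#' @param type_col Name of the annotation column.
#' @return Data frame `sample_id`, `cell_type`, `n_cells`,
#'   `median_distance_um`, `reference_type`.
#' @export
summarize_median_distance <- function(table,
                                      immune_types = c("CD8", "CD4",
                                                       "neutrophils",
                                                       "macrophages"),
                                      reference_type = "tumor cells",
                                      type_col = "annotation") {
  out <- list()
  for (ty in immune_types) {
    d <- nn_distances(table, ty, reference_type, type_col = type_col,
                      allow_missing = TRUE)
    if (nrow(d) == 0) next
    for (s in unique(d$sample_id)) {
      ds <- d$distance_um[d$sample_id == s]
      ds <- ds[!is.na(ds)]
      if (!length(ds)) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, cell_type = ty, n_cells = length(ds),
        median_distance_um = stats::median(ds),
        reference_type = reference_type, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), cell_type = character(0),
                      n_cells = integer(0), median_distance_um = numeric(0),
                      reference_type = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
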