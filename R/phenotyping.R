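#' Multi-restart K-means phenotyping
#'
#' Clusters the normalized cell-by-protein matrix with Lloyd's K-means,
#' restarted `n_restarts` times from random cell subsets and keeping the
#' restart with the smallest total within-cluster sum of squares.  A high
#' restart count (the production setting is 100,000; the desk-scale default
#' is 100) stabilizes the centroids against initialization.  Deterministic
#' given `seed`; restarts are drawn from a single RNG stream, so the best
#' objective is non-increasing in `n_restarts` at a fixed seed.
#'
#' @param x Numeric matrix (cells x markers), typically from
#'   [normalize_intensities()].
#' @param k Number of clusters (default 20).
#' @param n_restarts Number of random restarts (>= 1).
#' @param seed Integer seed.
#' @param iter_max Maximum Lloyd iterations per restart.
#' @return An `imc_kmeans` list: `k`, `assignments` (integer vector in 1..k),
#'   `centroids` (k x markers), `objective` (total within-cluster SS),
#'   `n_restarts`, `seed`.
#' @export
kmeans_cluster <- function(x, k = 20, n_restarts = 100, seed = 1L,
                           iter_max = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")")
  stopifnot(k >= 1, n_restarts >= 1)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- x[sample.int(n, k), , drop = FALSE]
      # Lloyd needs distinct starting centers; jitter exact duplicates.
      if (anyDuplicated(centers))
        centers <- centers + stats::rnorm(length(centers), 0, 1e-8)
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers, iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("no K-means restart converged")
  structure(list(k = as.integer(k), assignments = as.integer(best$cluster),
                 centroids = best$centers, objective = best$tot.withinss,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "imc_kmeans")
}

#' @export
print.imc_kmeans <- function(x, ...) {
  cat("imc_kmeans: k =", x$k, ",", length(x$assignments), "cells,",
      x$n_restarts, "restarts, objective =", format(x$objective), "\n")
  cat("cluster sizes:", paste(tabulate(x$assignments, x$k), collapse = " "), "\n")
  invisible(x)
}

#' Default minimum significant one-vs-one comparisons
#'
#' The rule that a marker is differential for a cluster when it is
#' significant (and upregulated) in at least `k - 3` of its `k - 1`
#' one-vs-one comparisons; at `k = 20` this is the 17-of-19 threshold.
#'
#' @param k Number of clusters.
#' @return Integer threshold, at least 1.
#' @export
min_significant_default <- function(k) {
  max(1L, as.integer(k) - 3L)
}

#' One-vs-one differential-marker calling per cluster
#'
#' For every cluster and marker, runs a two-sample Wilcoxon rank-sum test of
#' the marker in that cluster against each other cluster.  A comparison
#' counts as significant for the cluster only if `p < alpha` *and* the
#' cluster's median exceeds the other cluster's median (markers "expressed
#' in" a cluster are upregulated).  A marker is differential for a cluster
#' when its significant-comparison count reaches `min_significant`
#' (default `k - 3`, i.e. 17 of 19 at `k = 20`).  No multiplicity correction
#' is applied inside the counting; the threshold on the comparison count is
#' itself the stringency control.
#'
#' @param x Numeric matrix (cells x markers) on the clustering scale.
#' @param assignments Integer/factor cluster ids, one per row of `x`.
#' @param alpha Per-comparison significance level (default 0.05).
#' @param min_significant Minimum significant comparisons; default
#'   [min_significant_default()] of the cluster count.
#' @param panel Optional `marker_panel` fixing the marker tie-break order
#'   (defaults to column order of `x`).
#' @return An `imc_markers` list: `counts` (clusters x markers significant
#'   comparison counts), `medians`, `differential` (per cluster, marker
#'   names sorted by descending count then panel order), `names` (the
#'   "/"-joined cluster names), `min_significant`, `alpha`, `k`.
#' @export
differential_markers <- function(x, assignments, alpha = 0.05,
                                 min_significant = NULL, panel = NULL) {
  x <- as.matrix(x)
  cl <- as.integer(factor(assignments))
  levels_cl <- levels(factor(assignments))
  k <- length(levels_cl)
  if (k < 2) stop("differential-marker calling needs at least 2 clusters")
  if (is.null(min_significant)) min_significant <- min_significant_default(k)
  markers <- colnames(x) %||% paste0("marker", seq_len(ncol(x)))
  order_ref <- if (!is.null(panel)) {
    validate_panel(panel)
    c(intersect(panel$marker, markers), setdiff(markers, panel$marker))
  } else markers

  sizes <- tabulate(cl, k)
  small <- which(sizes < 2)
  if (length(small))
    warning("cluster(s) with fewer than 2 cells skipped in comparisons: ",
            paste(levels_cl[small], collapse = ", "))

  counts <- matrix(0L, k, length(markers),
                   dimnames = list(levels_cl, markers))
  med <- matrix(NA_real_, k, length(markers),
                dimnames = list(levels_cl, markers))
  by_cl <- split(seq_along(cl), cl)
  for (m in seq_along(markers)) {
    vals <- x[, m]
    med[, m] <- vapply(by_cl, function(i) stats::median(vals[i]), numeric(1))
    for (a in seq_len(k - 1)) {
      if (sizes[a] < 2) next
      va <- vals[by_cl[[a]]]
      for (b in (a + 1):k) {
        if (sizes[b] < 2) next
        vb <- vals[by_cl[[b]]]
        p <- suppressWarnings(
          stats::wilcox.test(va, vb, exact = FALSE)$p.value)
        if (!is.na(p) && p < alpha) {
          if (med[a, m] > med[b, m]) counts[a, m] <- counts[a, m] + 1L
          else if (med[b, m] > med[a, m]) counts[b, m] <- counts[b, m] + 1L
        }
      }
    }
  }

  differential <- lapply(seq_len(k), function(c) {
    hit <- markers[counts[c, ] >= min_significant]
    hit[order(-counts[c, hit], match(hit, order_ref))]
  })
  names(differential) <- levels_cl
  res <- structure(list(counts = counts, medians = med,
                        differential = differential,
                        min_significant = as.integer(min_significant),
                        alpha = alpha, k = as.integer(k)),
                   class = "imc_markers")
  res$names <- name_clusters(res)
  res
}

#' Name clusters by their differential markers
#'
#' Each cluster is named by its differential markers (sorted by descending
#' significant-comparison count, ties broken by panel order) joined with
#' "/"; a cluster with no differential marker gets the placeholder name
#' `"(none)"`, distinct from the annotation fallback `"unidentified"`.
#'
#' @param map An `imc_markers` object from [differential_markers()].
#' @return Named character vector of cluster names.
#' @export
name_clusters <- function(map) {
  stopifnot(inherits(map, "imc_markers"))
  vapply(map$differential, function(m)
    if (length(m) == 0) "(none)" else paste(m, collapse = "/"),
    character(1))
}

#' Annotation rules for cluster labeling
#'
#' An ordered rule set mapping differential-marker lists to cell-type
#' labels; the first rule whose marker set matches wins, and clusters
#' matching no rule are labeled `"unidentified"`.
#'
#' @param labels Character vector of unique rule labels, in priority order.
#' @param markers List of character vectors, the marker set per rule.
#' @param match `"any"` (rule fires if any of its markers is differential)
#'   or `"all"` (all must be), recycled per rule.
#' @return An `annotation_rules` object.
#' @export
annotation_rules <- function(labels, markers, match = "any") {
  if (anyDuplicated(labels)) stop("rule labels must be unique")
  if (length(labels) != length(markers))
    stop("labels and markers must have the same length")
  match <- rep_len(match, length(labels))
  if (!all(match %in% c("any", "all")))
    stop("match mode must be 'any' or 'all'")
  structure(Map(function(l, m, mm) list(label = l, markers = m, match = mm),
                labels, markers, match),
            class = "annotation_rules")
}

#' Default annotation rules
#'
#' Neutrophils (S100A8 or S100A9), then macrophages (F4/80), then tumor
#' cells (Vimentin or CD44); anything else falls through to
#' `"unidentified"`.
#'
#' @return An `annotation_rules` object.
#' @export
default_annotation_rules <- function() {
  annotation_rules(
    labels = c("neutrophils", "macrophages", "tumor cells"),
    markers = list(c("S100A8", "S100A9"), "F4/80", c("Vimentin", "CD44")),
    match = "any")
}

#' Annotate clusters with cell-type labels
#'
#' Applies an ordered rule set to each cluster's differential-marker list:
#' the first rule whose required markers are found (per its match mode)
#' assigns its label; clusters matching no rule are `"unidentified"`.
#'
#' @param map An `imc_markers` object.
#' @param rules An `annotation_rules` object.
#' @return Named character vector of labels, one per cluster.
#' @export
annotate_clusters <- function(map, rules = default_annotation_rules()) {
  stopifnot(inherits(map, "imc_markers"), inherits(rules, "annotation_rules"))
  vapply(map$differential, function(dm) {
    for (rule in rules) {
      hit <- if (rule$match == "any") length(intersect(rule$markers, dm)) > 0
             else all(rule$markers %in% dm)
      if (hit) return(rule$label)
    }
    "unidentified"
  }, character(1))
}

#' @export
print.imc_markers <- function(x, ...) {
  cat("imc_markers:", x$k, "clusters, threshold", x$min_significant, "of",
      x$k - 1, "one-vs-one comparisons at alpha =", x$alpha, "\n")
  for (c in names(x$differential))
    cat("  cluster ", c, ": ", x$names[[c]], "\n", sep = "")
  invisible(x)
}
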