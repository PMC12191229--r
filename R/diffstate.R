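#' Differential-state testing on sample-level medians
#'
#' Compares per-cluster marker expression between two conditions at the
#' sample level: for every (cluster, marker) pair the median expression is
#' computed per sample, an ordinary pooled-variance two-sample t-test is run
#' on the sample medians between conditions, and p-values are adjusted with
#' Benjamini-Hochberg jointly across all tested pairs.  This is a
#' deliberately plain sample-median contrast (no empirical-Bayes variance
#' moderation); its behavior is fully transparent at the typical 3-vs-3
#' region-of-interest design.  Pairs for which either condition contributes
#' fewer than 2 samples with cells in the cluster are reported untested.
#'
#' @param table Cell-table data frame with `sample_id`, `condition`, a
#'   cluster column, and marker columns (typically normalized values).
#' @param condition_a,condition_b The two condition labels to contrast; the
#'   estimate is mean(medians in `condition_b`) - mean(medians in
#'   `condition_a`).
#' @param cluster_col Name of the cluster column (default `"cluster"`).
#' @param markers Optional explicit marker columns.
#' @return A `DSResult` data frame: `cluster`, `marker`, `n_samples_a`,
#'   `n_samples_b`, `estimate`, `p_value`, `adjusted_p`, `tested`.
#' @export
ds_test <- function(table, condition_a, condition_b, cluster_col = "cluster",
                    markers = NULL) {
  for (col in c("sample_id", "condition", cluster_col))
    if (!col %in% names(table)) stop("table is missing column '", col, "'")
  for (cond in c(condition_a, condition_b))
    if (!cond %in% table$condition)
      stop("condition '", cond, "' absent from table")
  markers <- marker_columns(table, markers)

  keep <- table$condition %in% c(condition_a, condition_b)
  tab <- table[keep, , drop = FALSE]
  clusters <- sort(unique(tab[[cluster_col]]))

  res <- list()
  for (cl in clusters) {
    sub <- tab[tab[[cluster_col]] == cl, , drop = FALSE]
    for (m in markers) {
      med <- tapply(sub[[m]], sub$sample_id, stats::median)
      samp_cond <- tapply(sub$condition, sub$sample_id, `[`, 1)
      a <- med[samp_cond == condition_a]
      b <- med[samp_cond == condition_b]
      na <- sum(!is.na(a)); nb <- sum(!is.na(b))
      tested <- na >= 2 && nb >= 2
      est <- if (na >= 1 && nb >= 1) mean(b, na.rm = TRUE) - mean(a, na.rm = TRUE)
             else NA_real_
      p <- NA_real_
      if (tested) {
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
        if (sp2 == 0) {
          p <- if (est == 0) 1 else 0
        } else {
          p <- stats::t.test(b, a, var.equal = TRUE)$p.value
        }
      }
      res[[length(res) + 1L]] <- data.frame(
        cluster = cl, marker = m, n_samples_a = na, n_samples_b = nb,
        estimate = est, p_value = p, tested = tested,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$adjusted_p <- NA_real_
  out$adjusted_p[out$tested] <- stats::p.adjust(out$p_value[out$tested],
                                                method = "BH")
  rownames(out) <- NULL
  out[c("cluster", "marker", "n_samples_a", "n_samples_b", "estimate",
        "p_value", "adjusted_p", "tested")]
}
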