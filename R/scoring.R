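#' Size-bin score of a metastatic lesion
#'
#' Lesions measured on serial sections are scored by diameter: < 1 mm
#' scores 1, 1-3 mm scores 2, 3-5 mm scores 3, and > 5 mm scores 4.  Bins
#' are half-open `[low, high)` with the top bin closed below at 5 mm, so the
#' boundary diameters 1, 3 and 5 mm fall into the larger bin.
#'
#' @param diameter_mm Numeric vector of lesion diameters in mm (> 0).
#' @return Integer vector of scores in {1, 2, 3, 4}.
#' @examples
#' score_lesion(c(0.5, 2, 4, 7))  # 1 2 3 4
#' @export
score_lesion <- function(diameter_mm) {
  if (!is.numeric(diameter_mm) || any(!is.finite(diameter_mm)) ||
      any(diameter_mm <= 0))
    stop("diameter_mm must be positive and finite")
  as.integer(findInterval(diameter_mm, c(1, 3, 5)) + 1L)
}

#' Metastatic-burden score report for a lesion table
#'
#' Scores every lesion with [score_lesion()] and aggregates: per-section
#' subtotals and a per-sample total (the sum of lesion scores over all
#' sections of the sample).
#'
#' @param lesions Data frame with columns `sample_id`, `section_index`,
#'   `diameter_mm`; zero rows are allowed.
#' @return List of class `imc_score_report`: `per_lesion` (input plus
#'   `score`), `per_section` (`sample_id`, `section_index`,
#'   `section_score`, `n_lesions`) and `per_sample` (`sample_id`,
#'   `n_lesions`, `total_score`).
#' @export
score_report <- function(lesions) {
  required <- c("sample_id", "section_index", "diameter_mm")
  missing <- setdiff(required, names(lesions))
  if (length(missing))
    stop("lesion table is missing column(s): ", paste(missing, collapse = ", "))
  per_lesion <- lesions
  per_lesion$score <- if (nrow(lesions)) score_lesion(lesions$diameter_mm)
                      else integer(0)
  if (nrow(per_lesion)) {
    key <- interaction(per_lesion$sample_id, per_lesion$section_index,
                       drop = TRUE)
    per_section <- data.frame(
      sample_id = tapply(per_lesion$sample_id, key, `[`, 1),
      section_index = as.integer(tapply(per_lesion$section_index, key, `[`, 1)),
      section_score = as.integer(tapply(per_lesion$score, key, sum)),
      n_lesions = as.integer(tapply(per_lesion$score, key, length)),
      stringsAsFactors = FALSE)
    per_section <- per_section[order(per_section$sample_id,
                                     per_section$section_index), ]
    per_sample <- data.frame(
      sample_id = as.character(
        tapply(per_lesion$sample_id, per_lesion$sample_id, `[`, 1)),
      n_lesions = as.integer(table(per_lesion$sample_id)),
      total_score = as.integer(
        tapply(per_lesion$score, per_lesion$sample_id, sum)),
      stringsAsFactors = FALSE)
  } else {
    per_section <- data.frame(sample_id = character(0),
                              section_index = integer(0),
                              section_score = integer(0),
                              n_lesions = integer(0),
                              stringsAsFactors = FALSE)
    per_sample <- data.frame(sample_id = character(0), n_lesions = integer(0),
                             total_score = integer(0),
                             stringsAsFactors = FALSE)
  }
  rownames(per_section) <- rownames(per_sample) <- NULL
  structure(list(per_lesion = per_lesion, per_section = per_section,
                 per_sample = per_sample),
            class = "imc_score_report")
}

#' Total metastatic-burden score of one sample
#'
#' All lesion records must share one `sample_id`; the total is the sum of
#' per-lesion size-bin scores over all sections.  An empty lesion list
#' scores 0.
#'
#' @param lesions Data frame as in [score_report()], restricted to a single
#'   sample.
#' @return List: `sample_id` (NA for an empty list), `n_lesions`,
#'   `total_score`, `per_section` subtotals.
#' @export
score_sample <- function(lesions) {
  ids <- unique(lesions$sample_id)
  if (length(ids) > 1)
    stop("score_sample expects a single sample_id, got: ",
         paste(ids, collapse = ", "))
  rep <- score_report(lesions)
  list(sample_id = if (length(ids)) ids else NA_character_,
       n_lesions = nrow(rep$per_lesion),
       total_score = sum(rep$per_lesion$score),
       per_section = rep$per_section)
}

#' @export
print.imc_score_report <- function(x, ...) {
  cat("imc_score_report:", nrow(x$per_lesion), "lesions,",
      nrow(x$per_sample), "samples\n")
  print(x$per_sample, ...)
  invisible(x)
}
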