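.pipeline_stages <- c("simulate", "segment", "quantify", "normalize",
                      "phenotype", "annotate", "spatial", "ds", "score")

#' Default pipeline configuration
#'
#' Parameters for an end-to-end run on synthetic data: two conditions with
#' three regions of interest each, a modest scene per sample, and the
#' production analysis settings (threshold fraction 0.475 inside the 40-55%
#' in-cell window, k = 20 clusters, the k - 3 one-vs-one threshold that
#' gives 17 of 19 at k = 20).  `n_restarts` defaults to a desk-scale 100 and
#' can be raised to the production 100,000.
#'
#' @param seed Integer master seed; per-sample scene seeds are derived from
#'   it.
#' @return A nested list of stage parameters.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    conditions = c("control", "treated"),
    n_samples_per_condition = 3L,
    scene = list(image_height_px = 128L, image_width_px = 128L,
                 pixel_size_um = 1, n_cells = 60L, cell_radius_um = 4,
                 intensity_noise_sd = 0.3, background_level = 0.5),
    segmentation = list(target_fraction = 0.475, prominence = NULL, sigma = 1),
    phenotyping = list(k = 20L, n_restarts = 100L, alpha = 0.05,
                       min_significant = NULL),
    spatial = list(immune_types = c("neutrophils", "macrophages"),
                   reference_type = "tumor cells"),
    lesions = list(sections_per_sample = 10L, section_spacing_um = 150,
                   lesions_per_section_rate = 2,
                   input_csv = NULL),
    stages = "all"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults of [default_pipeline_config()];
#' unspecified parameters keep their defaults.
#'
#' @param path YAML config path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), user)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate, segment, quantify, normalize, phenotype, annotate,
#' spatial, ds and score in order (or the subset in `stages`), writing every
#' intermediate artifact to `out_dir` plus a JSON manifest recording
#' parameters, seed, package version and per-stage counts.  Rerunning with
#' the same configuration reproduces all outputs; every stochastic stage is
#' seeded from `config$seed`.
#'
#' @param config Configuration list, see [default_pipeline_config()] /
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages `"all"` or a character subset of the stage names; the
#'   `score` stage can run standalone on a lesion CSV supplied in
#'   `config$lesions$input_csv`.
#' @return Invisibly, a list with the main artifacts (`cells`, `markers`,
#'   `annotations`, `spatial`, `ds`, `scores`, `manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         stages = config$stages) {
  if (identical(stages, "all") || is.null(stages)) stages <- .pipeline_stages
  unknown <- setdiff(stages, .pipeline_stages)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- default_panel()
  write_panel(panel, file.path(out_dir, "panel.csv"))

  seed <- as.integer(config$seed)
  conditions <- rep(config$conditions, each = config$n_samples_per_condition)
  sample_ids <- paste0("ROI", seq_along(conditions))
  completed <- list()
  art <- list()
  scenes <- NULL
  masks <- NULL
  cells <- NULL
  norm <- NULL
  phen <- NULL
  dmm <- NULL

  scene_for <- function(i) {
    sc <- config$scene
    scene_spec(image_height_px = sc$image_height_px,
               image_width_px = sc$image_width_px,
               pixel_size_um = sc$pixel_size_um, n_cells = sc$n_cells,
               cell_radius_um = sc$cell_radius_um,
               intensity_noise_sd = sc$intensity_noise_sd,
               background_level = sc$background_level,
               seed = seed + i)
  }

  if ("simulate" %in% stages) .stage("simulate", {
    scenes <- lapply(seq_along(sample_ids), function(i) make_scene(scene_for(i), panel))
    names(scenes) <- sample_ids
    for (s in sample_ids) {
      write_image(scenes[[s]]$image, file.path(out_dir, paste0(s, "_image.tiff")))
      write_mask(imc_mask(scenes[[s]]$truth$label_grid,
                          config$scene$pixel_size_um),
                 file.path(out_dir, paste0(s, "_truth_labels.tiff")))
      utils::write.table(scenes[[s]]$truth$centroids,
                         file.path(out_dir, paste0(s, "_truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    completed$simulate <- list(n_samples = length(sample_ids),
                               n_cells_true = sum(vapply(scenes, function(x)
                                 nrow(x$truth$centroids), numeric(1))))
  })

  if ("segment" %in% stages) .stage("segment", {
    if (is.null(scenes)) stop("segment requires the simulate stage")
    sg <- config$segmentation
    masks <- lapply(sample_ids, function(s) {
      seg <- segment_image(scenes[[s]]$image, panel,
                           target_fraction = sg$target_fraction,
                           prominence = sg$prominence, sigma = sg$sigma)
      write_mask(seg$mask, file.path(out_dir, paste0(s, "_mask.tiff")))
      seg$mask
    })
    names(masks) <- sample_ids
    completed$segment <- list(n_cells = sum(vapply(masks, n_cells, numeric(1))))
  })

  if ("quantify" %in% stages) .stage("quantify", {
    if (is.null(masks)) stop("quantify requires the segment stage")
    cells <- do.call(rbind, lapply(seq_along(sample_ids), function(i)
      quantify(scenes[[sample_ids[i]]]$image, masks[[sample_ids[i]]], panel,
               sample_id = sample_ids[i], condition = conditions[i])))
    cells$cell_id <- seq_len(nrow(cells))  # unique across samples
    write_cell_table(cells, file.path(out_dir, "cells.tsv"))
    art$cells <- file.path(out_dir, "cells.tsv")
    completed$quantify <- list(n_cells = nrow(cells))
  })

  if ("normalize" %in% stages) .stage("normalize", {
    if (is.null(cells)) stop("normalize requires the quantify stage")
    norm <- normalize_intensities(cells)
    ntab <- cbind(cells[c("cell_id", "sample_id", "condition")],
                  as.data.frame(norm, check.names = FALSE))
    utils::write.table(ntab, file.path(out_dir, "cells_normalized.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(transform = attr(norm, "transform")),
                         file.path(out_dir, "normalization.json"),
                         auto_unbox = TRUE)
    completed$normalize <- list(n_cells = nrow(norm),
                                n_markers = ncol(norm))
  })

  if ("phenotype" %in% stages) .stage("phenotype", {
    if (is.null(norm)) stop("phenotype requires the normalize stage")
    ph <- config$phenotyping
    phen <- kmeans_cluster(norm, k = ph$k, n_restarts = ph$n_restarts,
                           seed = seed)
    dmm <- suppressWarnings(
      differential_markers(norm, phen$assignments, alpha = ph$alpha,
                           min_significant = ph$min_significant,
                           panel = panel))
    jsonlite::write_json(
      list(k = phen$k, objective = phen$objective,
           min_significant = dmm$min_significant,
           names = as.list(dmm$names),
           differential = dmm$differential),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    completed$phenotype <- list(k = phen$k, objective = phen$objective)
  })

  if ("annotate" %in% stages) .stage("annotate", {
    if (is.null(phen)) stop("annotate requires the phenotype stage")
    labels <- annotate_clusters(dmm)
    cells$cluster <- phen$assignments
    cells$annotation <- unname(labels[as.character(phen$assignments)])
    write_cell_table(cells, file.path(out_dir, "cells_annotated.tsv"))
    art$annotations <- file.path(out_dir, "cells_annotated.tsv")
    completed$annotate <- list(
      n_annotated = sum(cells$annotation != "unidentified"),
      labels = as.list(table(cells$annotation)))
  })

  if ("spatial" %in% stages) .stage("spatial", {
    if (is.null(cells) || is.null(cells$annotation))
      stop("spatial requires the annotate stage")
    sp <- config$spatial
    summ <- summarize_median_distance(cells, immune_types = sp$immune_types,
                                      reference_type = sp$reference_type)
    utils::write.table(summ, file.path(out_dir, "spatial_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    art$spatial <- file.path(out_dir, "spatial_summary.tsv")
    completed$spatial <- list(n_rows = nrow(summ))
  })

  if ("ds" %in% stages) .stage("ds", {
    if (is.null(norm) || is.null(cells$cluster))
      stop("ds requires the annotate stage")
    ntab <- cbind(cells[c("cell_id", "x_um", "y_um", "sample_id", "condition",
                          "cluster")],
                  as.data.frame(norm, check.names = FALSE))
    res <- ds_test(ntab, config$conditions[1], config$conditions[2])
    utils::write.table(res, file.path(out_dir, "ds_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    art$ds <- file.path(out_dir, "ds_results.tsv")
    completed$ds <- list(n_tested = sum(res$tested),
                         n_significant = sum(res$adjusted_p < 0.05,
                                             na.rm = TRUE))
  })

  if ("score" %in% stages) .stage("score", {
    le <- config$lesions
    lesions <- if (!is.null(le$input_csv)) {
      utils::read.csv(le$input_csv, stringsAsFactors = FALSE)
    } else {
      series <- make_lesion_series(lesion_series_spec(
        n_samples = length(sample_ids),
        sections_per_sample = le$sections_per_sample,
        section_spacing_um = le$section_spacing_um,
        lesions_per_section_rate = le$lesions_per_section_rate,
        seed = seed + 1000L))
      series$lesions
    }
    rep <- score_report(lesions)
    utils::write.csv(rep$per_sample, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$per_section,
                     file.path(out_dir, "scores_per_section.csv"),
                     row.names = FALSE)
    art$scores <- file.path(out_dir, "scores.csv")
    completed$score <- list(n_lesions = nrow(rep$per_lesion),
                            total_scores = as.list(stats::setNames(
                              rep$per_sample$total_score,
                              rep$per_sample$sample_id)))
  })

  manifest <- list(package = "imcpheno",
                   version = as.character(utils::packageVersion("imcpheno")),
                   seed = seed,
                   parameters = config[setdiff(names(config), "stages")],
                   stages = completed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  art$manifest <- file.path(out_dir, "manifest.json")
  invisible(art)
}
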