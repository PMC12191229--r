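test_that("scene generation is deterministic and handles the empty scene", {
  panel <- tiny_panel()
  spec <- scene_spec(image_height_px = 96, image_width_px = 96,
                     phenotypes = tiny_phenotypes(), n_cells = 25,
                     cell_radius_um = 3, seed = 7)
  a <- make_scene(spec, panel)
  b <- make_scene(spec, panel)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)

  empty <- make_scene(scene_spec(image_height_px = 32, image_width_px = 32,
                                 phenotypes = tiny_phenotypes(), n_cells = 0,
                                 background_level = 0.4, seed = 3), panel)
  expect_identical(unique(as.vector(empty$truth$label_grid)), 0L)
  expect_equal(nrow(empty$truth$centroids), 0L)
})

test_that("placed labels are conserved and phenotype draws follow proportions", {
  panel <- tiny_panel()
  spec <- scene_spec(image_height_px = 400, image_width_px = 400,
                     phenotypes = tiny_phenotypes(), n_cells = 1000,
                     cell_radius_um = 3, seed = 5)
  # override mixture to 0.3 / 0.7
  spec$phenotypes[[1]]$proportion <- 0.3
  spec$phenotypes[[2]]$proportion <- 0.7
  sc <- make_scene(spec, panel)
  labs <- sc$truth$label_grid
  expect_equal(sort(unique(labs[labs > 0])), 1:1000)
  expect_setequal(names(sc$truth$phenotype), as.character(1:1000))

  n1 <- sum(sc$truth$phenotype == "tumor cells")
  ci <- qbinom(c(0.005, 0.995), 1000, 0.3)  # binomial 99% interval
  expect_gte(n1, ci[1])
  expect_lte(n1, ci[2])

  # centroids lie inside image bounds
  expect_true(all(sc$truth$centroids$x_um >= 0 &
                  sc$truth$centroids$x_um <= 399))
  expect_true(all(sc$truth$centroids$y_um >= 0 &
                  sc$truth$centroids$y_um <= 399))
})

test_that("membrane markers are zero inside the nuclear disc of a noise-free scene", {
  panel <- tiny_panel()
  spec <- scene_spec(image_height_px = 96, image_width_px = 96,
                     phenotypes = tiny_phenotypes(), n_cells = 12,
                     cell_radius_um = 6, intensity_noise_sd = 0,
                     background_level = 0, seed = 2)
  sc <- make_scene(spec, panel)
  labs <- sc$truth$label_grid
  cents <- sc$truth$centroids
  r_nuc <- 0.6 * 6
  for (i in cents$cell_id) {
    # pixels strictly inside the nuclear disc
    idx <- which(labs == i, arr.ind = TRUE)
    d <- sqrt(((idx[, "col"] - 1) - cents$x_um[i])^2 +
              ((idx[, "row"] - 1) - cents$y_um[i])^2)
    nuc <- idx[d < r_nuc - 1e-9, , drop = FALSE]
    for (m in c("CD44", "F4/80"))
      expect_true(all(sc$image$channels[[m]][nuc] == 0))
  }
})

test_that("cell tables carry conditions per sample and separable phenotypes are recoverable", {
  panel <- tiny_panel()
  spec <- scene_spec(phenotypes = tiny_phenotypes(), n_cells = 50, seed = 9)
  # 3 ROIs per condition
  cmap <- setNames(rep(c("control", "treated"), each = 3),
                   paste0("ROI", 1:6))
  out <- make_cell_table(spec, panel, n_samples = 6, condition_map = cmap)
  expect_setequal(unique(out$table$sample_id), paste0("ROI", 1:6))
  expect_equal(length(unique(out$table$sample_id)), 6L)
  expect_equal(unname(table(out$table$condition)[c("control", "treated")]),
               c(150L, 150L), ignore_attr = TRUE)
  expect_error(make_cell_table(spec, panel, n_samples = 0), "positive")

  # zero noise: all rows of one phenotype identical
  one <- tiny_phenotypes()[1]
  one[[1]]$proportion <- 1
  spec0 <- scene_spec(phenotypes = one, n_cells = 10,
                      intensity_noise_sd = 0, seed = 4)
  t0 <- make_cell_table(spec0, panel)$table
  mk <- c("DNA1", "Ki67", "CD44", "F4/80")
  expect_true(all(apply(t0[mk], 2, function(v) length(unique(v)) == 1)))

  # 10 noise SDs of separation: nearest-centroid classification is perfect
  spec_sep <- scene_spec(phenotypes = tiny_phenotypes(sep = 50),
                         n_cells = 400, intensity_noise_sd = 0.1, seed = 8)
  out2 <- make_cell_table(spec_sep, panel)
  m <- log1p(as.matrix(out2$table[mk]))
  truth <- out2$truth$phenotype
  centroids <- rbind(colMeans(m[truth == "tumor cells", ]),
                     colMeans(m[truth == "macrophages", ]))
  pred <- c("tumor cells", "macrophages")[
    apply(m, 1, function(row)
      which.min(colSums((t(centroids) - row)^2)))]
  expect_equal(sum(pred != truth), 0L)
})

test_that("lesion series honor the serial-section design and regenerate deterministically", {
  spec <- lesion_series_spec(n_samples = 4, lesions_per_section_rate = 2,
                             seed = 21)
  out <- make_lesion_series(spec)
  # 10 sections per sample by default
  cnt <- table(out$sections$sample_id)
  expect_true(all(cnt == 10))
  expect_equal(sort(unique(out$sections$section_index)), 1:10)
  expect_true(all(out$lesions$diameter_mm > 0))

  again <- make_lesion_series(spec)
  expect_identical(out, again)

  # recorded true scores equal an independent recomputation
  for (s in out$sample_scores$sample_id) {
    d <- out$lesions$diameter_mm[out$lesions$sample_id == s]
    expect_equal(out$sample_scores$total_score[
      out$sample_scores$sample_id == s], sum(score_lesion(d)))
  }

  none <- make_lesion_series(lesion_series_spec(n_samples = 3,
                                                lesions_per_section_rate = 0,
                                                seed = 1))
  expect_equal(nrow(none$lesions), 0L)
  expect_true(all(none$sample_scores$total_score == 0))
})
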