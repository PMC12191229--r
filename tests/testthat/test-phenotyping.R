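test_that("K-means clustering is deterministic, optimal on small cases, monotone in restarts", {
  set.seed(10)
  x <- matrix(rnorm(40), 20, 2)

  # k = 1: objective is the total SS about the global centroid
  km1 <- kmeans_cluster(x, k = 1, n_restarts = 1, seed = 1)
  expect_equal(km1$objective, sum(scale(x, scale = FALSE)^2))

  # determinism under a fixed seed
  a <- kmeans_cluster(x, k = 3, n_restarts = 10, seed = 5)
  b <- kmeans_cluster(x, k = 3, n_restarts = 10, seed = 5)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$objective, b$objective)

  # two blobs 10 SDs apart, k = 2: exact ground-truth partition
  blob <- rbind(matrix(rnorm(60, 0), ncol = 2),
                matrix(rnorm(60, 10), ncol = 2))
  truth <- rep(1:2, each = 30)
  km2 <- kmeans_cluster(blob, k = 2, n_restarts = 10, seed = 2)
  expect_equal(ari(km2$assignments, truth), 1)

  # objective equals the exhaustive minimum for n <= 12, k = 2
  for (seed in 1:3) {
    set.seed(seed)
    tiny <- matrix(rnorm(24), 12, 2)
    km <- kmeans_cluster(tiny, k = 2, n_restarts = 50, seed = seed)
    expect_equal(km$objective, wss_exhaustive_k2(tiny), tolerance = 1e-8)
    # invariant: reported objective matches the recomputed assignment SS
    expect_equal(km$objective, wss_objective(tiny, km$assignments),
                 tolerance = 1e-8)
  }

  # best objective is non-increasing in the restart count (same stream)
  set.seed(20)
  hard <- matrix(rnorm(200), 100, 2)
  objs <- vapply(c(1, 5, 25), function(r)
    kmeans_cluster(hard, k = 6, n_restarts = r, seed = 7)$objective,
    numeric(1))
  expect_true(all(diff(objs) <= 1e-12))

  expect_error(kmeans_cluster(x, k = 30), "exceeds")
})

test_that("one-vs-one rule calls markers elevated in a single cluster of twenty", {
  # 20 clusters x 15 cells; marker "M" elevated only in cluster 1
  set.seed(31)
  k <- 20; n_per <- 15
  cl <- rep(1:k, each = n_per)
  m_null <- rnorm(k * n_per)
  m_hit <- m_null + ifelse(cl == 1, 8, 0)
  x <- cbind(M = m_hit, N = m_null)
  dm <- differential_markers(x, cl)
  expect_equal(dm$min_significant, 17L)          # k - 3 at k = 20
  expect_equal(unname(dm$counts[1, "M"]), 19L)   # significant in all 19
  expect_true("M" %in% dm$differential[["1"]])
  # an identically distributed marker is never differential
  expect_true(all(vapply(dm$differential, function(d) !"N" %in% d,
                         logical(1))))

  # elevated against only 16 of 19 others: below the 17-of-19 bar
  m_partial <- m_null + ifelse(cl == 1, 8, ifelse(cl %in% 2:4, 8, 0))
  x2 <- cbind(M = m_partial)
  dm2 <- differential_markers(x2, cl)
  expect_lte(unname(dm2$counts[1, "M"]), 16L)
  expect_false("M" %in% dm2$differential[["1"]])

  # a cluster with fewer than 2 cells is skipped with a warning
  cl3 <- cl; cl3[cl3 == 20] <- 19; cl3[1] <- 20L
  expect_warning(differential_markers(cbind(M = m_hit), cl3), "fewer than 2")
})

test_that("defining markers of separable phenotypes are recovered as differential", {
  panel <- default_panel()
  spec <- scene_spec(phenotypes = default_phenotypes(),
                     n_cells = 600, intensity_noise_sd = 0.3, seed = 14)
  out <- make_cell_table(spec, panel)
  nm <- normalize_intensities(out$table)
  km <- kmeans_cluster(nm, k = 6, n_restarts = 20, seed = 3)
  expect_gte(ari(km$assignments, out$truth$phenotype), 0.90)
  dm <- differential_markers(nm, km$assignments, panel = panel)
  ann <- annotate_clusters(dm)
  # each recovered cluster carries its phenotype's defining markers
  defs <- list("tumor cells" = c("Vimentin", "CD44"),
               "macrophages" = "F4/80",
               "neutrophils" = c("S100A8", "S100A9"))
  for (cid in names(dm$differential)) {
    truth_mode <- names(which.max(table(
      out$truth$phenotype[km$assignments == as.integer(cid)])))
    if (truth_mode %in% names(defs))
      expect_true(any(defs[[truth_mode]] %in% dm$differential[[cid]]),
                  info = paste("cluster", cid, "->", truth_mode))
  }
})

test_that("cluster names join differential markers with deterministic tie-breaks", {
  dm <- structure(list(
    counts = matrix(c(19L, 18L, 0L), 1, 3,
                    dimnames = list("1", c("F4/80", "CD68", "CD4"))),
    differential = list("1" = c("F4/80", "CD68")),
    min_significant = 17L, alpha = 0.05, k = 20L), class = "imc_markers")
  expect_equal(unname(name_clusters(dm)), "F4/80/CD68")

  dm$differential <- list("1" = character(0))
  expect_equal(unname(name_clusters(dm)), "(none)")

  # tie in counts: panel order decides
  set.seed(8)
  cl <- rep(1:2, each = 20)
  v <- rnorm(40) + ifelse(cl == 1, 6, 0)
  x <- cbind(CD68 = v, `F4/80` = v)  # identical counts by construction
  dmt <- differential_markers(x, cl, panel = default_panel())
  expect_equal(dmt$differential[["1"]], c("F4/80", "CD68"))  # panel order
})

test_that("annotation rules fire in order with an unidentified fallback", {
  mk_dm <- function(markers) structure(list(
    counts = matrix(0L, 1, 1, dimnames = list("1", "x")),
    differential = list("1" = markers),
    min_significant = 17L, alpha = 0.05, k = 20L), class = "imc_markers")

  expect_equal(unname(annotate_clusters(mk_dm(c("S100A8", "Ly6G")))),
               "neutrophils")
  expect_equal(unname(annotate_clusters(mk_dm("CD62L"))), "unidentified")
  # neutrophil rule precedes macrophage rule
  expect_equal(unname(annotate_clusters(mk_dm(c("S100A9", "F4/80")))),
               "neutrophils")
  expect_equal(unname(annotate_clusters(mk_dm(c("F4/80", "CD68")))),
               "macrophages")
  expect_equal(unname(annotate_clusters(mk_dm(c("Vimentin", "Ki67")))),
               "tumor cells")

  # match = "all" requires the full marker set
  rules <- annotation_rules("double positive", list(c("CD4", "CD8a")), "all")
  expect_equal(unname(annotate_clusters(mk_dm(c("CD4", "CD8a")), rules)),
               "double positive")
  expect_equal(unname(annotate_clusters(mk_dm("CD4"), rules)), "unidentified")
  expect_error(annotation_rules(c("a", "a"), list("x", "y")), "unique")
})
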