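make_blob_image <- function(centers, nr = 64, nc = 64, amp = 100, sd = 3) {
  g <- matrix(0, nr, nc)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    g <- g + amp * outer(exp(-((seq_len(nr) - r0)^2) / (2 * sd^2)),
                         exp(-((seq_len(nc) - c0)^2) / (2 * sd^2)))
  }
  g
}

test_that("composites select compartment channels, rescale to [0,1] and are idempotent", {
  panel <- tiny_panel()
  chans <- list(DNA1 = matrix(2, 8, 8), Ki67 = matrix(1:64 / 8, 8, 8),
                CD44 = matrix(5, 8, 8), `F4/80` = matrix(0, 8, 8))
  img <- imc_image(chans)

  nuc <- make_composite(img, panel, "nuclear")
  expect_equal(unclass(nuc),
               (chans$DNA1 + chans$Ki67) / max(chans$DNA1 + chans$Ki67),
               ignore_attr = TRUE)
  # nuclear composite includes the nuclear marker, not the membrane one
  full <- default_panel()
  img23 <- imc_image(lapply(setNames(full$marker, full$marker), function(m)
    matrix(as.numeric(m == "Ki67") + as.numeric(m == "CD44"), 4, 4) + 0.1))
  nuc23 <- make_composite(img23, full, "nuclear")
  memb23 <- make_composite(img23, full, "membrane")
  expect_gt(max(nuc23), 0)
  expect_equal(unique(as.vector(unclass(nuc23))), 1)    # Ki67 in, CD44 out
  expect_equal(unique(as.vector(unclass(memb23))), 1)   # CD44 only

  # single channel: composite equals channel / max
  single <- imc_image(list(Ki67 = chans$Ki67))
  comp1 <- make_composite(single, panel, "nuclear")
  expect_equal(unclass(comp1), chans$Ki67 / max(chans$Ki67),
               ignore_attr = TRUE)

  # two identical channels: identical to either after rescaling
  two <- imc_image(list(CD44 = chans$Ki67, `F4/80` = chans$Ki67))
  comp2 <- make_composite(two, panel, "membrane")
  expect_equal(unclass(comp2), chans$Ki67 / max(chans$Ki67),
               ignore_attr = TRUE)

  expect_error(make_composite(single, panel, "membrane"), "compartment")
})

test_that("quantile thresholding hits the target fraction", {
  comp <- matrix(1:100, 10, 10)
  thr <- select_threshold(comp, 0.5)
  expect_equal(sum(comp >= thr), 50L)
  expect_equal(attr(thr, "achieved_fraction"), 0.5)

  expect_error(select_threshold(matrix(3, 5, 5)), "constant")
  expect_error(select_threshold(comp, 1.2), "target_fraction")

  # heavy ties: 60% exact zeros pushes the achieved fraction past the target
  tied <- matrix(c(rep(0, 60), runif(40)), 10, 10)
  thr2 <- select_threshold(tied, 0.5)
  achieved <- attr(thr2, "achieved_fraction")
  expect_equal(achieved, mean(tied >= as.numeric(thr2)))
  expect_gte(achieved, 0.5)
})

test_that("in-cell fraction on the default synthetic scene lands in the 40-55% window", {
  sc <- make_scene(scene_spec(seed = 1), default_panel())
  comp <- make_composite(sc$image, default_panel(), "combined")
  thr <- select_threshold(comp)
  achieved <- attr(thr, "achieved_fraction")
  expect_gte(achieved, 0.40)
  expect_lte(achieved, 0.55)
})

test_that("prominence-filtered maxima find blob peaks and are monotone in prominence", {
  one <- make_blob_image(cbind(32, 32))
  mask <- matrix(TRUE, 64, 64)
  seeds <- find_maxima(structure(one, class = "imc_composite"), mask,
                       prominence = 5)
  expect_equal(nrow(seeds), 1L)
  expect_lt(sqrt((seeds$row - 32)^2 + (seeds$col - 32)^2), 2)

  # two blobs 10 blob-sd apart: exactly two seeds
  two <- make_blob_image(cbind(c(20, 50), c(20, 50)))
  seeds2 <- find_maxima(structure(two, class = "imc_composite"), mask,
                        prominence = 5)
  expect_equal(nrow(seeds2), 2L)

  # prominence above the global dynamic range: no seeds
  none <- find_maxima(structure(two, class = "imc_composite"), mask,
                      prominence = max(two) + 1)
  expect_equal(nrow(none), 0L)

  # empty mask: empty seed list, not an error
  expect_equal(nrow(find_maxima(structure(two, class = "imc_composite"),
                                matrix(FALSE, 64, 64))), 0L)

  # monotone: raising prominence never yields more seeds
  set.seed(3)
  noisy <- two + matrix(runif(64 * 64, 0, 5), 64)
  counts <- vapply(c(0, 1, 5, 20, 60),
                   function(p) nrow(find_maxima(
                     structure(noisy, class = "imc_composite"), mask,
                     prominence = p)), numeric(1))
  expect_true(all(diff(counts) <= 0))

  # plateau maxima collapse to one centered seed
  plat <- matrix(0, 32, 32)
  plat[10:14, 10:14] <- 7
  s <- find_maxima(structure(plat, class = "imc_composite"),
                   matrix(TRUE, 32, 32), prominence = 1, sigma = 0)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$row, s$col), c(12, 12))
})

test_that("seeded watershed grows disjoint regions that contain their seeds", {
  two <- make_blob_image(cbind(c(20, 50), c(20, 50)))
  comp <- structure(two / max(two), class = "imc_composite")
  mask <- unclass(comp) > 0.05
  seeds <- find_maxima(comp, mask, prominence = 0.1)
  m <- segment_particles(comp, seeds, mask)
  expect_s3_class(m, "imc_mask")
  expect_equal(n_cells(m), 2L)
  for (i in seq_len(nrow(seeds)))
    expect_gt(m[seeds$row[i], seeds$col[i]], 0)

  # one seed on a connected mask claims the whole mask component
  one <- make_blob_image(cbind(16, 16), nr = 32, nc = 32)
  comp1 <- structure(one / max(one), class = "imc_composite")
  mask1 <- unclass(comp1) > 0.05
  seeds1 <- find_maxima(comp1, mask1, prominence = 0.2)
  m1 <- segment_particles(comp1, seeds1, mask1)
  expect_equal(sum(m1 == 1), sum(mask1))

  # zero seeds: empty mask result
  m0 <- segment_particles(comp1, seeds1[0, ], mask1)
  expect_equal(n_cells(m0), 0L)

  # a seed outside the mask is dropped with a warning
  bad <- rbind(seeds1, data.frame(row = 1, col = 1, value = 0, prominence = 0))
  expect_warning(mb <- segment_particles(comp1, bad, mask1), "dropped")
  expect_equal(n_cells(mb), 1L)
})

test_that("segmentation recovers cell count and centroids on synthetic scenes", {
  panel <- default_panel()
  sc <- make_scene(scene_spec(seed = 1), panel)
  seg <- segment_image(sc$image, panel)
  found <- n_cells(seg$mask)
  truth <- nrow(sc$truth$centroids)
  expect_lte(abs(found - truth) / truth, 0.10)

  # noise-free sparse scene: among cells separated by >= 4 radii from their
  # nearest neighbor, >= 95% of region centroids fall within one cell radius
  # of truth.  The threshold target mirrors the operator's choice: the
  # in-cell fraction is set near the scene's actual cell coverage (sparse
  # validation scenes cover far less area than dense tissue).
  spec <- scene_spec(image_height_px = 200, image_width_px = 200,
                     n_cells = 40, cell_radius_um = 4,
                     intensity_noise_sd = 0, background_level = 0.2,
                     seed = 11)
  sc2 <- make_scene(spec, panel)
  coverage <- mean(sc2$truth$label_grid > 0)
  seg2 <- segment_image(sc2$image, panel, target_fraction = coverage)
  tab <- quantify(sc2$image, seg2$mask, panel)
  tru <- sc2$truth$centroids
  dmat <- as.matrix(dist(tru[c("x_um", "y_um")]))
  diag(dmat) <- Inf
  isolated <- apply(dmat, 1, min) >= 4 * 4
  expect_gte(sum(isolated), 10)
  hit <- vapply(which(isolated), function(i)
    min(sqrt((tab$x_um - tru$x_um[i])^2 + (tab$y_um - tru$y_um[i])^2)) <= 4,
    logical(1))
  expect_gte(mean(hit), 0.95)
})
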