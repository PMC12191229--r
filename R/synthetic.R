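#' Default synthetic phenotypes
#'
#' Marker-mean vectors for six spatially intermingled cell populations that
#' emulate a metastatic tumor-immune microenvironment: tumor cells
#' (Vimentin/CD44/PanCK/Ki67), macrophages (F4/80, CD68, CD11b, CD163),
#' neutrophils (S100A8/S100A9/Ly6G), CD4 and CD8 T cells, and B cells
#' (B220).  Every cell expresses the DNA channels; non-defining markers sit
#' at a low baseline.  Means are per-pixel ion counts.
#'
#' @param panel A `marker_panel` supplying marker names and compartments.
#' @param hi,lo,dna Mean per-pixel intensity for defining markers, baseline
#'   markers and DNA channels.
#' @return List of phenotypes, each a list with `name`, `means` (named
#'   numeric over all panel markers) and `proportion`.
#' @export
default_phenotypes <- function(panel = default_panel(), hi = 40, lo = 0.5,
                               dna = 30) {
  base <- stats::setNames(rep(lo, nrow(panel)), panel$marker)
  base[panel$compartment == "dna"] <- dna
  mk <- function(name, defining, proportion) {
    m <- base
    m[defining] <- hi
    list(name = name, means = m, proportion = proportion)
  }
  list(
    mk("tumor cells", c("Vimentin", "CD44", "PanCK", "Ki67"), 0.40),
    mk("macrophages", c("F4/80", "CD68", "CD11b", "CD163"), 0.20),
    mk("neutrophils", c("S100A8", "S100A9", "Ly6G"), 0.15),
    mk("CD4", c("CD4", "CD62L", "CD127"), 0.10),
    mk("CD8", c("CD8a", "CD62L"), 0.10),
    mk("B cells", c("B220", "CD86"), 0.05)
  )
}

#' Specification for a synthetic multichannel scene
#'
#' Defines the study-like conditions under which the imaging stages are
#' exercised: image size, pixel size (1 um, matching typical laser-ablation
#' rasters), phenotype mixture, cell number and geometry, lognormal
#' multiplicative intensity noise, and additive background.
#'
#' @param image_height_px,image_width_px Positive integers; grid size.
#' @param pixel_size_um Positive scalar, micrometers per pixel.
#' @param phenotypes List as produced by [default_phenotypes()]; proportions
#'   must sum to 1 and marker names must be a subset of the panel used.
#' @param n_cells Number of cells to place.
#' @param cell_radius_um Cell radius; the nuclear core has radius
#'   `0.6 * cell_radius_um` and the membrane annulus is the remainder.
#' @param intensity_noise_sd Log-scale SD of the per-cell, per-channel
#'   lognormal multiplier (0 = noise-free).
#' @param background_level Mean of the additive Gaussian background
#'   (truncated at 0, SD = 0.3 * level; 0 = no background).
#' @param seed Integer seed; every stochastic output is a deterministic
#'   function of the spec including its seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_height_px = 256, image_width_px = 256,
                       pixel_size_um = 1, phenotypes = default_phenotypes(),
                       n_cells = 200, cell_radius_um = 5,
                       intensity_noise_sd = 0.3, background_level = 0.5,
                       seed = 1L) {
  stopifnot(image_height_px >= 1, image_width_px >= 1, pixel_size_um > 0,
            n_cells >= 0, cell_radius_um > 0, intensity_noise_sd >= 0,
            background_level >= 0)
  props <- vapply(phenotypes, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop("phenotype proportions must sum to 1 (got ", sum(props), ")")
  for (ph in phenotypes)
    if (any(ph$means < 0)) stop("phenotype '", ph$name, "' has negative means")
  structure(list(image_height_px = as.integer(image_height_px),
                 image_width_px = as.integer(image_width_px),
                 pixel_size_um = pixel_size_um, phenotypes = phenotypes,
                 n_cells = as.integer(n_cells),
                 cell_radius_um = cell_radius_um,
                 intensity_noise_sd = intensity_noise_sd,
                 background_level = background_level, seed = as.integer(seed)),
            class = "scene_spec")
}

.check_phenotype_markers <- function(phenotypes, panel) {
  for (ph in phenotypes) {
    unknown <- setdiff(names(ph$means), panel$marker)
    if (length(unknown))
      stop("phenotype '", ph$name, "' names marker(s) not in panel: ",
           paste(unknown, collapse = ", "))
  }
}

# Truncated-at-zero Gaussian background for one channel grid.
.background <- function(n, level) {
  if (level <= 0) return(numeric(n))
  pmax(0, stats::rnorm(n, mean = level, sd = 0.3 * level))
}

# Dart-throwing placement with minimum center distance 2 * radius.
.place_cells <- function(n, height_um, width_um, r) {
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  lo_x <- min(r, width_um / 2); hi_x <- max(width_um - r, lo_x)
  lo_y <- min(r, height_um / 2); hi_y <- max(height_um - r, lo_y)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(50L)) {
      x <- stats::runif(1, lo_x, hi_x)
      y <- stats::runif(1, lo_y, hi_y)
      if (placed == 0L ||
          min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >= (2 * r)^2) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("could not place cell ", i, " of ", n,
           " without overlap after 50 retries (placed ", placed, ")")
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }
  list(x = xs, y = ys)
}

#' Generate a synthetic multichannel scene with ground truth
#'
#' Places non-overlapping disc-shaped cells by dart throwing (minimum center
#' distance twice the cell radius), paints DNA and nuclear markers into an
#' inner nuclear disc (radius 0.6 of the cell radius) and membrane markers
#' into the surrounding annulus, multiplies each cell's channel means by a
#' lognormal factor, and adds truncated-Gaussian background to every channel.
#' Deterministic given the spec seed.
#'
#' @param spec A [scene_spec()].
#' @param panel A `marker_panel`.
#' @return List with `image` (an `imc_image`), and `truth`: a list holding
#'   `label_grid` (integer matrix of true cell labels), `phenotype` (named
#'   character vector, cell id -> phenotype) and `centroids` (data frame
#'   `cell_id`, `x_um`, `y_um`, `phenotype`).
#' @export
make_scene <- function(spec, panel = default_panel()) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_panel(panel)
  .check_phenotype_markers(spec$phenotypes, panel)

  nr <- spec$image_height_px; nc <- spec$image_width_px
  psz <- spec$pixel_size_um
  withr::with_seed(spec$seed, {
    channels <- lapply(stats::setNames(panel$marker, panel$marker), function(m)
      matrix(.background(nr * nc, spec$background_level), nr, nc))
    labels <- matrix(0L, nr, nc)
    pheno <- character(0)
    centroids <- data.frame(cell_id = integer(0), x_um = numeric(0),
                            y_um = numeric(0), phenotype = character(0),
                            stringsAsFactors = FALSE)
    if (spec$n_cells > 0) {
      r <- spec$cell_radius_um
      pos <- .place_cells(spec$n_cells, (nr - 1) * psz, (nc - 1) * psz, r)
      props <- vapply(spec$phenotypes, `[[`, numeric(1), "proportion")
      which_ph <- sample.int(length(spec$phenotypes), spec$n_cells,
                             replace = TRUE, prob = props)
      pheno <- vapply(spec$phenotypes, `[[`, character(1), "name")[which_ph]
      names(pheno) <- as.character(seq_len(spec$n_cells))

      painted <- list(
        nuclear = panel$marker[panel$compartment %in% c("nuclear", "dna")],
        membrane = panel$marker[panel$compartment == "membrane"]
      )
      # pixel centers in um
      px_x <- (seq_len(nc) - 1) * psz
      px_y <- (seq_len(nr) - 1) * psz
      r_nuc <- 0.6 * r
      for (i in seq_len(spec$n_cells)) {
        cx <- pos$x[i]; cy <- pos$y[i]
        ci <- which(px_y >= cy - r & px_y <= cy + r)
        cj <- which(px_x >= cx - r & px_x <= cx + r)
        d2 <- outer((px_y[ci] - cy)^2, (px_x[cj] - cx)^2, `+`)
        in_cell <- d2 <= r^2
        in_nuc <- d2 <= r_nuc^2
        sub <- labels[ci, cj, drop = FALSE]
        sub[in_cell] <- i
        labels[ci, cj] <- sub
        means <- spec$phenotypes[[which_ph[i]]]$means
        mult <- if (spec$intensity_noise_sd > 0)
          exp(stats::rnorm(length(means), 0, spec$intensity_noise_sd))
        else rep(1, length(means))
        names(mult) <- names(means)
        for (m in names(means)) {
          lvl <- means[[m]] * mult[[m]]
          if (lvl <= 0) next
          where <- if (m %in% painted$nuclear) in_nuc else in_cell & !in_nuc
          if (!any(where)) next
          sub <- channels[[m]][ci, cj, drop = FALSE]
          sub[where] <- sub[where] + lvl
          channels[[m]][ci, cj] <- sub
        }
      }
      centroids <- data.frame(cell_id = seq_len(spec$n_cells), x_um = pos$x,
                              y_um = pos$y, phenotype = unname(pheno),
                              stringsAsFactors = FALSE)
    }
    list(image = imc_image(channels, pixel_size_um = psz),
         truth = list(label_grid = labels, phenotype = pheno,
                      centroids = centroids))
  })
}

#' Generate a synthetic cell table, bypassing imaging
#'
#' Draws per-cell marker totals directly from the phenotype means with
#' lognormal multiplicative noise, for one or more samples with condition
#' labels; used to exercise normalization, phenotyping, spatial and
#' differential-state stages on data with known ground truth.
#'
#' @param spec A [scene_spec()]; `n_cells`, `phenotypes`,
#'   `intensity_noise_sd`, image size and `seed` are used.
#' @param panel A `marker_panel`.
#' @param n_samples Number of samples (>= 1).
#' @param condition_map Named character vector mapping sample id to
#'   condition; default assigns all samples the condition `"control"`.
#'   Unnamed vectors of length `n_samples` are matched to samples
#'   `"S1"..."Sn"` in order.
#' @return List with `table` (cell-table data frame without ground truth) and
#'   `truth` (data frame `sample_id`, `cell_id`, `phenotype`).
#' @export
make_cell_table <- function(spec, panel = default_panel(), n_samples = 1,
                            condition_map = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_panel(panel)
  .check_phenotype_markers(spec$phenotypes, panel)
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1)
    stop("n_samples must be a positive integer")
  n_samples <- as.integer(n_samples)
  sample_ids <- paste0("S", seq_len(n_samples))
  if (is.null(condition_map)) {
    condition_map <- stats::setNames(rep("control", n_samples), sample_ids)
  } else if (is.null(names(condition_map))) {
    if (length(condition_map) != n_samples)
      stop("unnamed condition_map must have length n_samples")
    condition_map <- stats::setNames(as.character(condition_map), sample_ids)
  } else {
    sample_ids <- names(condition_map)
    if (length(sample_ids) != n_samples)
      stop("condition_map names ", length(sample_ids),
           " samples but n_samples is ", n_samples)
  }

  props <- vapply(spec$phenotypes, `[[`, numeric(1), "proportion")
  ph_names <- vapply(spec$phenotypes, `[[`, character(1), "name")
  markers <- panel$marker
  width_um <- (spec$image_width_px - 1) * spec$pixel_size_um
  height_um <- (spec$image_height_px - 1) * spec$pixel_size_um

  withr::with_seed(spec$seed, {
    rows <- vector("list", n_samples)
    truths <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      n <- spec$n_cells
      which_ph <- sample.int(length(props), n, replace = TRUE, prob = props)
      mu <- do.call(rbind, lapply(spec$phenotypes[which_ph], function(ph)
        ph$means[markers]))
      noise <- if (spec$intensity_noise_sd > 0)
        matrix(exp(stats::rnorm(n * length(markers), 0,
                                spec$intensity_noise_sd)), n)
      else matrix(1, n, length(markers))
      vals <- mu * noise
      colnames(vals) <- markers
      tab <- data.frame(cell_id = seq_len(n),
                        x_um = stats::runif(n, 0, width_um),
                        y_um = stats::runif(n, 0, height_um),
                        sample_id = sample_ids[s],
                        condition = unname(condition_map[sample_ids[s]]),
                        stringsAsFactors = FALSE, check.names = FALSE)
      tab[markers] <- as.data.frame(vals, check.names = FALSE)
      rows[[s]] <- tab
      truths[[s]] <- data.frame(sample_id = sample_ids[s],
                                cell_id = seq_len(n),
                                phenotype = ph_names[which_ph],
                                stringsAsFactors = FALSE)
    }
    list(table = do.call(rbind, rows), truth = do.call(rbind, truths))
  })
}

#' Specification for synthetic serial-section lesion series
#'
#' Defaults mirror a serial-sectioning protocol of 10 sections per sample
#' collected every 150 micrometers.
#'
#' @param n_samples Number of samples (mice).
#' @param sections_per_sample Sections collected per sample (default 10).
#' @param section_spacing_um Spacing between sections (default 150).
#' @param lesions_per_section_rate Poisson mean of the lesion count per
#'   section.
#' @param diameter_distribution List describing the lesion-diameter draw:
#'   `list(dist = "lognormal", meanlog, sdlog)` or
#'   `list(dist = "gamma", shape, rate)`; diameters in mm.
#' @param seed Integer seed.
#' @return A `lesion_series_spec` list.
#' @export
lesion_series_spec <- function(n_samples = 5, sections_per_sample = 10,
                               section_spacing_um = 150,
                               lesions_per_section_rate = 2,
                               diameter_distribution = list(
                                 dist = "lognormal", meanlog = 0.3, sdlog = 0.6),
                               seed = 1L) {
  stopifnot(n_samples >= 1, sections_per_sample >= 1, section_spacing_um > 0,
            lesions_per_section_rate >= 0)
  if (!diameter_distribution$dist %in% c("lognormal", "gamma"))
    stop("unsupported diameter distribution: ", diameter_distribution$dist)
  structure(list(n_samples = as.integer(n_samples),
                 sections_per_sample = as.integer(sections_per_sample),
                 section_spacing_um = section_spacing_um,
                 lesions_per_section_rate = lesions_per_section_rate,
                 diameter_distribution = diameter_distribution,
                 seed = as.integer(seed)),
            class = "lesion_series_spec")
}

#' Generate a synthetic serial-section lesion series
#'
#' Per sample and section, draws a Poisson number of lesions with diameters
#' from the configured distribution, and records each sample's true
#' metastatic-burden score using the same size-bin map as [score_lesion()].
#'
#' @param spec A [lesion_series_spec()].
#' @return List with `lesions` (data frame `sample_id`, `section_index`,
#'   `diameter_mm`), `sections` (one row per sample x section with its lesion
#'   count) and `sample_scores` (data frame `sample_id`, `n_lesions`,
#'   `total_score`).
#' @export
make_lesion_series <- function(spec) {
  stopifnot(inherits(spec, "lesion_series_spec"))
  dd <- spec$diameter_distribution
  draw <- switch(dd$dist,
    lognormal = function(n) stats::rlnorm(n, dd$meanlog, dd$sdlog),
    gamma = function(n) stats::rgamma(n, shape = dd$shape, rate = dd$rate))
  withr::with_seed(spec$seed, {
    sample_ids <- paste0("M", seq_len(spec$n_samples))
    sections <- expand.grid(section_index = seq_len(spec$sections_per_sample),
                            sample_id = sample_ids,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)[, 2:1]
    counts <- stats::rpois(nrow(sections), spec$lesions_per_section_rate)
    sections$n_lesions <- counts
    lesions <- data.frame(
      sample_id = rep(sections$sample_id, counts),
      section_index = rep(sections$section_index, counts),
      diameter_mm = draw(sum(counts)),
      stringsAsFactors = FALSE)
    score <- if (nrow(lesions)) score_lesion(lesions$diameter_mm) else integer(0)
    totals <- vapply(sample_ids, function(s)
      sum(score[lesions$sample_id == s]), numeric(1))
    nles <- vapply(sample_ids, function(s)
      sum(lesions$sample_id == s), numeric(1))
    list(lesions = lesions, sections = sections,
         sample_scores = data.frame(sample_id = sample_ids,
                                    n_lesions = as.integer(nles),
                                    total_score = as.integer(totals),
                                    stringsAsFactors = FALSE))
  })
}
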