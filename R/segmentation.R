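#' Gaussian smoothing of an intensity grid
#'
#' Separable Gaussian convolution with reflective boundary handling; used
#' before maxima detection and watershed flooding because raw ion-count
#' images are too noisy for pixel-level maxima to be meaningful.
#'
#' @param x Numeric matrix.
#' @param sigma Gaussian SD in pixels; `sigma <= 0` returns `x` unchanged.
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(x, sigma = 1) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_cols <- function(m) {
    n <- nrow(m)
    if (r >= n) stop("smoothing kernel larger than image")
    p <- rbind(m[r:1, , drop = FALSE], m, m[n:(n - r + 1), , drop = FALSE])
    f <- stats::filter(p, k, method = "convolution", sides = 2)
    matrix(f[(r + 1):(r + n), ], n, ncol(m))
  }
  t(conv_cols(t(conv_cols(x))))
}

#' Build a composite image from compartment channels
#'
#' Sums the selected channels pixel-wise and rescales by the maximum to
#' [0, 1]; this single-channel reduction is the grayscale conversion used for
#' thresholding and segmentation.  `"nuclear"` uses the DNA plus
#' nuclear-compartment channels, `"membrane"` the membrane channels, and
#' `"combined"` (nucleus + cell membrane) their union -- the composite used
#' for cell segmentation.
#'
#' @param image An `imc_image`.
#' @param panel A `marker_panel`.
#' @param which One of `"combined"`, `"nuclear"`, `"membrane"`.
#' @return An `imc_composite`: a numeric matrix in [0, 1] with attributes
#'   `compartment` and `pixel_size_um`.
#' @export
make_composite <- function(image, panel, which = c("combined", "nuclear", "membrane")) {
  stopifnot(inherits(image, "imc_image"))
  validate_panel(panel)
  which <- match.arg(which)
  wanted <- switch(which,
    nuclear = c("nuclear", "dna"),
    membrane = "membrane",
    combined = c("nuclear", "membrane", "dna"))
  markers <- intersect(panel_markers(panel, wanted), names(image$channels))
  if (length(markers) == 0)
    stop("no image channel belongs to compartment set '", which, "'")
  grid <- Reduce(`+`, image$channels[markers])
  mx <- max(grid)
  if (mx > 0) grid <- grid / mx
  structure(grid, class = "imc_composite", compartment = which,
            pixel_size_um = image$pixel_size_um)
}

#' Quantile threshold selection targeting an in-cell pixel fraction
#'
#' Automates the interactive grayscale thresholding step: the threshold is
#' the `(1 - target_fraction)` quantile of the composite's pixel intensities,
#' so that close to `target_fraction` of pixels are flagged as in-cell.  The
#' default of 0.475 is the midpoint of the 40--55% in-cell window typical of
#' IMC tissue images.  With heavily tied intensities the achieved fraction
#' may exceed the target.
#'
#' @param composite An `imc_composite` (any numeric matrix works).
#' @param target_fraction Desired in-cell pixel fraction, in (0, 1).
#' @return The threshold (scalar), with attributes `achieved_fraction` (the
#'   realized fraction of pixels `>=` threshold) and `target_fraction`.
#' @export
select_threshold <- function(composite, target_fraction = 0.475) {
  if (!is.numeric(target_fraction) || length(target_fraction) != 1 ||
      target_fraction <= 0 || target_fraction >= 1)
    stop("target_fraction must lie in (0, 1)")
  v <- as.vector(unclass(composite))
  if (diff(range(v)) == 0)
    stop("composite is constant; no threshold separates in-cell pixels")
  thr <- stats::quantile(v, 1 - target_fraction, names = FALSE, type = 7)
  structure(thr, achieved_fraction = mean(v >= thr),
            target_fraction = target_fraction)
}

#' In-cell pixel mask from a composite and threshold
#'
#' @param composite An `imc_composite`.
#' @param threshold Threshold as returned by [select_threshold()].
#' @return Logical matrix, `TRUE` for pixels at or above the threshold.
#' @export
in_cell_mask <- function(composite, threshold) {
  m <- unclass(composite) >= as.numeric(threshold)
  attributes(m) <- list(dim = dim(composite))
  m
}

#' Find seed maxima with prominence filtering
#'
#' Detects local maxima of the Gaussian-smoothed composite inside the
#' in-cell mask, keeping a maximum only if it exceeds its surrounding saddle
#' by at least `prominence` (the noise-tolerance semantics of interactive
#' maxima finders).  Plateau maxima collapse to a single seed at the plateau
#' pixel nearest the plateau centroid.
#'
#' @param composite An `imc_composite`.
#' @param mask Logical in-cell mask (default: the whole image).
#' @param prominence Minimum topographic prominence; default 10% of the
#'   composite's dynamic range.
#' @param sigma Gaussian smoothing SD in pixels applied before detection.
#' @return Data frame with one row per seed: `row`, `col` (1-based pixel
#'   indices), `value` (smoothed intensity at the summit) and `prominence`.
#' @export
find_maxima <- function(composite, mask = NULL, prominence = NULL, sigma = 1) {
  grid <- unclass(composite)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(grid), ncol(grid))
  storage.mode(mask) <- "logical"
  if (is.null(prominence)) prominence <- 0.1 * diff(range(grid))
  if (prominence < 0) stop("prominence must be nonnegative")
  if (!any(mask))
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0),
                      prominence = numeric(0)))
  sm <- gaussian_smooth(grid, sigma)
  res <- .find_maxima_cpp(sm, mask, prominence)
  data.frame(row = res$row, col = res$col, value = res$value,
             prominence = res$prominence)
}

#' Seeded watershed segmentation of in-cell pixels
#'
#' Floods the inverted smoothed composite from the seed pixels, restricted
#' to the in-cell mask (the "segmented particles" construction): each seed
#' grows one labeled region containing it, regions meet along one-pixel
#' watershed boundaries that are left as background, and labels are
#' renumbered consecutively from 1.  Seeds falling outside the mask are
#' dropped with a warning.
#'
#' @param composite An `imc_composite`.
#' @param seeds Data frame with `row`/`col` columns as from [find_maxima()].
#' @param mask Logical in-cell mask from [in_cell_mask()].
#' @param sigma Gaussian smoothing SD (pixels) applied before inversion; use
#'   the same value as in [find_maxima()].
#' @return An `imc_mask` of cell labels.
#' @export
segment_particles <- function(composite, seeds, mask, sigma = 1) {
  grid <- unclass(composite)
  storage.mode(mask) <- "logical"
  if (!identical(dim(grid), dim(mask)))
    stop("composite and mask dimensions differ")
  psz <- attr(composite, "pixel_size_um")
  if (is.null(psz)) psz <- 1
  if (nrow(seeds)) {
    inside <- mask[cbind(seeds$row, seeds$col)]
    if (any(!inside)) {
      warning(sum(!inside), " seed(s) outside the in-cell mask were dropped")
      seeds <- seeds[inside, , drop = FALSE]
    }
    seeds <- seeds[!duplicated(seeds[c("row", "col")]), , drop = FALSE]
  }
  if (nrow(seeds) == 0)
    return(imc_mask(matrix(0L, nrow(grid), ncol(grid)), pixel_size_um = psz))
  elev <- -gaussian_smooth(grid, sigma)
  lab <- .seeded_watershed_cpp(elev, as.matrix(seeds[c("row", "col")]), mask)
  # relabel consecutively (every seed retains at least its own pixel)
  present <- sort(unique(lab[lab > 0]))
  map <- integer(max(present))
  map[present] <- seq_along(present)
  lab[lab > 0] <- map[lab[lab > 0]]
  imc_mask(lab, pixel_size_um = psz)
}

#' One-call segmentation of a multichannel image
#'
#' Convenience wrapper chaining [make_composite()], [select_threshold()],
#' [find_maxima()] and [segment_particles()] on the combined composite.
#'
#' @param image An `imc_image`.
#' @param panel A `marker_panel`.
#' @param target_fraction In-cell pixel fraction for [select_threshold()].
#' @param prominence,sigma Passed to [find_maxima()]/[segment_particles()].
#' @return List with `mask` (an `imc_mask`), `composite`, `threshold` and
#'   `seeds`.
#' @export
segment_image <- function(image, panel, target_fraction = 0.475,
                          prominence = NULL, sigma = 1) {
  composite <- make_composite(image, panel, "combined")
  threshold <- select_threshold(composite, target_fraction)
  mask <- in_cell_mask(composite, threshold)
  seeds <- find_maxima(composite, mask, prominence = prominence, sigma = sigma)
  list(mask = segment_particles(composite, seeds, mask, sigma = sigma),
       composite = composite, threshold = threshold, seeds = seeds)
}
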