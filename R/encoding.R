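#' Preprocess a raw image into per-bin firing probabilities
#'
#' Pixel intensities in `[0, 255]` are normalised to `u = pixel/255` and
#' converted to per-time-bin spike probabilities `p_max * u`. Pixels whose
#' normalised intensity falls below the retention threshold `theta` are set
#' to zero, discarding weak intensities rather than clipping them upward:
#' only strokes strong enough to carry shape information survive. With the
#' defaults, a saturated pixel (255) maps to probability 0.63 per 10 ms bin,
#' i.e. an expected 63 Hz spike-train generator.
#'
#' @param img Square numeric matrix of integer intensities in `[0, 255]`.
#' @param theta Retention threshold on the normalised `[0, 1]` scale.
#' @param p_max Firing probability assigned to maximum intensity.
#' @return A `preprocessed_image`: list with `values` (matrix of per-bin
#'   probabilities), `theta`, and `p_max`.
#' @examples
#' p <- preprocess(matrix(255L, 28, 28))
#' p$values[1, 1] # 0.63
#' @export
preprocess <- function(img, theta = 0.4, p_max = 0.63) {
  if (!is.matrix(img) || nrow(img) != ncol(img))
    stop_structural("`img` must be a square matrix, got %s",
                    paste(dim(img), collapse = "x"))
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta > 1)
    stop("`theta` must be a single value in [0, 1]")
  if (!is.numeric(p_max) || length(p_max) != 1 || p_max <= 0 || p_max > 1)
    stop("`p_max` must be a single value in (0, 1]")
  bad <- which(!is.finite(img) | img < 0 | img > 255)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(img))
    stop(sprintf("pixel value %s at (row %d, col %d) is outside [0, 255]",
                 format(img[bad[1]]), rc[1], rc[2]), call. = FALSE)
  }
  u <- img / 255
  v <- ifelse(u < theta, 0, p_max * u)
  structure(list(values = v, theta = theta, p_max = p_max),
            class = "preprocessed_image")
}

#' Partition a square image into eight half-plane regions of strips
#'
#' The canvas is bisected four ways: horizontal midline, vertical midline,
#' main diagonal, and anti-diagonal. Each cut yields two half-plane regions
#' (labelled I--VIII), and within each half the pixels are grouped into
#' `side` strips parallel to the cutting line (rows for the horizontal cut,
#' columns for the vertical cut, constant `row - col` offsets for the main
#' diagonal, constant `row + col` offsets for the anti-diagonal), clipped to
#' the half-plane. Every region keeps exactly `side` strips even when the
#' clipped strip is empty, so a 28x28 image always maps onto 8 x 28 = 224
#' spike-train pixel-sets. Pixels lying exactly on a cutting diagonal are
#' assigned to the upper half of that cut.
#'
#' @param side Image side length (default 28).
#' @return A `region_partition`: list with `side`, `n_sets`, `sets` (list of
#'   1-based column-major linear pixel indices per pixel-set), `region`
#'   (roman label per set), `strip` (0-based strip index per set), and
#'   `set_sizes`.
#' @export
build_partition <- function(side = 28L) {
  side <- as.integer(side)
  if (is.na(side) || side < 2) stop("`side` must be an integer >= 2")
  h <- side %/% 2L
  idx <- seq_len(side * side)
  r0 <- (idx - 1L) %% side
  c0 <- (idx - 1L) %/% side

  member <- list(
    r0 < h,                   # I    horizontal cut, top half
    r0 >= h,                  # II   horizontal cut, bottom half
    c0 < h,                   # III  vertical cut, left half
    c0 >= h,                  # IV   vertical cut, right half
    r0 <= c0,                 # V    main diagonal, upper half (incl. diagonal)
    r0 > c0,                  # VI   main diagonal, lower half
    r0 + c0 <= side - 1L,     # VII  anti-diagonal, upper half (incl. diagonal)
    r0 + c0 > side - 1L       # VIII anti-diagonal, lower half
  )
  stripf <- list(r0, r0, c0, c0, c0 - r0, r0 - c0, r0 + c0, r0 + c0 - (side - 1L))

  sets <- rep(list(integer(0)), 8L * side)
  for (g in 1:8) {
    m <- member[[g]]
    sid <- (g - 1L) * side + stripf[[g]][m] + 1L
    sp <- split(idx[m], sid)
    sets[as.integer(names(sp))] <- sp
  }
  structure(list(
    side = side,
    n_sets = 8L * side,
    sets = sets,
    region = rep(roman_regions, each = side),
    strip = rep(0:(side - 1L), times = 8L),
    set_sizes = lengths(sets)
  ), class = "region_partition")
}

#' Restrict a partition to its first few regions
#'
#' Used by region-count experiments: keeps only the pixel-sets of the given
#' regions (in I--VIII order), shrinking the first neural layer to
#' `length(regions) * side` neurons.
#'
#' @param part A `region_partition`.
#' @param regions Integer region numbers in 1..8, or roman labels.
#' @return A `region_partition` with the retained sets.
#' @export
subset_partition <- function(part, regions) {
  stopifnot(inherits(part, "region_partition"))
  if (is.character(regions)) regions <- match(regions, roman_regions)
  regions <- as.integer(regions)
  if (any(is.na(regions)) || any(regions < 1) || any(regions > 8) ||
      anyDuplicated(regions))
    stop("`regions` must be distinct region numbers in 1..8")
  keep <- unlist(lapply(regions, function(g) (g - 1L) * part$side + seq_len(part$side)))
  structure(list(
    side = part$side,
    n_sets = length(keep),
    sets = part$sets[keep],
    region = part$region[keep],
    strip = part$strip[keep],
    set_sizes = part$set_sizes[keep]
  ), class = "region_partition")
}

#' Generate Bernoulli spike trains for every pixel-set generator
#'
#' Attaches one spike-train generator to every pixel occurrence in every
#' pixel-set of the partition (a pixel shared by several regions is sampled
#' independently in each) and draws, for each generator and time bin, an
#' independent Bernoulli spike with the pixel's preprocessed probability.
#'
#' @param p A `preprocessed_image`.
#' @param part A `region_partition` with matching side.
#' @param n_bins Number of simulation time bins (default 100).
#' @param dt_ms Bin width in milliseconds (default 10, so the default
#'   raster spans 1,000 ms).
#' @param seed Integer seed; the same seed reproduces the raster exactly.
#' @return A `generator_raster`: list with binary `spikes` (generators x
#'   bins), `gen_set` (pixel-set index per generator row), `gen_pixel`
#'   (linear pixel index per row), `n_sets`, `n_bins`, `dt_ms`.
#' @export
generate_raster <- function(p, part, n_bins = 100L, dt_ms = 10, seed = NULL) {
  stopifnot(inherits(p, "preprocessed_image"), inherits(part, "region_partition"))
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1) stop("`n_bins` must be >= 1")
  if (nrow(p$values) != part$side)
    stop_structural("image side %d does not match partition side %d",
                    nrow(p$values), part$side)
  gen_pixel <- unlist(part$sets)
  gen_set <- rep.int(seq_along(part$sets), part$set_sizes)
  pr <- p$values[gen_pixel]
  spikes <- with_seed(seed, {
    m <- matrix(runif(length(pr) * n_bins), length(pr), n_bins)
    (m < pr) * 1L
  })
  structure(list(spikes = spikes, gen_set = gen_set, gen_pixel = gen_pixel,
                 n_sets = part$n_sets, n_bins = n_bins, dt_ms = dt_ms,
                 seed = seed),
            class = "generator_raster")
}

#' Sum generator spikes per pixel-set into input currents
#'
#' Every pixel-set is fully connected to one first-layer neuron; its input
#' current in a bin is the number of the set's generators that spiked in
#' that bin. For the default 28x28 partition this yields a 224-row current
#' matrix, one row per first-layer neuron.
#'
#' @param raster A `generator_raster`.
#' @param part The `region_partition` the raster was generated from.
#' @return An `encoded_sample`: list with integer `currents` (pixel-sets x
#'   bins), `n_bins`, `dt_ms`, `side`, and the raster seed.
#' @export
encode_raster <- function(raster, part) {
  stopifnot(inherits(raster, "generator_raster"), inherits(part, "region_partition"))
  if (raster$n_sets != part$n_sets ||
      nrow(raster$spikes) != sum(part$set_sizes) ||
      !identical(raster$gen_set, rep.int(seq_along(part$sets), part$set_sizes)))
    stop_structural("raster rows are inconsistent with the partition (%d generators vs %d pixels in %d sets)",
                    nrow(raster$spikes), sum(part$set_sizes), part$n_sets)
  currents <- matrix(0L, part$n_sets, raster$n_bins)
  if (nrow(raster$spikes) > 0) {
    agg <- rowsum(raster$spikes, raster$gen_set)
    currents[as.integer(rownames(agg)), ] <- agg
  }
  structure(list(currents = currents, n_bins = raster$n_bins,
                 dt_ms = raster$dt_ms, side = part$side, seed = raster$seed),
            class = "encoded_sample")
}

#' Encode a raw image end to end
#'
#' Convenience pipeline: [preprocess()], [generate_raster()], then
#' [encode_raster()].
#'
#' @inheritParams preprocess
#' @inheritParams generate_raster
#' @param part A `region_partition`, or `NULL` to build one from the image.
#' @return An `encoded_sample`.
#' @export
encode_image <- function(img, part = NULL, theta = 0.4, p_max = 0.63,
                         n_bins = 100L, dt_ms = 10, seed = NULL) {
  p <- preprocess(img, theta = theta, p_max = p_max)
  if (is.null(part)) part <- build_partition(nrow(img))
  encode_raster(generate_raster(p, part, n_bins = n_bins, dt_ms = dt_ms,
                                seed = seed), part)
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> side %d: %d regions x %d strips = %d pixel-sets (%d empty)\n",
              x$side, length(unique(x$region)), x$side, x$n_sets,
              sum(x$set_sizes == 0)))
  invisible(x)
}

#' @export
print.encoded_sample <- function(x, ...) {
  cat(sprintf("<encoded_sample> %d input neurons x %d bins of %g ms (%d spikes)\n",
              nrow(x$currents), x$n_bins, x$dt_ms, sum(x$currents)))
  invisible(x)
}
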