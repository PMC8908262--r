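#' Stroke primitives for glyph specifications
#'
#' Glyphs are drawn on a normalised `[0, 1] x [0, 1]` canvas (`x` rightward,
#' `y` downward, matching the row-major, top-left-origin raster layout).
#' `stroke_line()` is a straight segment; `stroke_arc()` is a circular arc
#' with angles in degrees measured by `atan2(dy, dx)` on the y-down canvas
#' (a full circle is `0..360`).
#'
#' @param x0,y0,x1,y1 Segment endpoints in `[0, 1]`.
#' @return A stroke primitive list.
#' @export
stroke_line <- function(x0, y0, x1, y1) {
  stopifnot(all(c(x0, y0, x1, y1) >= 0), all(c(x0, y0, x1, y1) <= 1))
  list(type = "line", x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' @rdname stroke_line
#' @param cx,cy Arc centre in `[0, 1]`.
#' @param r Radius in canvas units.
#' @param a0,a1 Start and end angle in degrees, `a1 > a0` (counter-clockwise
#'   in canvas coordinates; `a1 - a0 >= 360` closes the circle).
#' @export
stroke_arc <- function(cx, cy, r, a0 = 0, a1 = 360) {
  stopifnot(cx >= 0, cx <= 1, cy >= 0, cy <= 1, r > 0, a1 > a0)
  list(type = "arc", cx = cx, cy = cy, r = r, a0 = a0, a1 = a1)
}

#' Glyph specification
#'
#' A labelled set of stroke primitives with a default stroke thickness and
#' ink intensity, realising the premise that written digits are composed of
#' lines and circle arcs.
#'
#' @param label Class label.
#' @param strokes Non-empty list of [stroke_line()] / [stroke_arc()] primitives.
#' @param thickness Default stroke thickness in pixels.
#' @param intensity Ink intensity in `[0, 255]`.
#' @return A `glyph_spec` list.
#' @export
glyph_spec <- function(label, strokes, thickness = 3, intensity = 255) {
  stopifnot(length(strokes) >= 1, thickness > 0,
            intensity >= 0, intensity <= 255)
  structure(list(label = label, strokes = strokes, thickness = thickness,
                 intensity = intensity), class = "glyph_spec")
}

#' Built-in library of ten digit-like glyphs
#'
#' Ten stroke-digit specifications labelled 0--9, each built from at most
#' four line/arc primitives. The library deliberately lets 0 and 6 share a
#' circle primitive and 3 and 8 share right-side arcs, so that the visually
#' confusable digit pairs of handwritten data have structurally similar
#' glyphs, while all ten classes remain separable.
#'
#' @return Named list of [glyph_spec()] objects ("0".."9").
#' @export
glyph_library <- function() {
  g <- list(
    "0" = glyph_spec(0L, list(stroke_arc(0.50, 0.50, 0.28))),
    "1" = glyph_spec(1L, list(stroke_line(0.52, 0.15, 0.52, 0.85))),
    "2" = glyph_spec(2L, list(stroke_arc(0.50, 0.32, 0.18, 130, 360),
                              stroke_line(0.66, 0.40, 0.30, 0.82),
                              stroke_line(0.30, 0.82, 0.74, 0.82))),
    "3" = glyph_spec(3L, list(stroke_arc(0.46, 0.33, 0.17, -100, 100),
                              stroke_arc(0.46, 0.67, 0.17, -100, 100))),
    "4" = glyph_spec(4L, list(stroke_line(0.60, 0.15, 0.28, 0.58),
                              stroke_line(0.28, 0.58, 0.78, 0.58),
                              stroke_line(0.62, 0.15, 0.62, 0.85))),
    "5" = glyph_spec(5L, list(stroke_line(0.68, 0.18, 0.32, 0.18),
                              stroke_line(0.32, 0.18, 0.32, 0.48),
                              stroke_arc(0.48, 0.64, 0.19, -90, 150))),
    "6" = glyph_spec(6L, list(stroke_arc(0.46, 0.64, 0.20),
                              stroke_line(0.63, 0.16, 0.48, 0.45))),
    "7" = glyph_spec(7L, list(stroke_line(0.25, 0.18, 0.75, 0.18),
                              stroke_line(0.75, 0.18, 0.40, 0.85))),
    "8" = glyph_spec(8L, list(stroke_arc(0.50, 0.32, 0.15),
                              stroke_arc(0.50, 0.68, 0.18))),
    "9" = glyph_spec(9L, list(stroke_arc(0.53, 0.36, 0.18),
                              stroke_line(0.71, 0.38, 0.62, 0.85)))
  )
  g
}

#' Jitter configuration for glyph rendering
#'
#' Controls the per-sample variability of rendered glyphs, emulating the
#' ways handwritten digits vary: whole-glyph translation, stroke thickness,
#' ink intensity noise, and pixel dropout. All ranges must be non-negative
#' and `dropout` lies in `[0, 1)`.
#'
#' @param translate_px Uniform translation range in pixels (+/-).
#' @param thickness_px Uniform thickness jitter in pixels (+/-).
#' @param intensity_sd Gaussian intensity noise s.d. on the 0--255 scale.
#' @param dropout Per-pixel probability of zeroing an inked pixel.
#' @return A `jitter_config` list.
#' @export
jitter_config <- function(translate_px = 1, thickness_px = 0.5,
                          intensity_sd = 15, dropout = 0.02) {
  stopifnot(translate_px >= 0, thickness_px >= 0, intensity_sd >= 0,
            dropout >= 0, dropout < 1)
  structure(list(translate_px = translate_px, thickness_px = thickness_px,
                 intensity_sd = intensity_sd, dropout = dropout),
            class = "jitter_config")
}

# Internal: distance (canvas units) from points (px, py) to one primitive.
primitive_distance <- function(px, py, s) {
  if (s$type == "line") {
    vx <- s$x1 - s$x0
    vy <- s$y1 - s$y0
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - s$x0) * vx + (py - s$y0) * vy) / len2))
    sqrt((px - (s$x0 + t * vx))^2 + (py - (s$y0 + t * vy))^2)
  } else {
    dx <- px - s$cx
    dy <- py - s$cy
    rr <- sqrt(dx * dx + dy * dy)
    span <- s$a1 - s$a0
    if (span >= 360) return(abs(rr - s$r))
    ang <- atan2(dy, dx) * 180 / pi
    rel <- (ang - s$a0) %% 360
    on_arc <- rel <= span
    d <- abs(rr - s$r)
    if (any(!on_arc)) {
      # off the angular span: distance to the nearer arc endpoint
      e0x <- s$cx + s$r * cos(s$a0 * pi / 180)
      e0y <- s$cy + s$r * sin(s$a0 * pi / 180)
      e1x <- s$cx + s$r * cos(s$a1 * pi / 180)
      e1y <- s$cy + s$r * sin(s$a1 * pi / 180)
      de <- pmin(sqrt((px - e0x)^2 + (py - e0y)^2),
                 sqrt((px - e1x)^2 + (py - e1y)^2))
      d[!on_arc] <- de[!on_arc]
    }
    d
  }
}

#' Render one glyph into a 28x28 image
#'
#' Rasterises the glyph's strokes with jittered translation and thickness,
#' a one-pixel anti-aliased edge, clipped Gaussian intensity noise on the
#' inked pixels, and pixel dropout. Deterministic under `seed`. Primitives
#' pushed outside the canvas by the translation jitter are clipped at the
#' canvas border with a warning.
#'
#' @param spec A [glyph_spec()].
#' @param jitter A [jitter_config()].
#' @param seed Integer seed.
#' @param side Image side length (default 28).
#' @return Integer matrix `side x side` with values in `[0, 255]`.
#' @export
render_glyph <- function(spec, jitter = jitter_config(), seed = 1L,
                         side = 28L) {
  stopifnot(inherits(spec, "glyph_spec"), inherits(jitter, "jitter_config"))
  with_seed(seed, {
    px_unit <- 1 / side
    dx <- runif(1, -jitter$translate_px, jitter$translate_px) * px_unit
    dy <- runif(1, -jitter$translate_px, jitter$translate_px) * px_unit
    th <- max(0.6, spec$thickness +
                runif(1, -jitter$thickness_px, jitter$thickness_px))

    shifted <- lapply(spec$strokes, function(s) {
      if (s$type == "line") {
        s$x0 <- s$x0 + dx; s$x1 <- s$x1 + dx
        s$y0 <- s$y0 + dy; s$y1 <- s$y1 + dy
        ends <- c(s$x0, s$x1, s$y0, s$y1)
      } else {
        s$cx <- s$cx + dx; s$cy <- s$cy + dy
        ends <- c(s$cx - s$r, s$cx + s$r, s$cy - s$r, s$cy + s$r)
      }
      if (any(ends < 0 | ends > 1))
        warning("jittered stroke extends beyond the canvas; clipped",
                call. = FALSE)
      s
    })

    r0 <- (seq_len(side * side) - 1L) %% side
    c0 <- (seq_len(side * side) - 1L) %/% side
    pxs <- (c0 + 0.5) * px_unit
    pys <- (r0 + 0.5) * px_unit
    d <- Reduce(pmin, lapply(shifted, function(s) primitive_distance(pxs, pys, s)))
    d_px <- d * side
    cover <- pmin(1, pmax(0, (th / 2 + 0.5 - d_px)))
    val <- spec$intensity * cover
    on <- val > 0
    if (jitter$intensity_sd > 0)
      val[on] <- val[on] + rnorm(sum(on), 0, jitter$intensity_sd)
    val <- pmin(255, pmax(0, val))
    if (jitter$dropout > 0)
      val[runif(side * side) < jitter$dropout] <- 0
    matrix(as.integer(round(val)), side, side)
  })
}

#' Generate a balanced labelled dataset of rendered glyphs
#'
#' Renders `n_per_class` jittered samples of every glyph, with per-sample
#' seeds split from the root seed, so the whole dataset is reproducible
#' bit for bit from `(specs, jitter, seed)`.
#'
#' @param specs List of [glyph_spec()] objects with distinct labels
#'   (e.g. [glyph_library()] or a subset).
#' @param n_per_class Samples per class, >= 1.
#' @param jitter A [jitter_config()].
#' @param seed Integer root seed.
#' @param side Image side length.
#' @return A `labeled_dataset`: list with `images` (list of matrices),
#'   `labels` (vector), and `provenance`.
#' @export
make_dataset <- function(specs, n_per_class = 10L, jitter = jitter_config(),
                         seed = 1L, side = 28L) {
  if (inherits(specs, "glyph_spec")) specs <- list(specs)
  stopifnot(n_per_class >= 1, length(specs) >= 1)
  labs <- lapply(specs, function(s) s$label)
  if (anyDuplicated(labs)) stop("duplicate class labels in `specs`")
  images <- vector("list", length(specs) * n_per_class)
  labels <- rep(unlist(labs), each = n_per_class)
  i <- 0L
  for (k in seq_along(specs)) {
    for (s in seq_len(n_per_class)) {
      i <- i + 1L
      images[[i]] <- render_glyph(specs[[k]], jitter,
                                  seed = split_seed(seed, (k - 1L) * n_per_class + s),
                                  side = side)
    }
  }
  structure(list(images = images, labels = labels,
                 provenance = list(seed = seed, jitter = jitter,
                                   classes = unlist(labs),
                                   n_per_class = n_per_class)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<labeled_dataset> %d images, %d classes (%s)\n",
              length(x$images), length(tab),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
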