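# Shared fixtures, built in code at load time.

part28 <- build_partition(28)

# Blank image with selected pixels set (1-based row/col, 0-255 intensity).
img_with <- function(coords, value = 255L, side = 28L) {
  m <- matrix(0L, side, side)
  for (rc in coords) m[rc[1], rc[2]] <- as.integer(value)
  m
}

# Three well-separated single-stroke classes: parallel horizontal bars at
# distinct heights, so their aligned row strips are disjoint.
bar_specs <- function() {
  list(
    glyph_spec(0L, list(stroke_line(0.22, 0.26, 0.78, 0.26))),
    glyph_spec(1L, list(stroke_line(0.22, 0.52, 0.78, 0.52))),
    glyph_spec(2L, list(stroke_line(0.22, 0.78, 0.78, 0.78)))
  )
}

# Small network/encoding pair for fast structural tests.
tiny_configs <- function(n_bins = 20L) {
  enc <- encoding_config(n_bins = n_bins)
  net <- network_config()
  list(enc = enc, net = net)
}
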