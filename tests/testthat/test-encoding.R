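test_that("preprocessing maps intensities to thresholded firing probabilities", {
  img <- matrix(0L, 28, 28)
  img[1, 1] <- 255L   # saturated -> p_max
  img[2, 3] <- 51L    # u = 0.2 < theta -> zeroed
  img[5, 7] <- 204L   # u = 0.8 -> p_max * 0.8
  p <- preprocess(img)
  expect_equal(p$values[1, 1], 0.63)
  expect_equal(p$values[2, 3], 0)
  expect_equal(p$values[5, 7], 0.63 * 0.8)
  expect_equal(p$values[10, 10], 0)
  # every retained value is either 0 or at least theta * p_max, never above p_max
  expect_true(all(p$values == 0 | p$values >= 0.4 * 0.63))
  expect_true(all(p$values <= 0.63))
})

test_that("out-of-range pixels are rejected with their coordinate", {
  img <- matrix(0L, 28, 28)
  img[17, 4] <- 300L
  expect_error(preprocess(img), "row 17, col 4")
  expect_error(preprocess(matrix(0L, 28, 27)), "square")
  expect_error(preprocess(matrix(0L, 28, 28), theta = 1.5), "theta")
})

test_that("the eight-region partition has the documented structure", {
  expect_equal(part28$n_sets, 224L)
  expect_equal(length(part28$sets), 224L)
  expect_true(all(table(part28$region) == 28))  # 28 strips per region

  # each half contains the expected pixel counts
  half_sizes <- as.vector(tapply(part28$set_sizes, rep(1:8, each = 28), sum))
  expect_equal(half_sizes[1:4], c(392, 392, 392, 392))
  expect_equal(half_sizes[5:8], c(406, 378, 406, 378))

  # within a region, strips are disjoint and cover the half-plane
  for (g in 1:8) {
    px <- unlist(part28$sets[(g - 1) * 28 + 1:28])
    expect_equal(anyDuplicated(px), 0L)
    expect_true(all(px >= 1 & px <= 784))
  }
  # all eight halves together cover each pixel exactly four times
  expect_equal(sum(part28$set_sizes), 4L * 784L)
  expect_error(build_partition(1), "side")
})

test_that("subsetting a partition keeps region order and sizes", {
  sub <- subset_partition(part28, 1:3)
  expect_equal(sub$n_sets, 84L)
  expect_identical(sub$sets, part28$sets[1:84])
  expect_error(subset_partition(part28, c(1, 1)), "distinct")
})

test_that("raster generation respects the probability map and the seed", {
  img0 <- matrix(0L, 28, 28)
  r0 <- generate_raster(preprocess(img0), part28, seed = 1)
  expect_true(all(r0$spikes == 0))

  # p = 1 everywhere: deterministic all-ones raster
  imgF <- matrix(255L, 28, 28)
  rF <- generate_raster(preprocess(imgF, theta = 0, p_max = 1), part28,
                        n_bins = 5, seed = 99)
  expect_true(all(rF$spikes == 1))

  p <- preprocess(img_with(list(c(14, 14))))
  r1 <- generate_raster(p, part28, seed = 42)
  r2 <- generate_raster(p, part28, seed = 42)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- generate_raster(p, part28, seed = 43)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("a generator's expected spike count is bins times probability", {
  p <- preprocess(img_with(list(c(14, 14))))
  # the bright pixel appears in 4 regions -> 4 independent generators
  counts <- vapply(1:250, function(s) {
    r <- generate_raster(p, part28, n_bins = 100, seed = s)
    sum(r$spikes[p$values[r$gen_pixel] > 0, ])
  }, numeric(1))
  n_gen <- 4 * 250
  mean_per_gen <- sum(counts) / n_gen
  se <- sqrt(100 * 0.63 * 0.37 / n_gen)
  expect_lt(abs(mean_per_gen - 63), 3 * se)
})

test_that("encoding sums generator spikes per pixel-set and conserves them", {
  img <- img_with(list(c(3, 5), c(3, 6), c(20, 20), c(14, 2)), 255)
  p <- preprocess(img)
  r <- generate_raster(p, part28, n_bins = 30, seed = 7)
  enc <- encode_raster(r, part28)
  expect_equal(dim(enc$currents), c(224L, 30L))

  # brute-force oracle: loop over each pixel-set's generator rows
  for (i in c(1, 3, 31, 60, 113, 150, 224)) {
    rows <- which(r$gen_set == i)
    manual <- if (length(rows)) colSums(r$spikes[rows, , drop = FALSE]) else rep(0, 30)
    expect_equal(unname(enc$currents[i, ]), unname(manual))
  }
  expect_equal(sum(enc$currents), sum(r$spikes))              # conservation
  expect_true(all(enc$currents <= part28$set_sizes))          # bounded by set size
  # empty clipped strips carry zero current in every bin
  empty <- which(part28$set_sizes == 0)
  expect_gt(length(empty), 0)
  expect_true(all(enc$currents[empty, ] == 0))
})

test_that("raster/partition mismatches are structural errors", {
  p <- preprocess(matrix(0L, 28, 28))
  r <- generate_raster(p, part28, n_bins = 5, seed = 1)
  expect_error(encode_raster(r, subset_partition(part28, 1:2)), "inconsistent")
})

test_that("expected per-set current is invariant to permuting intensities within a set", {
  # the expected current of a set is the sum of its pixels' probabilities,
  # which is exchangeable under any within-set permutation
  set_id <- 10L
  px <- part28$sets[[set_id]]
  vals <- as.integer(seq(110, 250, length.out = length(px)))
  img1 <- matrix(0L, 28, 28); img1[px] <- vals
  img2 <- matrix(0L, 28, 28); img2[px] <- with_seed(3, sample(vals))
  p1 <- preprocess(img1); p2 <- preprocess(img2)
  expect_equal(sum(p1$values[px]), sum(p2$values[px]))
  # and empirically the mean currents agree to Monte-Carlo precision
  m1 <- mean(vapply(1:60, function(s)
    mean(encode_raster(generate_raster(p1, part28, 20, seed = s), part28)$currents[set_id, ]),
    numeric(1)))
  m2 <- mean(vapply(1:60, function(s)
    mean(encode_raster(generate_raster(p2, part28, 20, seed = s + 500), part28)$currents[set_id, ]),
    numeric(1)))
  expect_lt(abs(m1 - m2), 0.5)
})

test_that("the full encoding pipeline is deterministic under a seed", {
  img <- render_glyph(glyph_library()[["5"]], seed = 8)
  e1 <- encode_image(img, part28, seed = 123)
  e2 <- encode_image(img, part28, seed = 123)
  expect_identical(e1$currents, e2$currents)
})
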