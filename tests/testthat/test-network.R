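test_that("network construction follows the configured architecture", {
  cfg <- network_config(connectivity_rate = 1)
  net <- build_network(cfg, seed = 1)
  expect_equal(dim(net$W1), c(224L, 150L))
  expect_equal(dim(net$M2), c(150L, 50L))
  expect_true(all(net$M2 == 1))                    # full connectivity
  expect_true(all(net$W1 >= 0 & net$W1 <= 1))
  expect_true(all(net$W3 == 1))

  net2 <- build_network(cfg, seed = 1)
  expect_identical(net$W1, net2$W1)                # determinism
  expect_identical(net$M2, net2$M2)

  exact <- build_network(network_config(connectivity_rate = 0.2,
                                        degree = "exact"), seed = 3)
  expect_true(all(rowSums(exact$M2) == 10))
})

test_that("mean out-degree matches the connectivity rate", {
  cfg <- network_config(connectivity_rate = 0.2)
  ones <- vapply(1:40, function(s) mean(rowSums(build_network(cfg, s)$M2)),
                 numeric(1))
  n_edges <- 40 * 150 * 50
  se <- sqrt(0.2 * 0.8 / n_edges) * 50
  expect_lt(abs(mean(ones) - 10), 3 * se)
})

test_that("forward passes propagate silence and obey the causal chain", {
  cfgs <- tiny_configs()
  net <- build_network(cfgs$net, seed = 5)
  zero <- encode_image(matrix(0L, 28, 28), part28, n_bins = 20, seed = 1)
  fw <- forward_pass(zero, net, seed = 2)
  expect_equal(fw$output_rate, 0)
  expect_true(all(fw$rates1 == 0))

  # an all-zero weight matrix silences everything downstream
  img <- render_glyph(bar_specs()[[1]], seed = 3)
  enc <- encode_image(img, part28, n_bins = 20, seed = 4)
  net0 <- net
  net0$W1[] <- 0
  fw0 <- forward_pass(net = net0, sample = enc, seed = 6)
  expect_true(any(fw0$rates1 > 0))
  expect_true(all(fw0$rates2 == 0))
  expect_equal(fw0$output_rate, 0)
  expect_error(forward_pass(zero, build_network(network_config(n1 = 10))),
               "input rows")
})

test_that("forward rates match the scalar reference simulator", {
  cfg <- network_config(n1 = 224, n2 = 8, n3 = 4, connectivity_rate = 0.5,
                        inhibition = FALSE)
  net <- build_network(cfg, seed = 11)
  img <- render_glyph(bar_specs()[[2]], seed = 2)
  enc <- encode_image(img, part28, n_bins = 15, seed = 3)
  fw <- forward_pass(enc, net)

  p <- cfg$if_params
  step_ref <- function(v, I) {
    v2 <- v + (p$dt / p$tau) * ((p$E_L - v) + I)
    if (v2 > p$V_th) list(v = p$V_reset, s = 1L) else list(v = v2, s = 0L)
  }
  sim_ref <- function(cur, vth = p$V_th) {
    n <- nrow(cur); nb <- ncol(cur)
    sp <- matrix(0L, n, nb)
    for (i in 1:n) {
      v <- p$V_0
      for (t in 1:nb) {
        v2 <- v + (p$dt / p$tau) * ((p$E_L - v) + cur[i, t])
        if (v2 > vth) { sp[i, t] <- 1L; v <- p$V_reset } else v <- v2
      }
    }
    sp
  }
  s1 <- sim_ref(enc$currents)
  s2 <- sim_ref(t(net$W1) %*% s1)
  s3 <- sim_ref(t(net$M2) %*% s2)
  so <- sim_ref(t(net$W3) %*% s3, vth = cfg$output_V_th)
  expect_equal(fw$rates1, rowMeans(s1))
  expect_equal(fw$rates2, rowMeans(s2))
  expect_equal(fw$rates3, rowMeans(s3))
  expect_equal(fw$output_rate, mean(so))
})

test_that("output rate is monotone in a first-layer weight", {
  cfg <- network_config(n1 = 224, n2 = 2, n3 = 1, connectivity_rate = 1,
                        inhibition = FALSE)
  net <- build_network(cfg, seed = 21)
  net$W1[] <- 0
  img <- render_glyph(bar_specs()[[1]], seed = 9)
  enc <- encode_image(img, part28, n_bins = 30, seed = 10)
  active_row <- which.max(rowSums(enc$currents > 0))
  rates <- vapply(c(0, 0.02, 0.06, 0.5), function(w) {
    net$W1[active_row, 1] <- w
    forward_pass(enc, net)$output_rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[4], rates[1])
})

test_that("activity distance is the RMS difference with similarity 1 - d", {
  a <- rep(1, 224)
  b <- rep(0, 224)
  d <- activity_distance(a, b)
  expect_equal(d$distance, 1)
  expect_equal(d$similarity, 0)
  expect_equal(d$euclidean, sqrt(224))
  same <- activity_distance(a, a)
  expect_equal(same$distance, 0)
  expect_equal(same$similarity, 1)
  expect_error(activity_distance(a, b[-1]), "length")
  expect_error(activity_distance(a * 2, b), "\\[0, 1\\]")
})

test_that("channel similarity is symmetric with unit diagonal", {
  W1 <- matrix(0, 10, 10); W1[1:3, ] <- 0.9
  W2 <- matrix(0, 10, 10); W2[8:10, ] <- 0.9
  S <- channel_similarity(list(a = W1, b = W2, c = W1))
  expect_equal(diag(S), c(a = 1, b = 1, c = 1))
  expect_equal(S, t(S))
  expect_equal(S["a", "c"], 1)            # identical channels
  expect_lt(S["a", "b"], 1)               # disjoint supports
})

test_that("classification argmaxes the per-class output rates with tie flags", {
  specs <- bar_specs()
  train <- make_dataset(specs, n_per_class = 4, seed = 31)
  ens <- train_ensemble(train, seed = 33)

  res <- classify_sample(train$images[[1]], ens, seed = 2)
  expect_true(res$predicted %in% ens$classes)
  expect_equal(unname(res$rates[as.character(res$predicted)]), max(res$rates))

  # an all-zero image drives no network: tie broken toward the lowest class
  res0 <- classify_sample(matrix(0L, 28, 28), ens, seed = 2)
  expect_true(res0$tie)
  expect_equal(res0$predicted, 0L)
  expect_true(all(res0$rates == 0))

  # unfrozen ensembles are rejected
  broken <- ens
  broken$channels[[1]]$frozen <- FALSE
  expect_error(classify_sample(train$images[[1]], broken, seed = 2), "unfrozen")
})

test_that("classification is invariant to reordering the stored networks", {
  specs <- bar_specs()
  train <- make_dataset(specs, n_per_class = 3, seed = 41)
  ens <- train_ensemble(train, seed = 43)
  perm <- c(2, 3, 1)
  ens2 <- ens
  ens2$classes <- ens$classes[perm]
  ens2$channels <- ens$channels[perm]
  ens2$networks <- ens$networks[perm]
  img <- train$images[[4]]
  r1 <- classify_sample(img, ens, seed = 5)
  r2 <- classify_sample(img, ens2, seed = 5)
  expect_equal(sort(names(r1$rates)), sort(names(r2$rates)))
  expect_equal(r2$rates[names(r1$rates)], r1$rates)
  expect_equal(r1$predicted, r2$predicted)
})

test_that("evaluation books correct counts and leaves the ensemble frozen", {
  specs <- bar_specs()
  train <- make_dataset(specs, n_per_class = 4, seed = 51)
  test <- make_dataset(specs, n_per_class = 3, seed = 52)
  ens <- train_ensemble(train, seed = 53)
  before <- serialize(ens, NULL)
  ev <- evaluate_ensemble(test, ens, seed = 54)
  expect_identical(serialize(ens, NULL), before)   # frozen contract

  expect_equal(unname(rowSums(ev$confusion)), rep(3L, 3))  # row sums = counts
  expect_equal(sum(ev$confusion), 9L)
  expect_true(all(ev$per_class_accuracy >= 0 & ev$per_class_accuracy <= 1))
  expect_equal(ev$accuracy, mean(ev$per_class_accuracy))
  expect_equal(ev$micro_accuracy, sum(diag(ev$confusion)) / 9)
  expect_error(evaluate_ensemble(list(images = list(), labels = integer(0)),
                                 ens), "empty")
})
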