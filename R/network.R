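#' Encoding configuration
#'
#' Bundles the rate-coding parameters and the region partition used to turn
#' images into first-layer input currents.
#'
#' @param side Image side length (default 28).
#' @param theta Retention threshold on the normalised intensity scale.
#' @param p_max Per-bin firing probability of a saturated pixel.
#' @param n_bins Simulation length in bins (default 100).
#' @param dt_ms Bin width in milliseconds (default 10).
#' @param partition Optional pre-built (possibly subset) `region_partition`;
#'   defaults to the full eight-region partition of the given side.
#' @return An `encoding_config` list; its `n1` element is the implied number
#'   of first-layer neurons.
#' @export
encoding_config <- function(side = 28L, theta = 0.4, p_max = 0.63,
                            n_bins = 100L, dt_ms = 10, partition = NULL) {
  if (is.null(partition)) partition <- build_partition(side)
  stopifnot(inherits(partition, "region_partition"))
  structure(list(side = partition$side, theta = theta, p_max = p_max,
                 n_bins = as.integer(n_bins), dt_ms = dt_ms,
                 partition = partition, n1 = partition$n_sets),
            class = "encoding_config")
}

#' Network architecture configuration
#'
#' The converging 224/150/50/1 architecture: `n1` first-layer neurons (one
#' per pixel-set), `n2` second-layer neurons fully connected to the first
#' layer with trainable weights, `n3` third-layer neurons reached through a
#' fixed binary mask with unit weights, and one output neuron fully
#' connected to the third layer with unit weights.
#'
#' @param n1,n2,n3 Layer sizes (defaults 224, 150, 50).
#' @param connectivity_rate Expected fraction of third-layer targets per
#'   second-layer neuron, in `(0, 1]` (default 0.2, the reported optimum).
#' @param if_params Shared [if_params()] for the three layers.
#' @param output_V_th Firing threshold of the output neuron (default 0.01;
#'   sweepable from -0.03 to 0.03).
#' @param phi Feedback-inhibition parameter for the first layer (default
#'   0.1, the reported optimum; smaller values inhibit more strongly).
#' @param inhibition Logical; whether the first layer's feedback inhibition
#'   is applied in the readout forward pass (default `TRUE`). Inhibition
#'   keeps the converging output pathway out of saturation so that output
#'   firing rates stay graded and comparable across the ensemble; training
#'   always runs the first layer uninhibited (see [train_class_network()]).
#' @param degree `"bernoulli"` samples each second-to-third-layer edge
#'   independently; `"exact"` gives every second-layer neuron exactly
#'   `round(connectivity_rate * n3)` targets.
#' @return A `network_config` list.
#' @export
network_config <- function(n1 = 224L, n2 = 150L, n3 = 50L,
                           connectivity_rate = 0.2,
                           if_params = spikeprune::if_params(),
                           output_V_th = 0.01, phi = 0.1, inhibition = TRUE,
                           degree = c("bernoulli", "exact")) {
  stopifnot(n1 >= 1, n2 >= 1, n3 >= 1,
            is.numeric(connectivity_rate), length(connectivity_rate) == 1,
            connectivity_rate > 0, connectivity_rate <= 1,
            inherits(if_params, "if_params"),
            is.numeric(output_V_th), length(output_V_th) == 1,
            is.numeric(phi), length(phi) == 1, phi >= 0,
            is.logical(inhibition), length(inhibition) == 1)
  degree <- match.arg(degree)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), n3 = as.integer(n3),
                 connectivity_rate = connectivity_rate, if_params = if_params,
                 output_V_th = output_V_th, phi = phi, inhibition = inhibition,
                 degree = degree),
            class = "network_config")
}

#' Build an untrained network
#'
#' Draws the trainable first-to-second-layer weights i.i.d. from `U(0, 1)`,
#' samples the second-to-third-layer binary connectivity mask at the
#' configured rate, and fixes the third-to-output weights at 1.
#' Deterministic under `seed`.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed.
#' @return An `snn_network`: list with `W1` (`n1 x n2`), `M2` (`n2 x n3`
#'   binary), `W3` (`n3 x 1` of ones), `config`, `seed`, `trained = FALSE`.
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  with_seed(seed, {
    W1 <- matrix(runif(cfg$n1 * cfg$n2), cfg$n1, cfg$n2)
    M2 <- if (cfg$degree == "bernoulli") {
      matrix(rbinom(cfg$n2 * cfg$n3, 1L, cfg$connectivity_rate), cfg$n2, cfg$n3)
    } else {
      k <- max(1L, round(cfg$connectivity_rate * cfg$n3))
      m <- matrix(0L, cfg$n2, cfg$n3)
      for (i in seq_len(cfg$n2)) m[i, sample.int(cfg$n3, k)] <- 1L
      m
    }
    structure(list(W1 = W1, M2 = M2, W3 = matrix(1, cfg$n3, 1),
                   config = cfg, seed = seed, trained = FALSE),
              class = "snn_network")
  })
}

#' Forward pass of one sample through one network
#'
#' Drives the first layer with the sample's input currents (with feedback
#' inhibition if configured), the second layer through the `W1` weights, the
#' third layer through the binary mask, and the output neuron through the
#' unit weights; the output neuron uses the configured `output_V_th` in
#' place of the shared layer threshold. Weights are never modified.
#'
#' @param sample An `encoded_sample` with `n1` rows.
#' @param net An `snn_network` (trained or not).
#' @param seed Optional seed for the inhibition draws.
#' @return A `forward_result`: list with `rates1`, `rates2`, `rates3`
#'   (mean spikes per bin per neuron) and scalar `output_rate`.
#' @export
forward_pass <- function(sample, net, seed = NULL) {
  stopifnot(inherits(sample, "encoded_sample"), inherits(net, "snn_network"))
  cfg <- net$config
  if (nrow(sample$currents) != cfg$n1)
    stop_structural("sample has %d input rows but the network expects %d",
                    nrow(sample$currents), cfg$n1)
  params <- cfg$if_params
  out_params <- params
  out_params$V_th <- cfg$output_V_th
  phi_eff <- if (isTRUE(cfg$inhibition)) cfg$phi else NULL
  l1 <- simulate_layer(sample$currents, params, phi = phi_eff, seed = seed)
  l2 <- simulate_layer(crossprod(net$W1, l1$spikes), params)
  l3 <- simulate_layer(crossprod(net$M2, l2$spikes), params)
  out <- simulate_layer(crossprod(net$W3, l3$spikes), out_params)
  structure(list(rates1 = l1$rates, rates2 = l2$rates, rates3 = l3$rates,
                 output_rate = out$rates[1]),
            class = "forward_result")
}

#' Train the per-class network ensemble
#'
#' Trains one network per class on that class's training images (see
#' [train_class_network()]) and freezes the resulting information channels
#' into an ensemble used for maximum-firing-rate classification.
#'
#' @param data A `labeled_dataset` (or list with `images` and `labels`).
#' @param net_cfg A [network_config()] shared by all class networks.
#' @param plast_cfg A [plasticity_config()].
#' @param enc_cfg An [encoding_config()].
#' @param epochs Presentations of each class's sample list.
#' @param seed Integer root seed; per-class seeds are split from it.
#' @return An `snn_ensemble`: list with `classes`, `channels`, `networks`
#'   (trained copies whose `W1` is the pruned channel), the three configs,
#'   and `seed`.
#' @export
train_ensemble <- function(data, net_cfg = network_config(),
                           plast_cfg = plasticity_config(),
                           enc_cfg = encoding_config(), epochs = 1L,
                           seed = 1L) {
  images <- data$images
  labels <- data$labels
  stopifnot(length(images) == length(labels), length(images) > 0)
  if (net_cfg$n1 != enc_cfg$n1)
    stop_structural("network n1 = %d does not match encoder n1 = %d",
                    net_cfg$n1, enc_cfg$n1)
  classes <- sort(unique(labels))
  channels <- vector("list", length(classes))
  networks <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    cls <- classes[k]
    net <- build_network(net_cfg, seed = split_seed(seed, 500 + k))
    ch <- train_class_network(images[labels == cls], net, plast_cfg,
                              epochs = epochs,
                              seed = split_seed(seed, 900 + k),
                              digit_class = cls, encoding = enc_cfg)
    net$W1 <- ch$W
    net$trained <- TRUE
    channels[[k]] <- ch
    networks[[k]] <- net
  }
  names(channels) <- names(networks) <- as.character(classes)
  structure(list(classes = classes, channels = channels, networks = networks,
                 net_config = net_cfg, plast_config = plast_cfg,
                 enc_config = enc_cfg, epochs = as.integer(epochs),
                 seed = seed),
            class = "snn_ensemble")
}

#' Classify one image with the trained ensemble
#'
#' Encodes the image once (one shared spike raster for all networks), runs
#' it through every class's trained network with a per-class seed for the
#' network-side noise, and predicts the class whose output neuron fires
#' fastest. Exact ties are broken toward the lowest class and flagged.
#'
#' @param img A raw image matrix or an `encoded_sample`.
#' @param ens A trained `snn_ensemble`.
#' @param seed Integer seed covering the encoding and all network draws.
#' @return A `classification_result`: list with `predicted`, `rates` (named
#'   per-class output rates, spikes per bin), and logical `tie`.
#' @export
classify_sample <- function(img, ens, seed = 1L) {
  stopifnot(inherits(ens, "snn_ensemble"))
  if (!all(vapply(ens$channels, function(ch) isTRUE(ch$frozen), logical(1))))
    stop("ensemble contains unfrozen channels; train it before classifying")
  enc <- if (inherits(img, "encoded_sample")) img else
    encode_image(img, part = ens$enc_config$partition,
                 theta = ens$enc_config$theta, p_max = ens$enc_config$p_max,
                 n_bins = ens$enc_config$n_bins, dt_ms = ens$enc_config$dt_ms,
                 seed = split_seed(seed, 1))
  # per-network seeds keyed to the class's rank, not its storage position,
  # so classification is invariant to reordering the stored networks
  ranks <- match(ens$classes, sort(ens$classes))
  rates <- vapply(seq_along(ens$classes), function(k) {
    forward_pass(enc, ens$networks[[k]],
                 seed = split_seed(seed, 7000 + ranks[k]))$output_rate
  }, numeric(1))
  names(rates) <- as.character(ens$classes)
  best <- which.max(rates)
  structure(list(predicted = ens$classes[best], rates = rates,
                 tie = sum(rates == rates[best]) > 1),
            class = "classification_result")
}

#' Evaluate the ensemble on a labelled test set
#'
#' Classifies every test image and reports the per-class accuracy (correct
#' assignments over that class's test count), the confusion matrix (true
#' classes in rows), the overall accuracy as the unweighted mean of the
#' per-class accuracies (a micro-average over samples is also reported), and
#' the number of argmax ties. Spike generation stays stochastic at test
#' time; `replicates > 1` averages each image's per-class output rates over
#' that many independent encodings before the argmax.
#'
#' @param data A `labeled_dataset` (or list with `images` and `labels`).
#' @param ens A trained `snn_ensemble`.
#' @param seed Integer root seed.
#' @param replicates Encoding replicates per test image (default 1).
#' @return An `snn_evaluation`: list with `per_class_accuracy`, `accuracy`
#'   (macro), `micro_accuracy`, `confusion`, `ties`, `n`, `predicted`.
#' @export
evaluate_ensemble <- function(data, ens, seed = 1L, replicates = 1L) {
  images <- data$images
  labels <- data$labels
  stopifnot(inherits(ens, "snn_ensemble"), length(images) == length(labels))
  if (!length(images)) stop("empty test set")
  if (!all(labels %in% ens$classes))
    stop("test labels outside the ensemble's classes")
  K <- length(ens$classes)
  preds <- vector(mode = typeof(ens$classes), length = length(images))
  ties <- 0L
  for (i in seq_along(images)) {
    rates <- rep(0, K)
    for (r in seq_len(replicates)) {
      res <- classify_sample(images[[i]], ens,
                             seed = split_seed(seed, i * 131L + r))
      rates <- rates + res$rates / replicates
    }
    best <- which.max(rates)
    if (sum(rates == rates[best]) > 1) ties <- ties + 1L
    preds[i] <- ens$classes[best]
  }
  cls <- as.character(ens$classes)
  confusion <- table(factor(labels, levels = ens$classes),
                     factor(preds, levels = ens$classes), dnn = c("true", "predicted"))
  per_class <- diag(confusion) / pmax(1L, rowSums(confusion))
  names(per_class) <- cls
  present <- rowSums(confusion) > 0
  structure(list(per_class_accuracy = per_class,
                 accuracy = mean(per_class[present]),
                 micro_accuracy = mean(preds == labels),
                 confusion = confusion, ties = ties, n = length(images),
                 predicted = preds),
            class = "snn_evaluation")
}

#' Distance and similarity between two activity patterns
#'
#' Activity patterns (e.g. first-layer mean rates) are vectors with values
#' in `[0, 1]`. The distance is the root-mean-square element-wise
#' difference, which stays in `[0, 1]` regardless of vector length, and the
#' similarity is `S = 1 - d`. The unnormalised Euclidean distance is also
#' returned for plots on the raw scale.
#'
#' @param a,b Numeric vectors of equal length with values in `[0, 1]`.
#' @return List with `distance` (RMS), `similarity`, and `euclidean`.
#' @export
activity_distance <- function(a, b) {
  if (length(a) != length(b))
    stop_structural("activity vectors differ in length (%d vs %d)",
                    length(a), length(b))
  if (any(a < 0 | a > 1) || any(b < 0 | b > 1))
    stop("activity values must lie in [0, 1]")
  d <- sqrt(mean((a - b)^2))
  list(distance = d, similarity = 1 - d, euclidean = sqrt(sum((a - b)^2)))
}

#' Pairwise similarity of the ensemble's information channels
#'
#' Flattens each trained channel's weight matrix and computes the pairwise
#' similarity `1 - RMS distance` between every pair. Identical channels have
#' similarity 1; class-specific channels should show clearly lower
#' off-diagonal values.
#'
#' @param x An `snn_ensemble`, or a list of `information_channel`s or
#'   weight matrices.
#' @return A symmetric K x K similarity matrix with unit diagonal.
#' @export
channel_similarity <- function(x) {
  ws <- if (inherits(x, "snn_ensemble")) {
    lapply(x$channels, function(ch) ch$W)
  } else {
    lapply(x, function(el) if (inherits(el, "information_channel")) el$W else el)
  }
  K <- length(ws)
  S <- diag(1, K)
  for (i in seq_len(K)) for (j in seq_len(K)) if (i < j) {
    S[i, j] <- S[j, i] <- 1 - sqrt(mean((ws[[i]] - ws[[j]])^2))
  }
  dimnames(S) <- list(names(ws), names(ws))
  S
}

#' First-layer mean rates of one image
#'
#' Encodes the image and simulates only the (optionally inhibited) first
#' layer, returning each first-layer neuron's mean spikes per bin. This is
#' the activity pattern used by the distance analyses.
#'
#' @param img Raw image matrix or `encoded_sample`.
#' @param enc_cfg An [encoding_config()].
#' @param net_cfg A [network_config()] supplying the neuron parameters and
#'   inhibition setting.
#' @param seed Integer seed.
#' @return Numeric vector of length `n1` with values in `[0, 1]`.
#' @export
layer1_rates <- function(img, enc_cfg = encoding_config(),
                         net_cfg = network_config(), seed = 1L) {
  enc <- if (inherits(img, "encoded_sample")) img else
    encode_image(img, part = enc_cfg$partition, theta = enc_cfg$theta,
                 p_max = enc_cfg$p_max, n_bins = enc_cfg$n_bins,
                 dt_ms = enc_cfg$dt_ms, seed = split_seed(seed, 1))
  phi_eff <- if (isTRUE(net_cfg$inhibition)) net_cfg$phi else NULL
  simulate_layer(enc$currents, net_cfg$if_params, phi = phi_eff,
                 seed = split_seed(seed, 2))$rates
}

#' @export
print.snn_ensemble <- function(x, ...) {
  cat(sprintf("<snn_ensemble> %d classes (%s), %d/%d/%d/1 architecture\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$net_config$n1, x$net_config$n2, x$net_config$n3))
  nz <- vapply(x$channels, function(ch) mean(ch$W > 0), numeric(1))
  cat(sprintf("  surviving synapses per channel: %s%%\n",
              paste(sprintf("%.1f", 100 * nz), collapse = ", ")))
  invisible(x)
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> predicted %s%s | rates: %s\n",
              format(x$predicted), if (x$tie) " (tie)" else "",
              paste(sprintf("%s=%.3f", names(x$rates), x$rates), collapse = " ")))
  invisible(x)
}

#' @export
print.snn_evaluation <- function(x, ...) {
  cat(sprintf("<snn_evaluation> n = %d: accuracy %.3f (macro), %.3f (micro), %d ties\n",
              x$n, x$accuracy, x$micro_accuracy, x$ties))
  print(x$confusion)
  invisible(x)
}
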