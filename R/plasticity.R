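#' Plasticity and pruning configuration
#'
#' Parameters of the firing-rate-difference learning rule and of synaptic
#' pruning. `alpha` scales potentiation (presynaptic rate above postsynaptic),
#' `beta` scales depression (the reverse); `mu` is the pruning threshold below
#' which trained weights are zeroed. Updates are applied at the end of each
#' time window in `window_ends_ms`; the default schedule splits a 1,000 ms
#' presentation into four 250 ms windows. Weights are clipped to
#' `[w_min, w_max]` after every update so that the pruning threshold keeps a
#' fixed meaning on the weight scale.
#'
#' @param alpha Potentiation gain in `[0, 1]` (default 0.2).
#' @param beta Depression gain, >= 0 (default 0.6; values up to 2 are
#'   meaningful in sweeps).
#' @param mu Pruning threshold in `[0, 1]` (default 0.8).
#' @param window_ends_ms Strictly increasing window end times (ms).
#' @param w_min,w_max Weight clipping bounds, `w_min < w_max`.
#' @return A `plasticity_config` list.
#' @export
plasticity_config <- function(alpha = 0.2, beta = 0.6, mu = 0.8,
                              window_ends_ms = c(250, 500, 750, 1000),
                              w_min = 0, w_max = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1,
            is.numeric(beta), length(beta) == 1, beta >= 0,
            is.numeric(mu), length(mu) == 1, mu >= 0, mu <= 1,
            is.numeric(window_ends_ms), length(window_ends_ms) >= 1,
            is.numeric(w_min), is.numeric(w_max), w_min < w_max)
  if (any(diff(window_ends_ms) <= 0) || any(window_ends_ms <= 0))
    stop("`window_ends_ms` must be positive and strictly increasing")
  structure(list(alpha = alpha, beta = beta, mu = mu,
                 window_ends_ms = window_ends_ms,
                 w_min = w_min, w_max = w_max),
            class = "plasticity_config")
}

#' Difference of pre- and postsynaptic mean firing rates
#'
#' The learning signal for one synapse: `Delta = f_pre - f_post`, with both
#' rates measured as mean spikes per bin over the just-finished window.
#'
#' @param f_pre Mean rate(s) of first-layer neurons over the window, in `[0, 1]`.
#' @param f_post Mean rate(s) of second-layer neurons, in `[0, 1]`.
#' @return Signed rate difference(s).
#' @export
rate_delta <- function(f_pre, f_post) {
  if (any(f_pre < 0 | f_pre > 1) || any(f_post < 0 | f_post > 1))
    stop("rates must lie in [0, 1]")
  f_pre - f_post
}

# Numerically safe evaluation of the rule's gain curve
# g(d) = (1 - exp(-d)) / (1 + exp(-d)), an odd sigmoid equal to tanh(d/2).
rate_gain <- function(d) {
  out <- d
  pos <- !is.na(d) & d >= 0
  e <- exp(-d[pos])
  out[pos] <- (1 - e) / (1 + e)
  e <- exp(d[!pos])
  out[!pos] <- -(1 - e) / (1 + e)
  out
}

#' Weight increment of the firing-rate-difference learning rule
#'
#' Maps a rate difference `Delta` to a bounded weight change through the odd
#' sigmoid `g(Delta) = (1 - e^(-Delta)) / (1 + e^(-Delta))`. When the
#' presynaptic neuron out-fires the postsynaptic one (`Delta > 0`) the
#' synapse is strengthened by `alpha * g(Delta)`; in the opposite case it is
#' weakened by `beta * g(Delta)` (negative); `Delta = 0` leaves the weight
#' untouched. Since `|g| < 1`, every increment is bounded by `max(alpha, beta)`.
#'
#' @param delta Signed rate difference(s) from [rate_delta()].
#' @param cfg A [plasticity_config()].
#' @return Weight increment(s), same shape as `delta`.
#' @export
weight_update <- function(delta, cfg = plasticity_config()) {
  stopifnot(inherits(cfg, "plasticity_config"))
  gain <- ifelse(delta > 0, cfg$alpha, cfg$beta)
  dw <- gain * rate_gain(delta)
  dim(dw) <- dim(delta)
  dw
}

#' Apply one window's weight update to a full weight matrix
#'
#' Updates every first-to-second-layer synapse from the two layers' mean
#' rates over the just-finished window and clips the result to the
#' configured bounds.
#'
#' @param W Weight matrix, first-layer neurons x second-layer neurons.
#' @param f_pre Vector of first-layer window rates (length `nrow(W)`).
#' @param f_post Vector of second-layer window rates (length `ncol(W)`).
#' @param cfg A [plasticity_config()].
#' @return Updated, clipped weight matrix.
#' @export
apply_window_update <- function(W, f_pre, f_post, cfg = plasticity_config()) {
  if (length(f_pre) != nrow(W) || length(f_post) != ncol(W))
    stop_structural("rate vectors (%d, %d) do not match weight matrix %dx%d",
                    length(f_pre), length(f_post), nrow(W), ncol(W))
  delta <- outer(as.numeric(f_pre), as.numeric(f_post), rate_delta)
  pmin(pmax(W + weight_update(delta, cfg), cfg$w_min), cfg$w_max)
}

#' Prune weak synapses
#'
#' Synaptic pruning: weights below the threshold `mu` are set to zero;
#' weights at or above it are kept unchanged. Idempotent.
#'
#' @param W Weight matrix (or vector).
#' @param mu Pruning threshold in `[0, 1]`.
#' @return Pruned weights, same shape.
#' @export
prune_weights <- function(W, mu) {
  stopifnot(is.numeric(mu), length(mu) == 1, mu >= 0, mu <= 1)
  W[W < mu] <- 0
  W
}

#' Train one class's network into an information channel
#'
#' Presents the class's training samples to the network `epochs` times. For
#' each presentation the simulation time is divided by the configured window
#' schedule; each window is simulated with the current weights (membrane
#' state carried across windows, re-initialised to `V_0` at the start of
#' every presentation), the two layers' window rates are taken, and the
#' weight matrix is updated before the next window. After all presentations
#' the weights are pruned once at threshold `mu`, yielding the sparse
#' "information channel" for that class.
#'
#' Training always simulates the first layer at full drive, without the
#' feedback inhibition used at readout: the learning signal is the rate
#' difference between the layers, and suppressing first-layer spikes while
#' the second layer still fires biases that difference negative for every
#' synapse, uniformly depressing the matrix instead of selecting features
#' (see the methods vignette).
#'
#' Raw images are re-encoded into fresh spike trains on every presentation
#' (seeded from the root seed), mirroring the stochastic rate code; already
#' `encoded_sample` objects are presented with their fixed raster.
#'
#' @param samples List of raw 28x28 image matrices or `encoded_sample`
#'   objects (a single matrix is accepted).
#' @param net A [build_network()] network whose `W1` is the starting matrix.
#' @param cfg A [plasticity_config()].
#' @param epochs Number of full presentations of the sample list.
#' @param seed Integer root seed for encoding and inhibition draws.
#' @param digit_class Label stored on the channel.
#' @param encoding An [encoding_config()] used to encode raw images.
#' @return An `information_channel`: list with the pruned `W`, `digit_class`,
#'   `config`, `net_config`, `n_samples`, `epochs`, `seed`, `frozen = TRUE`.
#' @export
train_class_network <- function(samples, net, cfg = plasticity_config(),
                                epochs = 1L, seed = 1L, digit_class = NA,
                                encoding = encoding_config()) {
  if (is.matrix(samples) || inherits(samples, "encoded_sample"))
    samples <- list(samples)
  if (!length(samples)) stop("`samples` must contain at least one sample")
  stopifnot(inherits(net, "snn_network"), inherits(cfg, "plasticity_config"),
            epochs >= 1)
  params <- net$config$if_params
  n_bins <- encoding$n_bins
  wb <- cfg$window_ends_ms / encoding$dt_ms
  if (any(abs(wb - round(wb)) > 1e-9))
    stop("`window_ends_ms` must be multiples of the bin width")
  wb <- as.integer(round(wb))

  W <- net$W1
  n1 <- nrow(W)
  n2 <- ncol(W)
  pres <- 0L
  for (e in seq_len(epochs)) {
    for (s in seq_along(samples)) {
      pres <- pres + 1L
      smp <- samples[[s]]
      enc <- if (inherits(smp, "encoded_sample")) smp else
        encode_image(smp, part = encoding$partition, theta = encoding$theta,
                     p_max = encoding$p_max,
                     n_bins = max(wb), dt_ms = encoding$dt_ms,
                     seed = split_seed(seed, pres))
      if (nrow(enc$currents) != n1)
        stop_structural("sample has %d input neurons but W1 has %d rows",
                        nrow(enc$currents), n1)
      if (max(wb) > enc$n_bins)
        stop("window schedule extends beyond the encoded sample")
      V1 <- rep(params$V_0, n1)
      V2 <- rep(params$V_0, n2)
      prev <- 0L
      for (w in seq_along(wb)) {
        cols <- (prev + 1L):wb[w]
        prev <- wb[w]
        l1 <- simulate_layer(enc$currents[, cols, drop = FALSE], params,
                             V0 = V1)
        V1 <- l1$V
        l2 <- simulate_layer(crossprod(W, l1$spikes), params, V0 = V2)
        V2 <- l2$V
        W <- apply_window_update(W, l1$rates, l2$rates, cfg)
      }
    }
  }
  W <- prune_weights(W, cfg$mu)
  structure(list(W = W, digit_class = digit_class, config = cfg,
                 net_config = net$config, n_samples = length(samples),
                 epochs = as.integer(epochs), seed = seed, frozen = TRUE),
            class = "information_channel")
}

#' @export
print.information_channel <- function(x, ...) {
  nz <- sum(x$W > 0)
  cat(sprintf("<information_channel> class %s: %dx%d weights, %d (%.1f%%) surviving synapses (mu = %g)\n",
              format(x$digit_class), nrow(x$W), ncol(x$W), nz,
              100 * nz / length(x$W), x$config$mu))
  invisible(x)
}
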