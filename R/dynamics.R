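#' Integrate-and-fire neuron parameters
#'
#' Electrophysiological constants of the discrete-time integrate-and-fire
#' neuron. The defaults are honeybee olfactory-system values (volts and
#' seconds): membrane time constant `tau = 0.01 s`, resting potential
#' `E_L = -0.065 V`, reset `V_reset = -0.065 V`, threshold `V_th = -0.01 V`,
#' initial voltage `V_0 = -0.03 V`, Euler step `dt = 0.01 s`. Note `dt = tau`
#' by default, which makes the update memoryless: the voltage after one step
#' is `E_L + I`, so a neuron fires in a bin exactly when its summed drive
#' exceeds `V_th - E_L` (0.055 with the defaults).
#'
#' `V_reset <= V_th` is deliberately not required: output-neuron threshold
#' sweeps go up to +0.03, above the reset value.
#'
#' @param tau Membrane time constant (s), > 0.
#' @param E_L Resting potential (V).
#' @param V_reset Reset voltage after a spike (V).
#' @param V_th Firing threshold (V); strict inequality, ties do not fire.
#' @param V_0 Initial membrane voltage at the start of a presentation (V).
#' @param dt Euler integration step (s), > 0.
#' @return An `if_params` list.
#' @export
if_params <- function(tau = 0.01, E_L = -0.065, V_reset = -0.065,
                      V_th = -0.01, V_0 = -0.03, dt = 0.01) {
  stopifnot(is.numeric(tau), tau > 0, is.numeric(dt), dt > 0)
  structure(list(tau = tau, E_L = E_L, V_reset = V_reset, V_th = V_th,
                 V_0 = V_0, dt = dt), class = "if_params")
}

#' One Euler step of the integrate-and-fire dynamics
#'
#' Updates a vector of membrane voltages by
#' `V' = V + (dt/tau) * ((E_L - V) + I)` and applies the spike rule: where
#' `V' > V_th` the neuron spikes and its voltage is reset to `V_reset`.
#'
#' @param V Numeric vector of membrane voltages.
#' @param I Summed weighted input drive per neuron (unitless, added to the
#'   leak term exactly as written in the model; recycled if scalar).
#' @param params An [if_params()] object.
#' @return List with `V` (post-step voltages) and `spiked` (logical).
#' @export
if_step <- function(V, I, params = if_params()) {
  stopifnot(inherits(params, "if_params"))
  if (any(!is.finite(I))) stop("non-finite input current", call. = FALSE)
  V1 <- V + (params$dt / params$tau) * ((params$E_L - V) + I)
  sp <- V1 > params$V_th
  V1[sp] <- params$V_reset
  list(V = V1, spiked = sp)
}

#' Feedback inhibition of a layer's spikes
#'
#' The first layer's inhibitory neuron suppresses each spike in the current
#' bin independently with probability `P = exp(-phi * C)`, where `C` is the
#' layer's mean activity (fraction of neurons spiking this bin, in `[0, 1]`)
#' and `phi >= 0` is the inhibition parameter. Smaller `phi` means stronger
#' inhibition (`phi = 0` deletes every spike; as `phi -> Inf`, `P -> 0` and
#' activity passes through untouched). Zeros are never altered.
#'
#' @param spikes Binary (0/1 or logical) vector of spikes in one bin.
#' @param phi Inhibition parameter, >= 0.
#' @param C Mean activity of the layer this bin, in `[0, 1]`.
#' @param seed Optional seed for the suppression draws.
#' @return Vector of the same type with some spikes deleted.
#' @export
apply_inhibition <- function(spikes, phi, C, seed = NULL) {
  stopifnot(is.numeric(phi), length(phi) == 1, phi >= 0,
            is.numeric(C), length(C) == 1, C >= 0, C <= 1)
  P <- exp(-phi * C)
  on <- spikes > 0
  u <- with_seed(seed, runif(length(spikes)))
  spikes[on & u < P] <- if (is.logical(spikes)) FALSE else 0L
  spikes
}

#' Simulate one layer of integrate-and-fire neurons over all time bins
#'
#' Runs the Euler update bin by bin for a whole layer, given each neuron's
#' per-bin input drive. When `phi` is supplied the layer is treated as the
#' inhibited first layer: in every bin the spikes are computed from the
#' threshold rule, the mean activity `C` of those spikes is taken, and each
#' spike is then deleted with probability `exp(-phi * C)` before being
#' recorded (the membrane still resets on the original spike; inhibition
#' suppresses transmission, not the reset).
#'
#' @param currents Numeric matrix, neurons x bins, of input drive.
#' @param params An [if_params()] object.
#' @param phi Inhibition parameter, or `NULL` for no inhibition.
#' @param V0 Optional vector of starting voltages (defaults to `params$V_0`),
#'   used to carry membrane state across consecutive simulation windows.
#' @param seed Optional seed for the inhibition draws.
#' @return List with integer `spikes` (neurons x bins), `rates` (mean spikes
#'   per bin per neuron, in `[0, 1]`; multiply by `1000/dt_ms` for Hz), and
#'   `V` (final voltages).
#' @export
simulate_layer <- function(currents, params = if_params(), phi = NULL,
                           V0 = NULL, seed = NULL) {
  currents <- as.matrix(currents)
  n <- nrow(currents)
  nb <- ncol(currents)
  if (!is.null(V0) && length(V0) != n)
    stop_structural("`V0` has length %d but the layer has %d neurons",
                    length(V0), n)
  V <- if (is.null(V0)) rep(params$V_0, n) else V0
  spikes <- matrix(0L, n, nb)
  with_seed(seed, {
    for (t in seq_len(nb)) {
      st <- if_step(V, currents[, t], params)
      V <- st$V
      s <- st$spiked
      if (!is.null(phi) && any(s)) {
        C <- mean(s)
        s[s & (runif(n) < exp(-phi * C))] <- FALSE
      }
      spikes[, t] <- s
    }
  })
  list(spikes = spikes, rates = rowMeans(spikes), V = V)
}
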