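#' Canonical Izhikevich coefficients for a cell class
#'
#' Regular-spiking (RS) cells model excitatory neurons, fast-spiking (FS) cells
#' model inhibitory neurons; the spike threshold is 30 mV in both cases.
#'
#' @param type `"regular_spiking"` or `"fast_spiking"`.
#' @return A named list with elements `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' izhikevich_params("regular_spiking")
izhikevich_params <- function(type = c("regular_spiking", "fast_spiking")) {
  type <- match.arg(type)
  switch(type,
    regular_spiking = list(a = 0.02, b = 0.2, c = -65, d = 8),
    fast_spiking    = list(a = 0.1,  b = 0.2, c = -65, d = 2)
  )
}

# Vector core of the neuron update; shared by izhikevich_step() and the
# reference R engine. `substeps = 2` is the published half-step scheme for the
# membrane potential (two 0.5 ms updates per 1 ms), `substeps = 1` plain Euler.
# The recovery variable is updated once per ms from the post-substep voltage.
.izh_advance <- function(v, u, I, a, b, c, d, substeps = 2L) {
  h <- 1 / substeps
  for (s in seq_len(substeps)) {
    # once a sub-step crosses threshold the spike is certain; further
    # sub-steps would square an already super-threshold voltage
    idx <- v < 30
    v[idx] <- v[idx] + h * (0.04 * v[idx] * v[idx] + 5 * v[idx] + 140 -
                              u[idx] + I[idx])
    # hyperpolarization floor: without it an extreme inhibitory volley can
    # push v so far negative that the quadratic term catapults it upward
    v[idx][v[idx] < -90] <- -90
  }
  # the model caps spikes at +30 mV: the recovery update must not see the
  # integrator's overshoot above threshold
  u <- u + a * (b * pmin(v, 30) - u)
  if (any(!is.finite(v)) || any(!is.finite(u))) {
    abort("numerical blow-up: non-finite membrane state after update")
  }
  fired <- v >= 30
  v[fired] <- c[fired]
  u[fired] <- u[fired] + d[fired]
  list(v = v, u = u, fired = fired)
}

#' Advance a neuron population by one millisecond
#'
#' One Euler step of the Izhikevich model `v' = 0.04 v^2 + 5 v + 140 - u + I`,
#' `u' = a (b v - u)`, with spike-and-reset at 30 mV (`v <- c`, `u <- u + d`).
#' The threshold test is evaluated after the sub-step updates; all neurons
#' crossing it in the same step are recorded as simultaneous spikes.
#'
#' @param neurons A tibble with columns `v`, `u`, `a`, `b`, `c`, `d`
#'   (as built by [lsa_network()]).
#' @param I Per-neuron total input (mV), recycled if scalar.
#' @param integrator `"half_step"` (two 0.5 ms voltage sub-steps, the default)
#'   or `"euler"` (one full step).
#' @return The `neurons` tibble with updated `v`, `u` and a logical column
#'   `fired` flagging this step's spikes.
#' @export
#' @examples
#' net <- lsa_network(n_neurons = 3, frac_inhibitory = 0, topology = "chain3", seed = 1)
#' izhikevich_step(net$neurons, I = 10)
izhikevich_step <- function(neurons, I = 0,
                            integrator = c("half_step", "euler")) {
  integrator <- match.arg(integrator)
  I <- rep_len(I, nrow(neurons))
  st <- .izh_advance(neurons$v, neurons$u, I,
                     neurons$a, neurons$b, neurons$c, neurons$d,
                     substeps = if (integrator == "half_step") 2L else 1L)
  neurons$v <- st$v
  neurons$u <- st$u
  neurons$fired <- st$fired
  neurons
}

#' Define an external stimulation channel
#'
#' While active, every target neuron receives `amplitude` mV added to its
#' external input at every 1 ms step (a 1000 Hz stimulation).
#'
#' @param targets Integer indices of the stimulated neurons.
#' @param amplitude Stimulation amplitude in mV.
#' @param active Logical on/off state.
#' @return An object of class `lsa_stimulus`.
#' @export
#' @examples
#' stimulus_channel(1:10, amplitude = 1)
stimulus_channel <- function(targets, amplitude = 1, active = TRUE) {
  structure(
    list(targets = as.integer(targets), amplitude = amplitude,
         active = isTRUE(active), frequency_hz = 1000),
    class = "lsa_stimulus"
  )
}

#' Sum synaptic, external and noise input for every neuron
#'
#' Implements the per-step input decomposition `I = I_synaptic + e + m`:
#' the synaptic term sums the (effective) weights of the neurons that fired at
#' the previous step, the external term sums the active stimulation channels,
#' and the noise term is freshly sampled zero-mean Gaussian noise.
#'
#' @param weights Effective weight matrix, `weights[pre, post]` (use
#'   [effective_weights()] when short-term plasticity is enabled).
#' @param spikes_prev Logical vector (or integer indices) of neurons that fired
#'   at the immediately preceding step.
#' @param stimuli A single [stimulus_channel()] or a list of them.
#' @param sigma Noise standard deviation in mV (0 disables sampling).
#' @return A tibble with columns `neuron`, `I_synaptic`, `e_external`,
#'   `m_noise`, `I_total`.
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- 5; w[1, 3] <- 2
#' gather_inputs(w, spikes_prev = c(TRUE, FALSE, FALSE))
gather_inputs <- function(weights, spikes_prev, stimuli = list(), sigma = 0) {
  n <- nrow(weights)
  if (is.logical(spikes_prev)) {
    stopifnot(length(spikes_prev) == n)
    fired <- which(spikes_prev)
  } else {
    fired <- as.integer(spikes_prev)
  }
  I_syn <- numeric(n)
  for (j in fired) I_syn <- I_syn + weights[j, ]
  if (inherits(stimuli, "lsa_stimulus")) stimuli <- list(stimuli)
  e_ext <- numeric(n)
  for (ch in stimuli) {
    if (any(ch$targets < 1L | ch$targets > n)) {
      abort("stimulus channel targets a neuron index outside the population")
    }
    if (ch$active) e_ext[ch$targets] <- e_ext[ch$targets] + ch$amplitude
  }
  m <- if (sigma > 0) sigma * rnorm(n) else numeric(n)
  tibble(
    neuron = seq_len(n),
    I_synaptic = unname(I_syn),
    e_external = e_ext,
    m_noise = m,
    I_total = unname(I_syn) + e_ext + m
  )
}
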