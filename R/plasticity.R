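#' Additive STDP weight change for a pre/post spike-time difference
#'
#' For a synapse from neuron a to neuron b and relative spike timing
#' `s = t_b - t_a` (ms), the weight change is `A exp(-s / tau)` when the
#' presynaptic neuron fired first (`s > 0`), `-A exp(s / tau)` when the
#' postsynaptic neuron fired first (`s < 0`), and 0 for exactly simultaneous
#' spikes (neither branch of the discontinuity at `s = 0` is privileged).
#'
#' @param s Relative spike timing `t_post - t_pre` in ms (vectorised).
#' @param A Amplitude of the curve (default 0.1).
#' @param tau Time constant in ms (default 20).
#' @return Weight changes, same length as `s`.
#' @export
#' @examples
#' stdp_delta(c(-20, 0, 1))
stdp_delta <- function(s, A = 0.1, tau = 20) {
  ifelse(s == 0, 0, sign(s) * A * exp(-abs(s) / tau))
}

#' Apply nearest-spike STDP for one step's spikes
#'
#' Pairing is nearest-spike: each new spike pairs once with the most recent
#' recorded spike of every counterpart excitatory neuron, provided the interval
#' does not exceed `cutoff` ms (beyond 5 tau the change is negligible). Both
#' directed synapses of a pair are updated: the connection from the earlier to
#' the later spiker is potentiated, the reverse connection depressed. Updated
#' weights are clipped to `[0, w_max]`. Only connections flagged in `plastic`
#' (excitatory-to-excitatory, existing, non-self) are touched.
#'
#' @param weights Weight matrix `weights[pre, post]`.
#' @param last_spike Per-neuron time of most recent spike (ms), `NA` if none,
#'   current through `t - 1`.
#' @param spikes_now Logical vector of spikes at time `t`.
#' @param t Current time (ms).
#' @param n_exc Number of excitatory neurons (indices `1:n_exc`).
#' @param plastic Logical matrix of plastic connections; defaults to all
#'   excitatory-to-excitatory non-self pairs.
#' @param A,tau STDP parameters, see [stdp_delta()].
#' @param cutoff Pairing window in ms (default 100 = 5 tau).
#' @param w_max Weight cap.
#' @return The updated weight matrix.
#' @export
apply_stdp <- function(weights, last_spike, spikes_now, t, n_exc,
                       plastic = NULL, A = 0.1, tau = 20, cutoff = 100,
                       w_max = 10) {
  n <- nrow(weights)
  if (is.null(plastic)) {
    plastic <- matrix(FALSE, n, n)
    plastic[seq_len(n_exc), seq_len(n_exc)] <- TRUE
    diag(plastic) <- FALSE
  }
  fired <- which(spikes_now[seq_len(n_exc)])
  for (i in fired) {
    js <- setdiff(seq_len(n_exc), i)
    js <- js[!spikes_now[js]]            # simultaneous spikes: dw = 0
    s <- t - last_spike[js]
    ok <- !is.na(s) & s >= 1 & s <= cutoff
    js <- js[ok]
    if (!length(js)) next
    dw <- A * exp(-s[ok] / tau)
    up <- plastic[cbind(js, i)]           # j fired first: potentiate j -> i
    weights[cbind(js, i)][up] <- pmin(
      pmax(weights[cbind(js, i)][up] + dw[up], 0), w_max)
    dn <- plastic[cbind(i, js)]           # i fired second: depress i -> j
    weights[cbind(i, js)][dn] <- pmin(
      pmax(weights[cbind(i, js)][dn] - dw[dn], 0), w_max)
  }
  weights
}

#' Multiplicative weight decay
#'
#' Every weight is scaled by `1 - mu` once per iteration, counteracting the
#' unbounded growth that additive STDP would otherwise produce in large
#' networks. Used in the 100-neuron experiments (`mu = 5e-7`), disabled in the
#' 3-neuron experiments.
#'
#' @param weights Weight matrix (or vector).
#' @param mu Decay rate in `[0, 1)`.
#' @return The decayed weights.
#' @export
#' @examples
#' apply_decay(10, 5e-7)
apply_decay <- function(weights, mu) {
  stopifnot(mu >= 0, mu < 1)
  (1 - mu) * weights
}

#' Initial short-term plasticity state
#'
#' @param n Number of neurons.
#' @param U Initial release probability (default 0.2).
#' @return A list with depression variable `x` (all 1) and facilitation
#'   variable `u` (all `U`).
#' @export
stp_init <- function(n, U = 0.2) {
  list(x = rep(1, n), u = rep(U, n))
}

#' Advance short-term plasticity variables by one millisecond
#'
#' Euler step of the two-variable depression/facilitation model
#' `dx/dt = (1 - x)/tau_d - u x f` and `du/dt = (U - u)/tau_f + U (1 - u) f`,
#' where `f` is the spike indicator. Both derivatives are evaluated at the
#' state from the start of the step. At rest (`f = 0`) the fixed point is
#' `x = 1`, `u = U`; frequent firing depletes `x` faster than `u` facilitates,
#' so sustained high-frequency firing is attenuated.
#'
#' @param stp A list with vectors `x` and `u` (see [stp_init()]).
#' @param spikes Logical (or 0/1) spike indicator per neuron at this step.
#' @param dt Step size, fixed at 1 ms.
#' @param U Release probability (default 0.2).
#' @param tau_d Depression time constant in ms (default 200).
#' @param tau_f Facilitation time constant in ms (default 600).
#' @return The updated list.
#' @export
#' @examples
#' stp_step(stp_init(1), spikes = TRUE)
stp_step <- function(stp, spikes, dt = 1, U = 0.2, tau_d = 200, tau_f = 600) {
  stopifnot(dt == 1)
  f <- as.numeric(spikes)
  x <- stp$x
  u <- stp$u
  stp$x <- x + (1 - x) / tau_d - u * x * f
  stp$u <- u + (U - u) / tau_f + U * (1 - u) * f
  if (any(stp$x <= 0 | stp$x > 1 + 1e-9) || any(stp$u < 0 | stp$u > 1 + 1e-9)) {
    abort("STP state left (0, 1]: integrator instability")
  }
  stp
}

#' Effective weights under short-term plasticity
#'
#' Short-term plasticity modulates the output weights of excitatory neurons
#' (onto both excitatory and inhibitory targets) as `w* = u x w`; inhibitory
#' output weights are returned unchanged. With `stp = NULL` this is the
#' identity.
#'
#' @param weights Weight matrix `weights[pre, post]`.
#' @param n_exc Number of excitatory neurons (rows `1:n_exc` are modulated).
#' @param stp A list with `x` and `u` vectors, or `NULL` when STP is disabled.
#' @return The effective weight matrix.
#' @export
#' @examples
#' effective_weights(matrix(10, 1, 1), n_exc = 1, stp = list(x = 1, u = 0.2))
effective_weights <- function(weights, n_exc, stp = NULL) {
  if (is.null(stp)) return(weights)
  fac <- (stp$u * stp$x)[seq_len(n_exc)]
  weights[seq_len(n_exc), ] <- weights[seq_len(n_exc), , drop = FALSE] * fac
  weights
}
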