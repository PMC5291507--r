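# Shared fixtures: tiny deterministic networks and independent oracles.

# Deterministic 3-neuron network (all excitatory, chain3 topology) with
# hand-set weights; sigma = 0 configs drive it without randomness.
fixture_chain3 <- function(w = matrix(0, 3, 3), w_max = 10,
                           zones = list(input = 1L, output_a = 3L)) {
  net <- lsa_network(topology = "chain3", w_max = w_max, seed = 1)
  stopifnot(all(dim(w) == c(3, 3)))
  diag(w) <- 0
  net$weights <- w
  assign_zones(net, sizes = setNames(lengths(zones), names(zones)),
               fixed_indices = zones)
}

# Fine-step reference integration of a single Izhikevich neuron under constant
# drive: plain Euler at dt_fine, same threshold/reset; returns spike count.
oracle_spike_count <- function(I, dur_ms = 1000, dt = 0.01,
                               p = list(a = 0.02, b = 0.2, c = -65, d = 8)) {
  v <- -65
  u <- p$b * v
  n <- 0L
  steps <- round(dur_ms / dt)
  for (k in seq_len(steps)) {
    v <- v + dt * (0.04 * v * v + 5 * v + 140 - u + I)
    u <- u + dt * p$a * (p$b * v - u)
    if (v >= 30) {
      n <- n + 1L
      v <- p$c
      u <- u + p$d
    }
  }
  n
}

# Coarse 1 ms spike count using the package step on a one-neuron population.
package_spike_count <- function(I, dur_ms = 1000,
                                type = "regular_spiking") {
  p <- izhikevich_params(type)
  neurons <- tibble::tibble(a = p$a, b = p$b, c = p$c, d = p$d,
                            v = -65, u = p$b * -65)
  n <- 0L
  for (k in seq_len(dur_ms)) {
    neurons <- izhikevich_step(neurons, I = I)
    n <- n + sum(neurons$fired)
  }
  n
}

# Independent suffix-scan for the learning criterion: earliest trial index k
# such that every reaction time from k on is below the threshold.
oracle_learning_index <- function(rt, timed_out, threshold = 4000) {
  n <- length(rt)
  rt[timed_out] <- Inf
  for (k in seq_len(n)) {
    if (all(rt[k:n] < threshold)) return(k)
  }
  NA_integer_
}

# Brute-force ray marching to the arena boundary (independent geometry
# oracle for the ray-cast sensor model).
oracle_ray_march <- function(x, y, theta, side = 1000, step = 0.01) {
  d <- 0
  repeat {
    d <- d + step
    px <- x + d * cos(theta)
    py <- y + d * sin(theta)
    if (px < 0 || px > side || py < 0 || py > side) return(d)
  }
}
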