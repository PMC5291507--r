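# Build a network + zones from a config (shared by both engines).
.build_from_config <- function(config, seed) {
  net <- lsa_network(
    n_neurons = config$n_neurons, frac_inhibitory = config$frac_inhibitory,
    topology = config$topology,
    connections_per_neuron = config$connections_per_neuron,
    weight_init = config$weight_init, weight_init_max = config$weight_init_max,
    weight_mean = config$weight_mean, weight_variance = config$weight_variance,
    w_max = config$w_max, seed = seed_for(seed, "topology")
  )
  if (config$topology == "chain3") {
    # minimal circuit: neuron 1 is the input, neuron 3 the output, neuron 2
    # the hidden neuron in between
    if (isTRUE(config$chain3_fixed_weights)) {
      w <- matrix(config$chain3_w_other, 3, 3)
      diag(w) <- 0
      w[1, 3] <- config$chain3_w_direct
      net$weights <- w
    }
    fixed <- lapply(config$zone_sizes, function(...) integer(0))
    for (nm in names(config$zone_sizes)) {
      fixed[[nm]] <- if (startsWith(nm, "input")) 1L else 3L
    }
    return(assign_zones(net, sizes = config$zone_sizes,
                        forbid_direct_io = config$forbid_direct_io,
                        fixed_indices = fixed))
  }
  assign_zones(net, sizes = config$zone_sizes,
               seed = seed_for(seed, "zones"),
               forbid_direct_io = config$forbid_direct_io)
}

.zone0 <- function(zones, name) {
  z <- zones[[name]]
  if (is.null(z)) integer(0) else as.integer(z) - 1L
}

.punish_targets0 <- function(network, config) {
  if (!config$stimulus_enabled) return(integer(0))
  if (config$punish_scope == "input_zone") {
    return(.zone0(network$zones, "input"))
  }
  zb <- network$zones$output_b %||% integer(0)
  setdiff(seq_len(network$n_exc), zb) - 1L
}

.dyn_list <- function(config) {
  list(
    sigma = config$sigma_noise_mv,
    stdp_A = config$stdp_A, stdp_tau = config$stdp_tau_ms,
    stdp_cutoff_ms = as.integer(config$stdp_cutoff_ms),
    w_max = config$w_max, decay_mu = config$decay_mu,
    decay_scope = config$decay_scope,
    substeps = if (config$integrator == "half_step") 2L else 1L,
    stdp_enabled = isTRUE(config$stdp_enabled),
    stp_enabled = isTRUE(config$stp_enabled),
    stp_U = config$stp_U, stp_tau_d = config$stp_tau_d_ms,
    stp_tau_f = config$stp_tau_f_ms
  )
}

.proto_list <- function(network, config, duration_ms) {
  list(
    stim_enabled = isTRUE(config$stim_enabled),
    input_zone = .zone0(network$zones, "input"),
    stim_amplitude = config$stim_amplitude_mv,
    zone_a = .zone0(network$zones, "output_a"),
    zone_b = .zone0(network$zones, "output_b"),
    stop_thr_a = as.integer(config$stop_thr_a),
    stop_thr_b = if (is.na(config$stop_thr_b)) -1L
                 else as.integer(config$stop_thr_b),
    timeout_ms = as.integer(config$timeout_ms),
    delay_min_ms = as.integer(config$delay_min_ms),
    delay_max_ms = as.integer(config$delay_max_ms),
    stimulus_enabled = isTRUE(config$stimulus_enabled),
    stimulus_thr = as.integer(config$stimulus_thr),
    punish_amplitude = config$punish_amplitude_mv,
    punish_ms = as.integer(config$punish_ms),
    punish_targets = .punish_targets0(network, config),
    duration_ms = as.integer(duration_ms)
  )
}

.assemble_run <- function(out, network, config, seed, duration_ms,
                          t_start = 0) {
  trials <- as_tibble(out$trials)
  trials$timed_out <- as.logical(trials$timed_out)
  trials <- tibble(trial = seq_len(nrow(trials)), trials)

  bin_s <- config$zone_bin_ms / 1000
  nb <- length(out$zone_a_counts)
  size_a <- max(length(network$zones$output_a %||% integer(0)), 1L)
  size_b <- max(length(network$zones$output_b %||% integer(0)), 1L)
  zone_rates <- tibble(
    time_s = t_start / 1000 + (seq_len(nb) - 0.5) * bin_s,
    rate_a_hz = out$zone_a_counts / size_a / bin_s,
    rate_b_hz = out$zone_b_counts / size_b / bin_s
  )
  win_s <- config$window_s
  neuron_rates <- tibble(
    neuron = rep(seq_len(network$n), 2),
    window = rep(c("first", "last"), each = network$n),
    rate_hz = c(out$counts_first / win_s, out$counts_last / win_s)
  )
  raster <- if (length(out$raster_t)) {
    tibble(time_ms = out$raster_t, neuron = out$raster_id + 1L)
  } else if (isTRUE(config$record_raster)) {
    tibble(time_ms = integer(0), neuron = integer(0))
  } else NULL

  lt <- learning_time(trials)
  run <- structure(
    list(
      trials = trials, zone_rates = zone_rates, neuron_rates = neuron_rates,
      raster = raster,
      snapshots = out$snapshots, snapshot_times = out$snapshot_times,
      w_final = t(out$w_final), state = out$state,
      network = network, config = config, seed = seed,
      duration_ms = duration_ms,
      success = !is.na(lt),
      learning_time_s = lt,
      attained_reaction_time_ms = attained_reaction_time(trials)
    ),
    class = "lsa_run"
  )
  run
}

#' Run a closed-loop stimulation-avoidance training protocol
#'
#' Executes the per-millisecond loop (input gathering, Izhikevich update,
#' short-term plasticity, stop/stimulus condition checks, STDP, decay) for
#' `duration_ms` simulated milliseconds under the protocol described by
#' `config`:
#'
#' * While a trial is active, the input zone is stimulated every millisecond.
#'   The trial ends when the stop condition holds in a 1 ms bin (at least
#'   `stop_thr_a` spikes in output zone A and, if set, fewer than `stop_thr_b`
#'   spikes in output zone B in the *same* bin), or times out after
#'   `timeout_ms` of stimulation. The next trial starts after a uniform random
#'   delay of `delay_min_ms` to `delay_max_ms`.
#' * If the stimulus condition is enabled, any millisecond with at least
#'   `stimulus_thr` spikes in output zone B triggers a `punish_ms`-long
#'   stimulation of all excitatory neurons outside zone B (a pending window is
#'   restarted by a new trigger).
#'
#' @param config An [lsa_config()].
#' @param seed Master seed (defaults to `config$seed`); fans out to substreams
#'   via [seed_for()].
#' @param duration_ms Simulated duration (defaults to `config$duration_ms`).
#' @param network Optionally, a pre-built [lsa_network()] with zones assigned
#'   (skips the seeded construction).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation composed from the exported step primitives; identical
#'   semantics, orders of magnitude slower - intended for validation on small
#'   fixtures).
#' @param record_raster Record the full spike raster (time, neuron) tibble.
#' @param snapshot_ms Interval for dense weight-matrix snapshots (0 = never).
#' @return An object of class `lsa_run` with elements `trials`, `zone_rates`,
#'   `neuron_rates`, `raster`, `snapshots`, `w_final`, `state` (for
#'   [resume()]), protocol `config`, `success`, `learning_time_s` and
#'   `attained_reaction_time_ms`. See [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' cfg <- lsa_config("selective_learning", duration_ms = 2000)
#' run <- simulate_training(cfg, seed = 1)
#' glance(run)
simulate_training <- function(config, seed = NULL,
                              duration_ms = config$duration_ms,
                              network = NULL, engine = c("cpp", "r"),
                              record_raster = config$record_raster,
                              snapshot_ms = config$snapshot_ms) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "lsa_config"))
  seed <- seed %||% config$seed
  if (is.null(network)) network <- .build_from_config(config, seed)
  if (is.null(network$zones)) {
    abort("network has no zones; call assign_zones() first")
  }
  config$record_raster <- record_raster
  config$snapshot_ms <- as.integer(snapshot_ms)
  set.seed(seed_for(seed, "run"))
  out <- .call_engine(network, config, duration_ms, engine,
                      state = NULL)
  .assemble_run(out, network, config, seed, duration_ms)
}

.call_engine <- function(network, config, duration_ms, engine = "cpp",
                         state = NULL) {
  dyn <- .dyn_list(config)
  proto <- .proto_list(network, config, duration_ms)
  rec <- list(
    record_raster = isTRUE(config$record_raster),
    zone_bin_ms = as.integer(config$zone_bin_ms),
    window_ms = as.integer(config$window_s * 1000),
    snapshot_ms = as.integer(config$snapshot_ms)
  )
  nn <- network$neurons
  if (engine == "cpp") {
    .run_network_cpp(t(network$weights), t(network$exists), network$n_exc,
                     nn$a, nn$b, nn$c, nn$d, nn$v, nn$u,
                     dyn, proto, rec, state)
  } else {
    .run_network_r(network, dyn, proto, rec, state)
  }
}

#' Continue a finished run for additional simulated time
#'
#' Resumes from the stored synaptic, neuronal, short-term-plasticity and
#' protocol state. Continuation is exact: a run of `a + b` ms equals a run of
#' `a` ms resumed for `b` ms, provided the R random-number-generator state is
#' carried over (i.e. resume in the same session without reseeding).
#'
#' @param run An `lsa_run`.
#' @param duration_ms Additional simulated milliseconds.
#' @return A new `lsa_run` covering the continuation segment.
#' @export
resume <- function(run, duration_ms) {
  stopifnot(inherits(run, "lsa_run"))
  network <- run$network
  network$weights <- run$w_final
  out <- .call_engine(network, run$config, duration_ms, engine = "cpp",
                      state = run$state)
  .assemble_run(out, network, run$config, run$seed, duration_ms,
                t_start = run$state$t)
}

#' @export
print.lsa_run <- function(x, ...) {
  cat(sprintf("<lsa_run> preset '%s', seed %s, %g s simulated\n",
              x$config$preset, format(x$seed), x$duration_ms / 1000))
  cat(sprintf("  trials: %d (%d timed out)\n", nrow(x$trials),
              sum(x$trials$timed_out)))
  if (isTRUE(x$success)) {
    cat(sprintf("  learned at %.1f s; attained reaction time %.0f ms\n",
                x$learning_time_s, x$attained_reaction_time_ms))
  } else {
    cat("  task not learned within the simulated budget\n")
  }
  invisible(x)
}

#' @rdname simulate_training
#' @param x An `lsa_run`.
#' @param ... Unused.
#' @export
tidy.lsa_run <- function(x, ...) x$trials

#' @rdname simulate_training
#' @export
glance.lsa_run <- function(x, ...) {
  tibble(
    preset = x$config$preset,
    seed = x$seed,
    duration_s = x$duration_ms / 1000,
    n_trials = nrow(x$trials),
    n_timeouts = sum(x$trials$timed_out),
    success = x$success,
    learning_time_s = x$learning_time_s,
    attained_reaction_time_ms = x$attained_reaction_time_ms
  )
}
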