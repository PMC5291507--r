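# Full key registry with defaults (the selective-learning parameter set).
.config_defaults <- function() {
  list(
    preset = "selective_learning",
    # network
    n_neurons = 100L, frac_inhibitory = 0.2,
    topology = "fully_connected", connections_per_neuron = 20L,
    weight_init = "uniform", weight_init_max = 5,
    weight_mean = 5, weight_variance = 1,
    zone_sizes = c(input = 10, output_a = 10, output_b = 10),
    forbid_direct_io = FALSE,
    # dynamics
    dt_ms = 1, integrator = "half_step",
    sigma_noise_mv = 3,
    # plasticity
    stdp_enabled = TRUE, stdp_A = 0.1, stdp_tau_ms = 20,
    stdp_pairing = "nearest", stdp_cutoff_ms = 100L,
    w_max = 10, decay_mu = 5e-7, decay_scope = "all",
    stp_enabled = FALSE, stp_U = 0.2, stp_tau_d_ms = 200, stp_tau_f_ms = 600,
    # protocol
    stim_enabled = TRUE, stim_amplitude_mv = 1,
    stop_thr_a = 4L, stop_thr_b = 4L,
    stimulus_enabled = FALSE, stimulus_thr = 1L,
    punish_amplitude_mv = 1, punish_ms = 10L, punish_scope = "excitatory_not_b",
    timeout_ms = 10000L, delay_min_ms = 1000L, delay_max_ms = 2000L,
    duration_ms = 400000L,
    # bookkeeping
    seed = 1L, record_raster = FALSE, zone_bin_ms = 1000L,
    window_s = 100, snapshot_ms = 0L,
    # three-neuron circuits: fixed initial weights (per-seed variation comes
    # from the noise stream); chain3_w_direct is the input->output weight
    chain3_fixed_weights = FALSE, chain3_w_direct = 1, chain3_w_other = 3
  )
}

.preset_overrides <- list(
  selective_learning = list(),
  selective_nostim_control = list(stim_enabled = FALSE),
  sparse_steering = list(
    topology = "sparse_fixed_outdegree", connections_per_neuron = 20L,
    weight_init_max = 10, w_max = 50, sigma_noise_mv = 5,
    stim_amplitude_mv = 10, punish_amplitude_mv = 10,
    stop_thr_a = 1L, stop_thr_b = NA_integer_,
    stimulus_enabled = TRUE, duration_ms = 500000L
  ),
  sparse_stop_only = list(
    topology = "sparse_fixed_outdegree", connections_per_neuron = 20L,
    weight_init_max = 10, w_max = 50, sigma_noise_mv = 5,
    stim_amplitude_mv = 10, stop_thr_a = 1L, stop_thr_b = NA_integer_,
    stimulus_enabled = FALSE, duration_ms = 500000L
  ),
  stp_selective = list(
    w_max = 20, stim_amplitude_mv = 10, punish_amplitude_mv = 10,
    stp_enabled = TRUE, forbid_direct_io = TRUE,
    stimulus_enabled = TRUE, duration_ms = 400000L
  ),
  sweep = list(
    topology = "sparse_fixed_outdegree", weight_init = "mean_offset",
    connections_per_neuron = 20L, w_max = 50, sigma_noise_mv = 5,
    stim_amplitude_mv = 10, stop_thr_a = 1L, stop_thr_b = NA_integer_,
    stimulus_enabled = FALSE, duration_ms = 500000L,
    zone_sizes = c(input = 10, output_a = 10)
  ),
  chain3_reinforce = list(
    topology = "chain3", n_neurons = 3L, frac_inhibitory = 0,
    sigma_noise_mv = 3, stim_amplitude_mv = 10, w_max = 10, decay_mu = 0,
    stop_thr_a = 1L, stop_thr_b = NA_integer_,
    zone_sizes = c(input = 1, output_a = 1), duration_ms = 600000L,
    snapshot_ms = 1000L,
    chain3_fixed_weights = TRUE, chain3_w_direct = 2, chain3_w_other = 3
  ),
  chain3_indirect = list(
    topology = "chain3", n_neurons = 3L, frac_inhibitory = 0,
    sigma_noise_mv = 3, stim_amplitude_mv = 10, w_max = 10, decay_mu = 0,
    stop_thr_a = 1L, stop_thr_b = NA_integer_,
    zone_sizes = c(input = 1, output_a = 1), forbid_direct_io = TRUE,
    duration_ms = 3000000L, snapshot_ms = 1000L,
    chain3_fixed_weights = TRUE, chain3_w_direct = 0, chain3_w_other = 3
  ),
  chain3_prune = list(
    topology = "chain3", n_neurons = 3L, frac_inhibitory = 0,
    sigma_noise_mv = 3, stim_amplitude_mv = 10, punish_amplitude_mv = 10,
    w_max = 10, decay_mu = 0,
    stim_enabled = FALSE, stimulus_enabled = TRUE, stimulus_thr = 1L,
    punish_scope = "input_zone",
    zone_sizes = c(input = 1, output_b = 1), duration_ms = 600000L,
    snapshot_ms = 1000L,
    chain3_fixed_weights = TRUE, chain3_w_direct = 3, chain3_w_other = 3
  )
)

#' Build a simulation configuration from a named preset
#'
#' Presets encode the parameter sets of the main experiments:
#' `selective_learning` (fully connected 100-neuron network, 1 mV stimulation,
#' sigma 3 mV, w_max 10, decay 5e-7, stop condition 4/4), its no-stimulation
#' control, `sparse_steering` (20 connections per neuron, 10 mV, sigma 5,
#' w_max 50, stop threshold 1 plus the punishment stimulus condition),
#' `sparse_stop_only`, `stp_selective` (fully connected with short-term
#' plasticity, w_max 20, zeroed direct input-output weights, 4/4 plus
#' punishment), `sweep` (connectivity sweep initialisation `5 + omega`), and
#' the three-neuron presets `chain3_reinforce`, `chain3_indirect`,
#' `chain3_prune`.
#'
#' Overrides are applied last; unknown keys are rejected.
#'
#' @param preset Preset name, see above.
#' @param ... Named overrides of individual configuration keys.
#' @return An object of class `lsa_config` (a named list).
#' @export
#' @examples
#' cfg <- lsa_config("selective_learning", sigma_noise_mv = 2)
#' cfg$sigma_noise_mv
lsa_config <- function(preset = "selective_learning", ...) {
  if (!preset %in% names(.preset_overrides)) {
    abort(sprintf("unknown preset '%s'; available: %s", preset,
                  paste(names(.preset_overrides), collapse = ", ")))
  }
  cfg <- modifyList(.config_defaults(), .preset_overrides[[preset]],
                    keep.null = TRUE)
  cfg$preset <- preset
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(.config_defaults()))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      abort(sprintf("unknown configuration key(s): %s",
                    paste(bad, collapse = ", ")))
    }
    cfg <- modifyList(cfg, over, keep.null = TRUE)
  }
  .validate_config(cfg)
  structure(cfg, class = "lsa_config")
}

.validate_config <- function(cfg) {
  if (!identical(as.numeric(cfg$dt_ms), 1)) {
    abort("dt_ms is fixed at 1 ms")
  }
  if (!cfg$integrator %in% c("half_step", "euler")) {
    abort("integrator must be 'half_step' or 'euler'")
  }
  if (!cfg$decay_scope %in% c("all", "plastic")) {
    abort("decay_scope must be 'all' or 'plastic'")
  }
  if (!cfg$punish_scope %in% c("excitatory_not_b", "input_zone")) {
    abort("punish_scope must be 'excitatory_not_b' or 'input_zone'")
  }
  if (cfg$decay_mu < 0 || cfg$decay_mu >= 1) abort("decay_mu must be in [0, 1)")
  if (is.null(names(cfg$zone_sizes))) abort("zone_sizes must be named")
  invisible(cfg)
}

#' @export
print.lsa_config <- function(x, ...) {
  cat(sprintf("<lsa_config> preset '%s'\n", x$preset))
  cat(sprintf("  network: %s, n=%d, w_max=%g, sigma=%g mV\n",
              x$topology, x$n_neurons, x$w_max, x$sigma_noise_mv))
  cat(sprintf("  stimulation: e=%g mV (%s), stop %s/%s, stimulus condition: %s\n",
              x$stim_amplitude_mv,
              if (x$stim_enabled) "on" else "off",
              x$stop_thr_a,
              ifelse(is.na(x$stop_thr_b), "-", x$stop_thr_b),
              if (x$stimulus_enabled) "on" else "off"))
  cat(sprintf("  plasticity: STDP A=%g tau=%g, decay mu=%g, STP %s\n",
              x$stdp_A, x$stdp_tau_ms, x$decay_mu,
              if (x$stp_enabled) "on" else "off"))
  invisible(x)
}

#' Load a configuration from a YAML or JSON file
#'
#' The file holds flat `key: value` pairs plus an optional `preset` key giving
#' the base preset (default `selective_learning`). Unknown keys are rejected
#' with the offending key named.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `lsa_config`.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(sprintf("unsupported config format '.%s' (use yaml or json)", ext))
  )
  if (!is.list(raw)) abort("config file must hold a mapping of keys")
  if (!is.null(raw$zone_sizes)) raw$zone_sizes <- unlist(raw$zone_sizes)
  preset <- raw$preset %||% "selective_learning"
  raw$preset <- NULL
  do.call(lsa_config, c(list(preset = preset), raw))
}
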