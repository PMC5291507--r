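#' Connectivity / weight-variance parameter sweep
#'
#' For each combination of out-degree `M` (output connections drawn per
#' neuron, with replacement) and initial-weight half-range `v` (weights
#' `5 + Uniform(-v, v)`, sign-preserving), runs `reps` independent
#' simple-learning experiments (stop condition only, threshold 1) and reports
#' the learnability of the output zone: its mean per-neuron firing rate over
#' the last 100 s minus the first 100 s of each run.
#'
#' @param m_values Out-degrees to test.
#' @param v_values Weight half-ranges to test.
#' @param reps Repetitions per cell (default 20).
#' @param duration_ms Run length (default 500,000 ms = 500 s).
#' @param seed Master seed; each cell/rep gets a distinct derived seed.
#' @param config Base configuration (default: the `sweep` preset).
#' @return A tibble with `connections_per_neuron`, `weight_variance`, `rep`,
#'   `seed`, `learnability_hz`.
#' @export
#' @examples
#' \donttest{
#' run_sweep(m_values = c(5, 25), v_values = 1, reps = 2,
#'           duration_ms = 200500)
#' }
run_sweep <- function(m_values, v_values, reps = 20, duration_ms = 500000,
                      seed = 1, config = NULL) {
  if (is.null(config)) config <- lsa_config("sweep")
  grid <- expand.grid(
    connections_per_neuron = m_values,
    weight_variance = v_values,
    rep = seq_len(reps),
    KEEP.OUT.ATTRS = FALSE
  )
  purrr::pmap_dfr(grid, function(connections_per_neuron, weight_variance,
                                 rep) {
    cfg <- lsa_config(
      config$preset,
      connections_per_neuron = as.integer(connections_per_neuron),
      weight_variance = weight_variance,
      duration_ms = as.integer(duration_ms)
    )
    run_seed <- seed_for(
      seed * 1000 + connections_per_neuron * 13 + weight_variance * 7 + rep,
      "run")
    run <- simulate_training(cfg, seed = run_seed)
    tibble(
      connections_per_neuron = connections_per_neuron,
      weight_variance = weight_variance,
      rep = rep,
      seed = run_seed,
      learnability_hz = learnability(run, zone = "a")
    )
  })
}
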