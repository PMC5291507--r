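#' Learning curve of a training run
#'
#' Reaction time per trial; timed-out trials are drawn in red at the timeout
#' limit, and the learning criterion (4000 ms) is marked.
#'
#' @param object An `lsa_run`.
#' @param threshold_ms Criterion line (default 4000).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lsa_run <- function(object, threshold_ms = 4000, ...) {
  tr <- object$trials
  tr$shown_rt <- ifelse(tr$timed_out, object$config$timeout_ms,
                        tr$reaction_time_ms)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trial, y = .data$shown_rt)) +
    ggplot2::geom_hline(yintercept = threshold_ms, linetype = "dashed") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$timed_out)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red"),
                                 name = "timed out") +
    ggplot2::labs(x = "trial", y = "reaction time (ms)",
                  title = sprintf("Learning curve (%s, seed %s)",
                                  object$config$preset,
                                  format(object$seed)))
}

#' Spike raster plot
#'
#' @param raster A raster tibble (`time_ms`, `neuron`) or an `lsa_run`
#'   recorded with `record_raster = TRUE`.
#' @return A ggplot object.
#' @export
plot_raster <- function(raster) {
  if (inherits(raster, "lsa_run")) {
    if (is.null(raster$raster)) {
      abort("run has no raster; rerun with record_raster = TRUE")
    }
    raster <- raster$raster
  }
  ggplot2::ggplot(raster,
                  ggplot2::aes(x = .data$time_ms / 1000, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "neuron")
}

#' Firing-rate trajectory of the two output zones
#'
#' The run's path in the (zone A rate, zone B rate) plane, coloured by time -
#' the space in which the stop + stimulus protocol steers the network.
#'
#' @param run An `lsa_run`.
#' @param bin_s Re-binning width in seconds (default 10).
#' @return A ggplot object.
#' @export
plot_zone_trajectory <- function(run, bin_s = 10) {
  zr <- run$zone_rates
  grp <- (seq_len(nrow(zr)) - 1) %/% bin_s
  agg <- dplyr::summarise(
    dplyr::group_by(zr, grp = grp),
    time_s = mean(.data$time_s),
    rate_a_hz = mean(.data$rate_a_hz),
    rate_b_hz = mean(.data$rate_b_hz),
    .groups = "drop"
  )
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$rate_a_hz, y = .data$rate_b_hz,
                                    colour = .data$time_s)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "output zone A rate (Hz/neuron)",
                  y = "output zone B rate (Hz/neuron)", colour = "time (s)")
}

#' Weight trajectories of a small-network run
#'
#' One line per directed connection; requires snapshots
#' (`snapshot_ms > 0`). Intended for the three-neuron experiments.
#'
#' @param run An `lsa_run` with snapshots.
#' @return A ggplot object.
#' @export
plot_weight_trajectories <- function(run) {
  wt <- weight_trajectory(run)
  wt <- wt[wt$pre != wt$post, , drop = FALSE]
  wt$connection <- sprintf("w[%d,%d]", wt$pre, wt$post)
  ggplot2::ggplot(wt, ggplot2::aes(x = .data$time_ms / 1000,
                                   y = .data$weight,
                                   colour = .data$connection)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "weight")
}

#' Arena trajectory of a robot run
#'
#' @param object An `lsa_robot_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lsa_robot_run <- function(object, ...) {
  side <- object$arena$arena_side
  rng <- object$arena$sensor_range
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$time_ms / 1000)) +
    ggplot2::geom_path() +
    ggplot2::annotate("rect", xmin = rng, xmax = side - rng, ymin = rng,
                      ymax = side - rng, fill = NA, linetype = "dotted",
                      colour = "grey40") +
    ggplot2::coord_fixed(xlim = c(0, side), ylim = c(0, side)) +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "time (s)",
                  title = sprintf("%s loop, seed %s", object$mode,
                                  format(object$seed)))
}

#' Heat map of a connectivity sweep
#'
#' @param sweep The tibble returned by [run_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  agg <- dplyr::summarise(
    dplyr::group_by(sweep, .data$connections_per_neuron,
                    .data$weight_variance),
    learnability_hz = mean(.data$learnability_hz), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = factor(.data$connections_per_neuron),
                                    y = factor(.data$weight_variance),
                                    fill = .data$learnability_hz)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "connections per neuron (M)",
                  y = "initial weight half-range (v)",
                  fill = "learnability\n(Hz/neuron)")
}
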