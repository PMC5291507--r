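#' Evaluate the stop condition on one millisecond bin
#'
#' True when at least `thr_a` neurons of output zone A spiked and - if a zone B
#' clause is set - fewer than `thr_b` neurons of output zone B spiked in the
#' same bin.
#'
#' @param spiked Logical vector over neurons, or integer indices of the
#'   neurons that spiked in this 1 ms bin.
#' @param zone_a,zone_b Integer neuron indices of the monitored zones
#'   (`zone_b = NULL` for simple-learning configurations).
#' @param thr_a Minimum zone A spike count (`>=`).
#' @param thr_b Zone B spike bound (`<`), or `NULL`/`NA` to skip the clause.
#' @return Logical flag.
#' @export
#' @examples
#' check_stop_condition(c(1, 2, 3, 4, 21), zone_a = 1:10, zone_b = 11:20)
check_stop_condition <- function(spiked, zone_a, zone_b = NULL,
                                 thr_a = 4, thr_b = 4) {
  ids <- if (is.logical(spiked)) which(spiked) else as.integer(spiked)
  ok_a <- sum(ids %in% zone_a) >= thr_a
  if (is.null(zone_b) || is.null(thr_b) || is.na(thr_b)) return(ok_a)
  ok_a && sum(ids %in% zone_b) < thr_b
}

#' Evaluate the stimulus (punishment) condition on one millisecond bin
#'
#' True when at least `thr` neurons of output zone B spiked; the protocol then
#' stimulates the whole network, excluding inhibitory neurons and zone B
#' itself, for 10 ms.
#'
#' @param spiked Logical vector or integer spike indices for the bin.
#' @param zone_b Integer neuron indices of output zone B.
#' @param thr Trigger threshold (default 1).
#' @return Logical flag.
#' @export
check_stimulus_condition <- function(spiked, zone_b, thr = 1) {
  ids <- if (is.logical(spiked)) which(spiked) else as.integer(spiked)
  sum(ids %in% zone_b) >= thr
}

#' Learning time of a trial sequence
#'
#' The task counts as learned at the start of the earliest trial from which
#' *every* subsequent reaction time stays below `threshold_ms` (timed-out
#' trials count as above threshold); an early dip that does not keep under the
#' limit does not count. Returns the elapsed simulated time in seconds at that
#' trial's stimulation onset, or `NA` if the criterion is never met.
#'
#' @param trials A tibble with columns `onset_ms`, `reaction_time_ms`,
#'   `timed_out` (as returned in `lsa_run$trials`), or an `lsa_run`.
#' @param threshold_ms Reaction-time criterion (default 4000 ms).
#' @return Learning time in seconds, or `NA_real_`.
#' @export
#' @examples
#' tr <- tibble::tibble(onset_ms = c(0, 11000, 16000),
#'                      reaction_time_ms = c(NA, 3000, 2000),
#'                      timed_out = c(TRUE, FALSE, FALSE))
#' learning_time(tr)
learning_time <- function(trials, threshold_ms = 4000) {
  if (inherits(trials, "lsa_run")) trials <- trials$trials
  n <- nrow(trials)
  if (n == 0) return(NA_real_)
  rt <- ifelse(trials$timed_out, Inf, trials$reaction_time_ms)
  ok <- rt < threshold_ms
  bad <- which(!ok)
  k <- if (length(bad)) max(bad) + 1L else 1L
  if (k > n) return(NA_real_)
  trials$onset_ms[k] / 1000
}

#' Mean reaction time after learning
#'
#' Averages the reaction times of all trials from the learning point onward
#' (the suffix of trials that stay below the criterion); `NA` when the task
#' was not learned.
#'
#' @inheritParams learning_time
#' @return Mean post-learning reaction time in ms, or `NA_real_`.
#' @export
attained_reaction_time <- function(trials, threshold_ms = 4000) {
  if (inherits(trials, "lsa_run")) trials <- trials$trials
  n <- nrow(trials)
  if (n == 0) return(NA_real_)
  rt <- ifelse(trials$timed_out, Inf, trials$reaction_time_ms)
  ok <- rt < threshold_ms
  bad <- which(!ok)
  k <- if (length(bad)) max(bad) + 1L else 1L
  if (k > n) return(NA_real_)
  mean(trials$reaction_time_ms[k:n])
}

#' Learnability: firing-rate change of an output zone
#'
#' The average per-neuron firing rate of the zone over the last `window_s`
#' seconds minus the average over the first `window_s` seconds of the run
#' (positive = the zone learned to fire more).
#'
#' @param run An `lsa_run` (zone rates are recorded in 1 s bins by default).
#' @param zone `"a"` or `"b"`.
#' @param window_s Window length in seconds (default 100).
#' @return Rate difference in Hz per neuron.
#' @export
learnability <- function(run, zone = c("a", "b"), window_s = 100) {
  zone <- match.arg(zone)
  stopifnot(inherits(run, "lsa_run"))
  if (run$duration_ms < 2 * window_s * 1000) {
    abort("run too short: learnability needs at least 2 * window_s of data")
  }
  zr <- run$zone_rates
  col <- if (zone == "a") zr$rate_a_hz else zr$rate_b_hz
  bin_s <- run$config$zone_bin_ms / 1000
  k <- round(window_s / bin_s)
  mean(tail(col, k)) - mean(head(col, k))
}

#' Zone firing-rate trajectory from a spike raster
#'
#' Bins a spike raster and reports the per-neuron firing rate of output zones
#' A and B over time (the two-dimensional state space in which the stop +
#' stimulus protocol steers the network).
#'
#' @param raster A tibble with columns `time_ms`, `neuron`.
#' @param zone_a,zone_b Integer neuron indices of the two zones.
#' @param bin_s Bin width in seconds (default 1).
#' @param duration_ms Total run length (defaults to the last observed bin).
#' @return A tibble with `time_s`, `rate_a_hz`, `rate_b_hz`.
#' @export
zone_rate_trajectory <- function(raster, zone_a, zone_b, bin_s = 1,
                                 duration_ms = NULL) {
  duration_ms <- duration_ms %||%
    (if (nrow(raster)) (max(raster$time_ms) %/% (bin_s * 1000) + 1) *
       bin_s * 1000 else bin_s * 1000)
  n_bins <- ceiling(duration_ms / (bin_s * 1000))
  bin_of <- function(t) pmin(t %/% (bin_s * 1000) + 1, n_bins)
  count_zone <- function(zone) {
    sub <- raster[raster$neuron %in% zone, , drop = FALSE]
    tabulate(bin_of(sub$time_ms), nbins = n_bins)
  }
  tibble(
    time_s = (seq_len(n_bins) - 0.5) * bin_s,
    rate_a_hz = count_zone(zone_a) / max(length(zone_a), 1) / bin_s,
    rate_b_hz = count_zone(zone_b) / max(length(zone_b), 1) / bin_s
  )
}

#' Per-neuron firing-rate distribution in a time window
#'
#' Computes each neuron's firing rate over the first or last `window_s`
#' seconds and histograms the rates (used to compare the network before and
#' after learning).
#'
#' @param run An `lsa_run`.
#' @param window `"first"` or `"last"`.
#' @param breaks Histogram breaks in Hz (passed to [graphics::hist()]
#'   semantics via [cut()]); default 0 to the maximum rate in 1 Hz bins.
#' @return A tibble with `bin_lo`, `bin_hi`, `n_neurons`.
#' @export
firing_rate_distribution <- function(run, window = c("first", "last"),
                                     breaks = NULL) {
  window <- match.arg(window)
  stopifnot(inherits(run, "lsa_run"))
  rates <- run$neuron_rates$rate_hz[run$neuron_rates$window == window]
  if (is.null(breaks)) breaks <- seq(0, max(1, ceiling(max(rates))), by = 1)
  idx <- cut(rates, breaks = breaks, include.lowest = TRUE, right = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  tibble(
    bin_lo = head(breaks, -1),
    bin_hi = tail(breaks, -1),
    n_neurons = counts
  )
}

#' Weight trajectories from snapshots
#'
#' Long-format weight time series from a run recorded with `snapshot_ms > 0`;
#' handy for the three-neuron reinforcement/pruning experiments.
#'
#' @param run An `lsa_run` with snapshots.
#' @return A tibble with `time_ms`, `pre`, `post`, `weight`.
#' @export
weight_trajectory <- function(run) {
  stopifnot(inherits(run, "lsa_run"))
  if (!length(run$snapshots)) {
    abort("run has no weight snapshots; rerun with snapshot_ms > 0")
  }
  n <- run$network$n
  purrr::map2_dfr(run$snapshots, run$snapshot_times, function(wpp, tm) {
    w <- t(wpp)                                 # back to [pre, post]
    tibble(
      time_ms = tm,
      pre = rep(seq_len(n), times = n),
      post = rep(seq_len(n), each = n),
      weight = as.vector(w)
    )
  })
}
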