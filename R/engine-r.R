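# Reference implementation of the training loop, composed from the exported
# step primitives. Semantics (and the random-number stream) match the compiled
# engine exactly; used to validate it on small fixtures. Weight decay is
# applied eagerly here (the compiled engine folds an algebraically identical
# scalar factor lazily), so with decay_mu > 0 weights agree to rounding, and
# exactly when decay_mu = 0.
.run_network_r <- function(network, dyn, proto, rec, state = NULL) {
  n <- network$n
  n_exc <- network$n_exc
  nn <- network$neurons
  w <- network$weights          # w[pre, post]
  exists <- network$exists
  plastic <- matrix(FALSE, n, n)
  plastic[seq_len(n_exc), seq_len(n_exc)] <- TRUE
  diag(plastic) <- FALSE
  plastic <- plastic & exists

  v <- nn$v; u <- nn$u
  stp <- stp_init(n, U = dyn$stp_U)
  last_spike <- rep(NA_integer_, n)
  fired_prev <- integer(0)
  t0 <- 0
  stim_on <- FALSE; onset <- 0; next_onset <- 0; punish_until <- -1
  if (!is.null(state)) {
    v <- state$v; u <- state$u
    stp <- list(x = state$stp_x, u = state$stp_u)
    last_spike <- ifelse(state$last_spike < 0, NA_integer_, state$last_spike)
    fired_prev <- state$fired_prev + 1L
    t0 <- state$t
    stim_on <- state$stim_on; onset <- state$onset
    next_onset <- state$next_onset; punish_until <- state$punish_until
  }
  zone_in <- proto$input_zone + 1L
  zone_a <- proto$zone_a + 1L
  zone_b <- proto$zone_b + 1L
  punish_targets <- proto$punish_targets + 1L
  duration <- proto$duration_ms
  substeps <- dyn$substeps

  trials <- list()
  ras_t <- integer(0); ras_id <- integer(0)
  n_bins <- if (rec$zone_bin_ms > 0) ceiling(duration / rec$zone_bin_ms) else 0
  binA <- numeric(n_bins); binB <- numeric(n_bins)
  cnt_first <- numeric(n); cnt_last <- numeric(n)
  snaps <- list(); snap_times <- numeric(0)

  for (t in seq(t0, t0 + duration - 1)) {
    if (proto$stim_enabled && !stim_on && t >= next_onset) {
      stim_on <- TRUE
      onset <- t
    }
    e_ext <- numeric(n)
    if (stim_on) e_ext[zone_in] <- e_ext[zone_in] + proto$stim_amplitude
    if (t < punish_until) {
      e_ext[punish_targets] <- e_ext[punish_targets] + proto$punish_amplitude
    }
    # input gathering: noise, then one presynaptic neuron at a time in the
    # order the spikes were recorded (matches the compiled accumulation order)
    I <- e_ext + (if (dyn$sigma > 0) dyn$sigma * rnorm(n) else 0)
    for (j in fired_prev) {
      f <- if (dyn$stp_enabled && j <= n_exc) stp$u[j] * stp$x[j] else 1
      I <- I + f * w[j, ]
    }
    st <- .izh_advance(v, u, I, nn$a, nn$b, nn$c, nn$d, substeps = substeps)
    v <- st$v; u <- st$u
    fired_flag <- st$fired
    fired <- which(fired_flag)
    if (dyn$stp_enabled) {
      e_idx <- seq_len(n_exc)
      sub <- stp_step(list(x = stp$x[e_idx], u = stp$u[e_idx]),
                      fired_flag[e_idx],
                      U = dyn$stp_U, tau_d = dyn$stp_tau_d,
                      tau_f = dyn$stp_tau_f)
      stp$x[e_idx] <- sub$x
      stp$u[e_idx] <- sub$u
    }
    nA <- sum(fired_flag[zone_a])
    nB <- sum(fired_flag[zone_b])
    if (stim_on) {
      met <- nA >= proto$stop_thr_a &&
        (proto$stop_thr_b < 0 || nB < proto$stop_thr_b)
      if (met) {
        dly <- proto$delay_min_ms +
          floor(runif(1) * (proto$delay_max_ms - proto$delay_min_ms + 1))
        trials[[length(trials) + 1L]] <-
          c(onset, t - onset, 0, dly)
        stim_on <- FALSE
        next_onset <- t + dly
      } else if (t - onset + 1 >= proto$timeout_ms) {
        dly <- proto$delay_min_ms +
          floor(runif(1) * (proto$delay_max_ms - proto$delay_min_ms + 1))
        trials[[length(trials) + 1L]] <- c(onset, NA, 1, dly)
        stim_on <- FALSE
        next_onset <- t + 1 + dly
      }
    }
    if (proto$stimulus_enabled && nB >= proto$stimulus_thr) {
      punish_until <- t + 1 + proto$punish_ms
    }
    if (dyn$stdp_enabled) {
      w <- apply_stdp(w, last_spike, fired_flag, t, n_exc, plastic = plastic,
                      A = dyn$stdp_A, tau = dyn$stdp_tau,
                      cutoff = dyn$stdp_cutoff_ms, w_max = dyn$w_max)
    }
    if (dyn$decay_mu > 0) {
      if (dyn$decay_scope == "all") {
        w <- apply_decay(w, dyn$decay_mu)
      } else {
        w[seq_len(n_exc), seq_len(n_exc)] <-
          apply_decay(w[seq_len(n_exc), seq_len(n_exc)], dyn$decay_mu)
      }
    }
    last_spike[fired] <- t
    fired_prev <- fired

    rel <- t - t0
    if (n_bins > 0) {
      bin <- rel %/% rec$zone_bin_ms + 1L
      binA[bin] <- binA[bin] + nA
      binB[bin] <- binB[bin] + nB
    }
    if (rec$record_raster && length(fired)) {
      ras_t <- c(ras_t, rep.int(as.integer(t), length(fired)))
      ras_id <- c(ras_id, fired - 1L)
    }
    if (rel < rec$window_ms) cnt_first[fired] <- cnt_first[fired] + 1
    if (rel >= duration - rec$window_ms) cnt_last[fired] <- cnt_last[fired] + 1
    if (rec$snapshot_ms > 0 && (rel + 1) %% rec$snapshot_ms == 0) {
      snaps[[length(snaps) + 1L]] <- t(w)
      snap_times <- c(snap_times, t + 1)
    }
  }

  tr <- if (length(trials)) do.call(rbind, trials) else matrix(numeric(0), 0, 4)
  state_out <- list(
    v = v, u = u, stp_x = stp$x, stp_u = stp$u,
    last_spike = ifelse(is.na(last_spike), -1L, as.integer(last_spike)),
    fired_prev = fired_prev - 1L, t = t0 + duration,
    stim_on = stim_on, onset = onset, next_onset = next_onset,
    punish_until = punish_until, pending_delay = 0L
  )
  list(
    trials = data.frame(onset_ms = tr[, 1], reaction_time_ms = tr[, 2],
                        timed_out = tr[, 3], delay_ms = tr[, 4]),
    raster_t = ras_t, raster_id = ras_id,
    zone_a_counts = binA, zone_b_counts = binB,
    counts_first = cnt_first, counts_last = cnt_last,
    snapshots = snaps, snapshot_times = snap_times,
    w_final = t(w), state = state_out
  )
}
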