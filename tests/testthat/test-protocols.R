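test_that("stop condition needs zone A active and zone B quiet in one bin", {
  za <- 1:10
  zb <- 11:20
  expect_true(check_stop_condition(c(1:4, 11:13), za, zb))       # A=4, B=3
  expect_false(check_stop_condition(c(1:4, 11:14), za, zb))      # A=4, B=4
  expect_false(check_stop_condition(integer(0), za, zb))
  # simple-learning configs skip the B clause
  expect_true(check_stop_condition(1:4, za, zone_b = NULL, thr_a = 4))
  expect_true(check_stop_condition(c(1, 11:20), za, zb, thr_a = 1,
                                   thr_b = NA))
})

test_that("stimulus condition triggers on zone B activity", {
  zb <- 11:20
  expect_true(check_stimulus_condition(11, zb))
  expect_false(check_stimulus_condition(c(1:10, 21), zb))
  expect_true(check_stimulus_condition(c(11, 12), zb, thr = 2))
})

test_that("learning time is the start of the stable sub-threshold suffix", {
  mk <- function(rt) {
    n <- length(rt)
    tibble::tibble(
      onset_ms = (seq_len(n) - 1) * 12000,
      reaction_time_ms = ifelse(is.na(rt), NA, rt),
      timed_out = is.na(rt))
  }
  tr <- mk(c(9000, 5000, 3000, 2000, 1000))
  expect_equal(learning_time(tr), 2 * 12)        # third trial onset, seconds
  # an early dip does not count if it does not keep under the limit
  tr2 <- mk(c(3000, 6000, 3000, 3000, 3000))
  expect_equal(learning_time(tr2), 2 * 12)
  # all timed out -> failure
  expect_true(is.na(learning_time(mk(c(NA, NA, NA)))))
  expect_true(is.na(learning_time(mk(numeric(0)))))
  # attained reaction time averages the suffix
  expect_equal(attained_reaction_time(tr), mean(c(3000, 2000, 1000)))
})

test_that("learning time agrees with a brute-force suffix scan", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(1:15, 1)
    rt <- sample(c(500, 2000, 3999, 4000, 8000), n, replace = TRUE)
    to <- runif(n) < 0.2
    rt[to] <- NA
    tr <- tibble::tibble(onset_ms = cumsum(c(0, rep(11000, n - 1))),
                         reaction_time_ms = rt, timed_out = to)
    k <- oracle_learning_index(ifelse(to, Inf, rt), to)
    expect_equal(learning_time(tr),
                 if (is.na(k)) NA_real_ else tr$onset_ms[k] / 1000)
  }
})

test_that("zone rate trajectory recounts a synthetic raster", {
  za <- 1:10
  zb <- 11:20
  # empty raster -> all-zero trajectory
  empty <- tibble::tibble(time_ms = integer(0), neuron = integer(0))
  tr <- zone_rate_trajectory(empty, za, zb, bin_s = 1, duration_ms = 3000)
  expect_equal(tr$rate_a_hz, rep(0, 3))
  # one zone A spike in one bin -> 1/(10 * bin_s) Hz per neuron
  one <- tibble::tibble(time_ms = 1500L, neuron = 3L)
  tr <- zone_rate_trajectory(one, za, zb, bin_s = 1, duration_ms = 3000)
  expect_equal(tr$rate_a_hz, c(0, 0.1, 0))
  expect_equal(tr$rate_b_hz, rep(0, 3))
  # random raster vs direct recount
  set.seed(8)
  ras <- tibble::tibble(time_ms = sample(0:9999, 400, replace = TRUE),
                        neuron = sample(1:30, 400, replace = TRUE))
  tr <- zone_rate_trajectory(ras, za, zb, bin_s = 2, duration_ms = 10000)
  for (b in 1:5) {
    in_bin <- ras$time_ms >= (b - 1) * 2000 & ras$time_ms < b * 2000
    expect_equal(tr$rate_a_hz[b],
                 sum(in_bin & ras$neuron %in% za) / 10 / 2)
    expect_equal(tr$rate_b_hz[b],
                 sum(in_bin & ras$neuron %in% zb) / 10 / 2)
  }
})

test_that("learnability is the late-minus-early zone rate difference", {
  mk_run <- function(rate_first, rate_last, dur_s = 500) {
    rates <- c(rep(rate_first, min(100, dur_s)),
               rep(rate_last, max(dur_s - 100, 0)))
    structure(list(
      zone_rates = tibble::tibble(time_s = seq_len(dur_s) - 0.5,
                                  rate_a_hz = rates, rate_b_hz = rates * 0),
      config = lsa_config("sweep"),
      duration_ms = dur_s * 1000), class = "lsa_run")
  }
  expect_equal(learnability(mk_run(5, 5)), 0)
  expect_equal(learnability(mk_run(0, 10)), 10)
  expect_error(learnability(mk_run(0, 10, dur_s = 150)), "too short")
})

test_that("firing rate distribution histograms per-neuron window rates", {
  mk_run <- function(rates_first, rates_last) {
    n <- length(rates_first)
    structure(list(
      neuron_rates = tibble::tibble(
        neuron = rep(seq_len(n), 2),
        window = rep(c("first", "last"), each = n),
        rate_hz = c(rates_first, rates_last)),
      config = lsa_config("stp_selective")), class = "lsa_run")
  }
  run <- mk_run(rep(0, 50), rep(5, 50))
  d0 <- firing_rate_distribution(run, "first", breaks = 0:10)
  expect_equal(d0$n_neurons[1], 50)
  expect_equal(sum(d0$n_neurons), 50)
  d5 <- firing_rate_distribution(run, "last", breaks = 0:10)
  expect_equal(d5$n_neurons[6], 50)       # all mass in the [5,6) bin
  # mixed rates vs direct recount
  set.seed(4)
  r <- runif(100, 0, 8)
  dm <- firing_rate_distribution(mk_run(r, r), "first", breaks = 0:9)
  expect_equal(dm$n_neurons, as.vector(table(cut(r, 0:9, right = FALSE))))
})

test_that("reaction time is measured from onset to the satisfying bin", {
  # deterministic circuit: strong direct weight, no noise; the output neuron's
  # first spike time in the raster must equal the recorded reaction time
  # a 20 mV weight lets a single presynaptic spike trigger the output neuron
  w <- matrix(0, 3, 3)
  w[1, 3] <- 20
  net <- fixture_chain3(w, w_max = 20)
  cfg <- lsa_config("chain3_reinforce", sigma_noise_mv = 0, w_max = 20,
                    chain3_fixed_weights = FALSE, duration_ms = 3000L,
                    snapshot_ms = 0L)
  run <- simulate_training(cfg, seed = 1, network = net, record_raster = TRUE)
  expect_gte(nrow(run$trials), 1)
  first_out <- min(run$raster$time_ms[run$raster$neuron == 3])
  expect_equal(run$trials$reaction_time_ms[1],
               first_out - run$trials$onset_ms[1])
})

test_that("timeouts schedule the next trial after the drawn delay", {
  # nothing can fire: all weights zero, no noise; every trial times out and
  # total simulated time decomposes exactly into trials plus delays
  net <- fixture_chain3(matrix(0, 3, 3))
  cfg <- lsa_config("chain3_reinforce", sigma_noise_mv = 0,
                    stim_amplitude_mv = 0.5, chain3_fixed_weights = FALSE,
                    duration_ms = 60000L, snapshot_ms = 0L)
  run <- simulate_training(cfg, seed = 2, network = net)
  tr <- run$trials
  expect_true(all(tr$timed_out))
  expect_true(all(tr$delay_ms >= 1000 & tr$delay_ms <= 2000))
  expect_gte(nrow(tr), 4)
  # conservation: onset_{k+1} = onset_k + timeout + delay_k
  expect_equal(tr$onset_ms[-1],
               tr$onset_ms[-nrow(tr)] + 10000 + tr$delay_ms[-nrow(tr)])
})

test_that("a silent unstimulated network logs no trials and no learning", {
  cfg <- lsa_config("selective_nostim_control", duration_ms = 5000)
  run <- simulate_training(cfg, seed = 3)
  expect_equal(nrow(run$trials), 0)
  expect_false(run$success)
  expect_true(is.na(run$learning_time_s))
})

test_that("the stimulus condition stimulates for 10 ms outside zone B", {
  # rig: stimulation drives neuron 1, the strong 1->3 weight makes neuron 3
  # (output zone B) spike, which must trigger a punishment window that makes
  # the otherwise disconnected neuron 2 fire within 10 ms
  w <- matrix(0, 3, 3)
  w[1, 3] <- 20
  net <- fixture_chain3(w, w_max = 20,
                        zones = list(input = 1L, output_b = 3L))
  cfg <- lsa_config("chain3_prune", sigma_noise_mv = 0, stim_enabled = TRUE,
                    w_max = 20, punish_amplitude_mv = 30,
                    punish_scope = "excitatory_not_b",
                    chain3_fixed_weights = FALSE,
                    duration_ms = 5000L, snapshot_ms = 0L,
                    zone_sizes = c(input = 1, output_b = 1))
  run <- simulate_training(cfg, seed = 1, network = net, record_raster = TRUE)
  t3 <- run$raster$time_ms[run$raster$neuron == 3]
  t2 <- run$raster$time_ms[run$raster$neuron == 2]
  expect_gt(length(t3), 0)
  expect_gt(length(t2), 0)
  # neuron 2 can only fire inside a punishment window: within ~10 ms of a
  # preceding zone B spike (a small allowance for the regenerative upstroke
  # completing just after the window)
  gaps <- vapply(t2, function(t) min(t - t3[t3 < t]), numeric(1))
  expect_true(all(gaps >= 1 & gaps <= 12))
  # zone B itself is never punished: neuron 3 fires only via the 1 -> 3 drive
  # (every neuron 3 spike follows a neuron 1 spike; crossing the threshold
  # saddle can take a few extra milliseconds)
  t1 <- run$raster$time_ms[run$raster$neuron == 1]
  gap13 <- vapply(t3, function(t) min(t - t1[t1 < t]), numeric(1))
  expect_true(all(gap13 >= 1 & gap13 <= 20))
})

test_that("zone rates recorded by the engine match the recorded raster", {
  cfg <- lsa_config("selective_learning", duration_ms = 4000)
  run <- simulate_training(cfg, seed = 13, record_raster = TRUE)
  z <- run$network$zones
  tr <- zone_rate_trajectory(run$raster, z$output_a, z$output_b,
                             bin_s = 1, duration_ms = 4000)
  expect_equal(run$zone_rates$rate_a_hz, tr$rate_a_hz)
  expect_equal(run$zone_rates$rate_b_hz, tr$rate_b_hz)
})
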