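test_that("a regular-spiking neuron rests at its fixed point", {
  # 0.04 v^2 + 5 v + 140 - u = 0 with u = b v and b = 0.2 rests at v = -70
  p <- izhikevich_params("regular_spiking")
  neurons <- tibble::tibble(a = p$a, b = p$b, c = p$c, d = p$d,
                            v = -70, u = 0.2 * -70)
  out <- izhikevich_step(neurons, I = 0)
  expect_false(out$fired)
  expect_equal(out$v, -70, tolerance = 1e-10)
  expect_equal(out$u, -14, tolerance = 1e-10)
})

test_that("a neuron at or above threshold spikes and resets to c", {
  p <- izhikevich_params("fast_spiking")
  neurons <- tibble::tibble(a = p$a, b = p$b, c = p$c, d = p$d,
                            v = c(35, 30, -65),
                            u = c(0, 0, p$b * -65))
  out <- izhikevich_step(neurons, I = 0)
  expect_equal(out$fired, c(TRUE, TRUE, FALSE))
  expect_equal(out$v[1:2], c(p$c, p$c))
})

test_that("non-finite membrane state aborts with a diagnostic", {
  p <- izhikevich_params("regular_spiking")
  neurons <- tibble::tibble(a = p$a, b = p$b, c = p$c, d = p$d,
                            v = NaN, u = 0)
  expect_error(izhikevich_step(neurons, I = 0), "non-finite")
})

test_that("1 ms integration tracks a fine-step reference", {
  # regular-spiking rates up to ~20 Hz agree within one spike per second
  for (I in c(4, 6, 10)) {
    coarse <- package_spike_count(I, dur_ms = 1000)
    fine <- oracle_spike_count(I, dur_ms = 1000, dt = 0.01)
    expect_lte(abs(coarse - fine), 1)
  }
  # at stronger drive the 1 ms grid quantizes the period (every spike
  # consumes a full step): the count is biased low, bounded at ~12%
  for (I in c(12, 20)) {
    coarse <- package_spike_count(I, dur_ms = 1000)
    fine <- oracle_spike_count(I, dur_ms = 1000, dt = 0.01)
    expect_lte(coarse, fine + 1)
    expect_gte(coarse, fine * 0.88 - 1)
  }
  # fast-spiking cells run near the grid limit (true period ~7 ms at
  # I = 10): the rate is underestimated but stays within a factor of two
  coarse_fs <- package_spike_count(10, type = "fast_spiking")
  fine_fs <- oracle_spike_count(
    10, dt = 0.01, p = izhikevich_params("fast_spiking"))
  expect_lte(coarse_fs, fine_fs + 1)
  expect_gte(coarse_fs, fine_fs / 2)
})

test_that("gather_inputs sums synapses, stimulation and noise per definition", {
  # empty sums
  w <- matrix(0, 3, 3)
  out <- gather_inputs(w, spikes_prev = rep(FALSE, 3))
  expect_equal(out$I_total, c(0, 0, 0))

  # direct weight sum from one firing presynaptic neuron
  w[1, 2] <- 5
  w[1, 3] <- 2
  out <- gather_inputs(w, spikes_prev = c(TRUE, FALSE, FALSE))
  expect_equal(out$I_synaptic, c(0, 5, 2))
  expect_equal(out$I_total, c(0, 5, 2))

  # 1 mV channel on 10 targets
  w10 <- matrix(0, 20, 20)
  ch <- stimulus_channel(1:10, amplitude = 1)
  out <- gather_inputs(w10, spikes_prev = rep(FALSE, 20), stimuli = ch)
  expect_equal(out$e_external, rep(c(1, 0), each = 10))
  # inactive channel contributes nothing
  ch$active <- FALSE
  out <- gather_inputs(w10, spikes_prev = rep(FALSE, 20), stimuli = list(ch))
  expect_equal(out$I_total, rep(0, 20))

  expect_error(
    gather_inputs(w, spikes_prev = rep(FALSE, 3),
                  stimuli = stimulus_channel(4, 1)),
    "outside")
})

test_that("gather_inputs is linear in disjoint spike sets", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 12
    w <- matrix(runif(n * n, -2, 5), n, n)
    diag(w) <- 0
    s1 <- sample(n, 4)
    s2 <- sample(setdiff(seq_len(n), s1), 4)
    i1 <- gather_inputs(w, s1)$I_synaptic
    i2 <- gather_inputs(w, s2)$I_synaptic
    i12 <- gather_inputs(w, c(s1, s2))$I_synaptic
    expect_equal(i12, i1 + i2, tolerance = 1e-12)
  }
})

test_that("the compiled engine is bit-reproducible under a fixed seed", {
  cfg <- lsa_config("selective_learning", duration_ms = 2000)
  r1 <- simulate_training(cfg, seed = 7, record_raster = TRUE)
  r2 <- simulate_training(cfg, seed = 7, record_raster = TRUE)
  expect_identical(r1$raster, r2$raster)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$w_final, r2$w_final)
})

test_that("compiled engine and R reference engine agree step for step", {
  # noise, stimulation, STDP and decay all active; the spike raster and trial
  # log must match exactly, weights to rounding (decay is folded lazily in
  # the compiled engine, eagerly in R)
  cfg <- lsa_config("selective_learning", duration_ms = 2500)
  rc <- simulate_training(cfg, seed = 11, engine = "cpp", record_raster = TRUE)
  rr <- simulate_training(cfg, seed = 11, engine = "r", record_raster = TRUE)
  expect_identical(rc$raster, rr$raster)
  expect_equal(as.data.frame(rc$trials), as.data.frame(rr$trials))
  expect_equal(rc$w_final, rr$w_final, tolerance = 1e-10)
  expect_equal(rc$zone_rates, rr$zone_rates)

  # and with STP + punishment (stimulus condition) active
  cfg2 <- lsa_config("stp_selective", duration_ms = 1500)
  sc <- simulate_training(cfg2, seed = 3, engine = "cpp", record_raster = TRUE)
  sr <- simulate_training(cfg2, seed = 3, engine = "r", record_raster = TRUE)
  expect_identical(sc$raster, sr$raster)
  expect_equal(sc$w_final, sr$w_final, tolerance = 1e-10)
})
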