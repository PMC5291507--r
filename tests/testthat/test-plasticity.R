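test_that("stdp_delta matches the exponential pair rule", {
  expect_equal(stdp_delta(1), 0.1 * exp(-1 / 20), tolerance = 1e-12)
  expect_equal(stdp_delta(1), 0.09512, tolerance = 1e-4)
  expect_equal(stdp_delta(0), 0)
  expect_equal(stdp_delta(-20), -0.1 * exp(-1), tolerance = 1e-12)
  expect_equal(stdp_delta(-20), -0.03679, tolerance = 1e-4)
})

test_that("stdp_delta is antisymmetric, decaying and bounded by A", {
  s <- 1:100
  expect_equal(stdp_delta(-s), -stdp_delta(s))
  d <- stdp_delta(s)
  expect_true(all(diff(d) < 0))           # strictly decreasing in s > 0
  expect_true(all(abs(stdp_delta(-100:100)) <= 0.1))
  # custom constants
  expect_equal(stdp_delta(5, A = 0.2, tau = 10), 0.2 * exp(-0.5))
})

test_that("apply_stdp pairs nearest spikes and clips to [0, w_max]", {
  w <- matrix(0, 2, 2)
  w[1, 2] <- 5
  last <- c(100, NA)                       # pre fired at t = 100
  spikes <- c(FALSE, TRUE)                 # post fires at t = 105
  out <- apply_stdp(w, last, spikes, t = 105, n_exc = 2, w_max = 10)
  expect_equal(out[1, 2], 5 + 0.1 * exp(-5 / 20))
  expect_equal(out[2, 1], 0)               # depression clipped at the floor

  # at the cap the weight stays at the cap
  w[1, 2] <- 10
  out <- apply_stdp(w, last, spikes, t = 105, n_exc = 2, w_max = 10)
  expect_equal(out[1, 2], 10)

  # outside the pairing window nothing changes
  w[1, 2] <- 5
  out <- apply_stdp(w, c(1, NA), spikes, t = 205, n_exc = 2, w_max = 10)
  expect_equal(out[1, 2], 5)

  # simultaneous spikes change nothing
  out <- apply_stdp(w, c(100, 100), c(TRUE, TRUE), t = 100, n_exc = 2,
                    w_max = 10)
  expect_equal(out, w)
})

test_that("plastic weights stay in [0, w_max] under random STDP/decay", {
  set.seed(5)
  n <- 6
  w <- matrix(runif(n * n, 0, 10), n, n)
  diag(w) <- 0
  last <- rep(NA_real_, n)
  for (t in 1:300) {
    spikes <- runif(n) < 0.2
    w <- apply_stdp(w, last, spikes, t, n_exc = n, w_max = 10)
    w <- apply_decay(w, 1e-4)
    last[spikes] <- t
    expect_true(all(w >= 0 & w <= 10))
  }
})

test_that("apply_decay follows w <- (1 - mu) w", {
  expect_equal(apply_decay(10, 5e-7), 9.999995)
  expect_equal(apply_decay(c(1, 2, 3), 0), c(1, 2, 3))
  expect_error(apply_decay(1, 1.2))
})

test_that("iterated engine decay matches the closed-form power", {
  # silent network (zero weights, zero noise, no stimulation): weights can
  # only change through decay; 1e5 iterations of mu = 5e-7
  net <- fixture_chain3(matrix(3, 3, 3))
  cfg <- lsa_config("chain3_reinforce", sigma_noise_mv = 0,
                    stim_enabled = FALSE, decay_mu = 5e-7,
                    chain3_fixed_weights = FALSE,
                    duration_ms = 100000L, snapshot_ms = 0L)
  run <- simulate_training(cfg, seed = 1, network = net)
  expect_equal(nrow(run$trials), 0)
  off_diag <- run$w_final[row(run$w_final) != col(run$w_final)]
  expect_equal(off_diag, rep(3 * (1 - 5e-7)^1e5, 6), tolerance = 1e-12)
})

test_that("STP rests at x = 1, u = U and depresses sustained firing", {
  # fixed point under silence
  stp <- stp_init(1)
  for (t in 1:5000) stp <- stp_step(stp, FALSE)
  expect_equal(stp$x, 1, tolerance = 1e-4)
  expect_equal(stp$u, 0.2, tolerance = 1e-4)

  # one-step Euler jumps for a single spike from rest
  stp <- stp_step(stp_init(1), TRUE)
  expect_equal(stp$x, 1 - 0.2)             # depleted by u x
  expect_equal(stp$u, 0.2 + 0.2 * 0.8)     # jumps toward 1 by U (1 - u)

  # sustained 100 Hz firing settles below the single-spike efficacy
  single <- stp$u * stp$x
  stp <- stp_init(1)
  ux_track <- numeric(0)
  for (t in 1:20000) {
    f <- (t %% 10) == 0
    stp <- stp_step(stp, f)
    if (f && t > 15000) ux_track <- c(ux_track, stp$u * stp$x)
  }
  expect_lt(mean(ux_track), single)
})

test_that("u x never exceeds 1 over random spike trains", {
  set.seed(9)
  for (rate in c(0.02, 0.2, 0.8)) {
    stp <- stp_init(4)
    for (t in 1:3000) {
      stp <- stp_step(stp, runif(4) < rate)
      expect_true(all(stp$u * stp$x <= 1))
      expect_true(all(stp$x > 0 & stp$x <= 1))
      expect_true(all(stp$u >= 0 & stp$u < 1))
    }
  }
})

test_that("effective weights modulate excitatory outputs only", {
  w <- matrix(10, 3, 3)
  expect_equal(effective_weights(w, n_exc = 2, stp = NULL), w)
  stp <- list(x = c(1, 0.5, 1), u = c(0.2, 0.4, 0.2))
  out <- effective_weights(w, n_exc = 2, stp = stp)
  expect_equal(out[1, ], rep(2, 3))        # u x w = 0.2 * 1 * 10
  expect_equal(out[2, ], rep(2, 3))        # 0.4 * 0.5 * 10
  expect_equal(out[3, ], rep(10, 3))       # inhibitory row untouched
})

test_that("inhibitory weights keep their sign and, bar decay, their value", {
  cfg <- lsa_config("selective_learning", duration_ms = 3000,
                    decay_scope = "plastic")
  run <- simulate_training(cfg, seed = 2)
  net <- run$network
  inh <- which(net$neurons$type == "inhibitory")
  # inhibitory output weights bit-identical to their initial values
  expect_identical(run$w_final[inh, ], net$weights[inh, ])
  # excitatory -> inhibitory weights are non-plastic too
  exc <- which(net$neurons$type == "excitatory")
  expect_identical(run$w_final[exc, inh], net$weights[exc, inh])
  expect_true(all(run$w_final[inh, ] <= 0))
  expect_true(all(run$w_final[exc, ] >= 0))

  # with decay applied to all weights they scale by the closed-form power
  cfg2 <- lsa_config("selective_learning", duration_ms = 3000,
                     decay_scope = "all")
  run2 <- simulate_training(cfg2, seed = 2)
  expect_equal(run2$w_final[inh, ],
               run2$network$weights[inh, ] * (1 - 5e-7)^3000,
               tolerance = 1e-12)
})

test_that("short-term plasticity suppresses network-wide bursts", {
  frac_bursting <- function(stp_on, seed) {
    cfg <- lsa_config("stp_selective", stp_enabled = stp_on,
                      stimulus_enabled = FALSE, forbid_direct_io = FALSE,
                      duration_ms = 15000)
    run <- simulate_training(cfg, seed = seed, record_raster = TRUE)
    per_ms <- tabulate(run$raster$time_ms + 1L, nbins = 15000)
    mean(per_ms > 50)
  }
  on <- sapply(1:3, function(s) frac_bursting(TRUE, s))
  off <- sapply(1:3, function(s) frac_bursting(FALSE, s))
  expect_true(all(on < off))
})
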