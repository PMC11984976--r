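test_that("activation amplitudes follow the stated formula on a toy config", {
  # 2-channel toy config with every gain written out by hand
  A <- matrix(c(1, 2,
                3, 4,
                5, 6,
                7, 8), nrow = 4, byrow = TRUE)
  P <- matrix(0.5, 4, 2)
  cfg <- sim_config(n_channels = 2, emg_base_amplitude = A,
                    fmg_gesture_pattern = P, load_gain_slope = 1e-3,
                    kappa_pos = 0.2, kappa_load = 0.1, fmg_baseline = 0.1)
  act <- compute_activation("pulp_pinch", 500L, 4L, cfg)
  # hand evaluation: d_pos(4, c) = (2/6) sin(2 pi (c-1)/2 + 3 pi/3 + pi/6),
  # d_load(500, c) = 0.5 sin(2 pi (c-1)/2 + pi/2 + pi/6)
  d_pos <- (2 / 6) * sin(2 * pi * (0:1) / 2 + pi + pi / 6)
  d_load <- 0.5 * sin(2 * pi * (0:1) / 2 + pi / 2 + pi / 6)
  pert <- 1 + 0.2 * d_pos + 0.1 * d_load
  expect_equal(act$emg_gains, c(3, 4) * (1 + 1e-3 * 500) * pert)
  expect_equal(act$fmg_targets,
               pmax(0, 0.1 + 0.5 * (1 + 1e-3 * 500) * pert))
  expect_error(compute_activation("fist", 0L, 1L, cfg), "gesture")
})

test_that("disabling the effect magnitudes makes positions interchangeable", {
  cfg <- quiet_config()
  a2 <- compute_activation("power", 250L, 2L, cfg)
  a7 <- compute_activation("power", 250L, 7L, cfg)
  expect_identical(a2, a7)
})

test_that("EMG gains increase monotonically with load when slope > 0", {
  cfg <- sim_config(kappa_load = 0, load_gain_slope = 5e-4)
  g0 <- compute_activation("key", 0L, 3L, cfg)$emg_gains
  g1000 <- compute_activation("key", 1000L, 3L, cfg)$emg_gains
  expect_true(all(g1000 > g0))
})

test_that("perturbation tables are bounded and vanish at the neutral levels", {
  for (p in POSITIONS) expect_true(all(abs(position_perturbation(p)) <= 1))
  for (l in LOADS_G) expect_true(all(abs(load_perturbation(l)) <= 1))
  expect_equal(position_perturbation(2L), rep(0, 8))
  expect_equal(load_perturbation(0L), rep(0, 8))
})

test_that("simulation is bit-identical under a repeated seed", {
  sched <- filter_schedule(generate_schedule(1), loads_g = 0L, positions = 2L)
  a <- simulate_session(sched, sim_config(), "P01", 9, sample_rate_hz = 500)
  b <- simulate_session(sched, sim_config(), "P01", 9, sample_rate_hz = 500)
  expect_identical(a, b)
  c <- simulate_session(sched, sim_config(), "P01", 10, sample_rate_hz = 500)
  expect_false(identical(a$emg, c$emg))
})

test_that("FMG stays non-negative and tracks its first-order lag exactly", {
  sched <- filter_schedule(generate_schedule(2), gestures = "power",
                           loads_g = 500L, positions = 4L)
  cfg <- quiet_config()
  fs <- 500
  rec <- simulate_session(sched, cfg, "P01", 0, sample_rate_hz = fs)
  expect_true(all(rec$fmg >= 0))
  tgt <- compute_activation("power", 500L, 4L, cfg)$fmg_targets
  tau <- cfg$fmg_rise_tau_s
  # closed form from baseline: p(t) = tgt + (p0 - tgt) e^(-t/tau)
  ev <- rec$events[1, ]
  i0 <- floor(ev$onset_s * fs) + 1L
  mid <- i0 + round(1.5 * fs)
  t_mid <- (mid - i0) / fs
  expected <- tgt + (cfg$fmg_baseline - tgt) * exp(-t_mid / tau)
  expect_equal(rec$fmg[, mid], expected, tolerance = 1e-8)
  # and the lag tolerance bound at the contraction midpoint
  expect_true(all(abs(rec$fmg[, mid] - tgt) <=
                    abs(cfg$fmg_baseline - tgt) * exp(-1.5 / tau) + 1e-9))
})

test_that("mid-contraction EMG amplitude grows with load (Monte Carlo)", {
  cfg <- sim_config(kappa_load = 0, kappa_pos = 0, trial_jitter_sd = 0,
                    load_gain_slope = 5e-4)
  sched <- filter_schedule(generate_schedule(4), gestures = "tripod",
                           loads_g = c(0L, 1000L), positions = 2L)
  # replicate the 2 x 3 trials ~10x by re-seeding the noise
  m0 <- m1 <- matrix(0, 10, 8)
  fs <- 500
  for (r in 1:10) {
    rec <- simulate_session(sched, cfg, "P01", 100 + r, sample_rate_hz = fs)
    mids <- lapply(seq_len(nrow(sched)), function(i) {
      i0 <- floor(sched$onset_s[i] * fs)
      rowMeans(abs(rec$emg[, (i0 + fs):(i0 + 2 * fs)]))
    })
    loads <- sched$load_g
    m0[r, ] <- rowMeans(do.call(cbind, mids[loads == 0]))
    m1[r, ] <- rowMeans(do.call(cbind, mids[loads == 1000]))
  }
  expect_true(all(colMeans(m1) > colMeans(m0)))
})

test_that("with effects off, positions are distributionally identical", {
  # MAV of windows from two positions, same gesture/load: a two-sample
  # t-test must not reject at alpha = 0.01 (n = 100+ windows per side)
  tbl <- small_feature_table(loads_g = 0L, positions = c(2L, 6L),
                             config = quiet_config(),
                             schedule_seed = 5, signal_seed = 6)
  tbl <- tbl[tbl$gesture == "key", ]
  p2 <- tbl$emg1_mav[tbl$position == 2]
  p6 <- tbl$emg1_mav[tbl$position == 6]
  expect_gte(length(p2), 100)
  expect_gt(t.test(p2, p6)$p.value, 0.01)
})

test_that("band-limited EMG carriers stay deterministic and unit-scaled", {
  skip_if_not_installed("signal")
  sched <- filter_schedule(generate_schedule(1), gestures = "power",
                           loads_g = 0L, positions = 2L)
  cfg <- sim_config(emg_band = c(20, 150), trial_jitter_sd = 0)
  a <- simulate_session(sched, cfg, "P01", 5, sample_rate_hz = 1000)
  b <- simulate_session(sched, cfg, "P01", 5, sample_rate_hz = 1000)
  expect_identical(a$emg, b$emg)
  expect_true(all(is.finite(a$emg)))
  # mid-contraction amplitude still reflects the envelope gains
  gains <- compute_activation("power", 0L, 2L, cfg)$emg_gains
  i0 <- floor(sched$onset_s[1] * 1000)
  mid_sd <- apply(a$emg[, (i0 + 1000):(i0 + 2000)], 1, sd)
  expect_equal(mid_sd, gains, tolerance = 0.15)
})

test_that("validation rejects malformed configs and empty schedules", {
  expect_error(sim_config(kappa_pos = 0.9, kappa_load = 0.4), "kappa")
  expect_error(sim_config(noise_sd_emg = -1), "noise_sd_emg")
  expect_error(sim_config(emg_base_amplitude = matrix(1, 2, 8)), "4 x 8")
  sched <- generate_schedule(0)[0, ]
  expect_error(simulate_session(sched, sim_config(), "P", 0), "empty")
})
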