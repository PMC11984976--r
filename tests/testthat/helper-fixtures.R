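# Shared fixtures. Heavy cohorts are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A noise-free, effect-free configuration: deterministic envelopes, FMG
# exactly follows its lag dynamics.
quiet_config <- function(...) {
  sim_config(kappa_pos = 0, kappa_load = 0, trial_jitter_sd = 0,
             noise_sd_fmg = 0, fmg_drift_slope = 0, ...)
}

# Reduced-design feature table: gestures x loads x positions as given.
small_feature_table <- function(loads_g = c(0L, 1000L), positions = c(2L, 5L),
                                config = sim_config(), schedule_seed = 7,
                                signal_seed = 11, participant_id = "P01",
                                sample_rate_hz = 1000) {
  sched <- filter_schedule(generate_schedule(schedule_seed),
                           loads_g = loads_g, positions = positions)
  rec <- simulate_session(sched, config, participant_id, signal_seed,
                          sample_rate_hz)
  featurize_session(rec)
}

# Full-grid cohort used by the direction-of-effect suite: 5 synthetic
# participants, all 160 conditions, default generator settings, 1 kHz.
cohort_tables <- function(n = 5) {
  cached(paste0("cohort", n), {
    tabs <- lapply(seq_len(n), function(k) {
      sched <- generate_schedule(100 + k)
      rec <- simulate_session(sched, sim_config(), sprintf("P%02d", k),
                              500 + k, sample_rate_hz = 1000)
      featurize_session(rec)
    })
    names(tabs) <- sprintf("P%02d", seq_len(n))
    tabs
  })
}

# A configuration where gesture information is split across modalities:
# EMG separates {key, pulp_pinch} from {power, tripod} only, FMG separates
# {key, power} from {pulp_pinch, tripod} only; only the stacked vector
# identifies all four gestures.
complementary_config <- function() {
  a1 <- 0.7 + 0.25 * cos(2 * pi * (0:7) / 8)
  a2 <- 0.7 + 0.25 * cos(2 * pi * (0:7) / 8 + pi)
  A <- rbind(key = a1, pulp_pinch = a1, power = a2, tripod = a2)
  q1 <- 0.5 + 0.18 * cos(2 * pi * (0:7) / 8 + pi / 2)
  q2 <- 0.5 + 0.18 * cos(2 * pi * (0:7) / 8 - pi / 2)
  P <- rbind(key = q1, pulp_pinch = q2, power = q1, tripod = q2)
  sim_config(emg_base_amplitude = A, fmg_gesture_pattern = P,
             kappa_pos = 0, kappa_load = 0)
}

# Tiny recording with known content for segmentation arithmetic tests.
ramp_recording <- function(n_samples = 12000, sample_rate_hz = 2000,
                           onset_s = 0, contraction_s = 3, rest_s = 3) {
  events <- data.frame(
    gesture = "key", load_g = 0L, position = 2L,
    condition = "key|0g|p2", repetition = 1L,
    onset_s = onset_s, offset_s = onset_s + contraction_s,
    rest_offset_s = onset_s + contraction_s + rest_s
  )
  ramp <- matrix(rep(seq_len(n_samples) - 1, each = 8), nrow = 8)
  structure(
    list(emg = ramp, fmg = ramp, sample_rate_hz = sample_rate_hz,
         events = events, participant_id = "PX", seed = 0L),
    class = "session_recording"
  )
}

# Well-separated Gaussian class fixture for classifier tests.
gaussian_fixture <- function(n_per_class = 30, k = 3, d = 2, sep = 6,
                             seed = 42) {
  set.seed(seed)
  mu <- matrix(rnorm(k * d), k, d) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(rnorm(n_per_class * d), n_per_class, d) + rep(mu[j, ],
                                                         each = n_per_class)
  }))
  y <- factor(rep(letters[seq_len(k)], each = n_per_class))
  list(x = x, y = y, mu = mu)
}
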