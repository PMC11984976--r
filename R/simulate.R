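#' Simulation configuration for synthetic EMG/FMG sessions
#'
#' Bundles every knob of the signal model. The EMG model is
#' amplitude-modulated Gaussian noise: channel `c` during a contraction of
#' condition (gesture g, load l, position p) is
#' `a_c(t) * w(t)` with `w` unit-variance noise and plateau amplitude
#'
#' `a_c = A[g, c] * (1 + s_c * l) * (1 + kappa_pos * d_pos(p, c) +
#'  kappa_load * d_load(l, c))`
#'
#' where `A` is the per-gesture channel pattern, `s_c` the per-channel load
#' gain per gram, and `d_pos`, `d_load` fixed deterministic perturbation
#' tables in \[-1, 1\] (see [position_perturbation()]); the amplitude ramps
#' linearly over `envelope_ramp_s` at contraction onset/offset and never
#' drops below the rest noise floor `noise_sd_emg`. FMG channels follow a
#' first-order lag toward a per-condition target pressure during
#' contraction (time constant `fmg_rise_tau_s`) and back toward baseline
#' during rest (`fmg_decay_tau_s`; hysteresis when the two differ), plus
#' optional linear drift and additive noise, clipped at zero.
#'
#' @param n_channels Channels per modality (the armband has 8 of each).
#' @param emg_base_amplitude 4 x n_channels matrix of per-gesture EMG
#'   envelope gains (rows in canonical gesture order).
#' @param load_gain_slope Per-channel envelope multiplier per gram of added
#'   load (recycled to n_channels).
#' @param kappa_pos,kappa_load Magnitudes of the position and load
#'   channel-pattern perturbations (0 disables; their sum must stay below
#'   0.95 so envelope gains remain positive).
#' @param fmg_baseline Per-channel rest pressure (recycled).
#' @param fmg_gesture_pattern 4 x n_channels matrix of contact-pressure
#'   increments above baseline per gesture.
#' @param fmg_rise_tau_s,fmg_decay_tau_s First-order lag time constants (s).
#' @param fmg_drift_slope Linear drift in pressure units per second.
#' @param noise_sd_emg Rest-phase EMG noise SD (also the envelope floor).
#' @param noise_sd_fmg Additive FMG noise SD.
#' @param envelope_ramp_s EMG envelope rise/fall time at contraction
#'   onset/offset (s).
#' @param trial_jitter_sd SD of the per-trial, per-channel lognormal gain
#'   jitter `exp(N(0, sd))` applied to the EMG envelope and the FMG
#'   pressure increment, emulating trial-to-trial variation in contraction
#'   effort and sensor seating (0 disables).
#' @param emg_band Optional length-2 numeric band (Hz) to band-limit the EMG
#'   noise carrier with a 4th-order Butterworth filter; `NULL` keeps the
#'   white carrier.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(kappa_pos = 0, kappa_load = 0)
#' cfg$kappa_pos
sim_config <- function(n_channels = 8L,
                       emg_base_amplitude = default_emg_patterns(n_channels),
                       load_gain_slope = 5e-4,
                       kappa_pos = 0.55,
                       kappa_load = 0.18,
                       fmg_baseline = 0.1,
                       fmg_gesture_pattern = default_fmg_patterns(n_channels),
                       fmg_rise_tau_s = 0.15,
                       fmg_decay_tau_s = 0.25,
                       fmg_drift_slope = 0,
                       noise_sd_emg = 0.05,
                       noise_sd_fmg = 0.02,
                       envelope_ramp_s = 0.25,
                       trial_jitter_sd = 0.05,
                       emg_band = NULL) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stop("n_channels must be >= 1", call. = FALSE)
  cfg <- list(
    n_channels = n_channels,
    emg_base_amplitude = as_gesture_matrix(emg_base_amplitude, n_channels,
                                           "emg_base_amplitude"),
    load_gain_slope = rep_len(load_gain_slope, n_channels),
    kappa_pos = kappa_pos,
    kappa_load = kappa_load,
    fmg_baseline = rep_len(fmg_baseline, n_channels),
    fmg_gesture_pattern = as_gesture_matrix(fmg_gesture_pattern, n_channels,
                                            "fmg_gesture_pattern"),
    fmg_rise_tau_s = fmg_rise_tau_s,
    fmg_decay_tau_s = fmg_decay_tau_s,
    fmg_drift_slope = fmg_drift_slope,
    noise_sd_emg = noise_sd_emg,
    noise_sd_fmg = noise_sd_fmg,
    envelope_ramp_s = envelope_ramp_s,
    trial_jitter_sd = trial_jitter_sd,
    emg_band = emg_band
  )
  for (nm in c("kappa_pos", "kappa_load", "fmg_rise_tau_s", "fmg_decay_tau_s",
               "noise_sd_emg", "noise_sd_fmg", "envelope_ramp_s",
               "trial_jitter_sd")) {
    stopifnot_scalar_nonneg(cfg[[nm]], nm)
  }
  if (any(cfg$load_gain_slope < 0)) {
    stop("load_gain_slope must be non-negative", call. = FALSE)
  }
  if (cfg$kappa_pos + cfg$kappa_load >= 0.95) {
    stop("kappa_pos + kappa_load must be < 0.95 to keep gains positive",
         call. = FALSE)
  }
  if (any(cfg$fmg_baseline < 0) || any(cfg$fmg_gesture_pattern < 0) ||
      any(cfg$emg_base_amplitude < 0)) {
    stop("amplitude patterns and baselines must be non-negative",
         call. = FALSE)
  }
  if (!is.null(emg_band) &&
      (length(emg_band) != 2L || any(emg_band <= 0) ||
       emg_band[1] >= emg_band[2])) {
    stop("emg_band must be NULL or an increasing positive pair of Hz",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

as_gesture_matrix <- function(m, n_channels, name) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(length(GESTURES), n_channels))) {
    stop(name, " must be a ", length(GESTURES), " x ", n_channels,
         " matrix (gestures x channels)", call. = FALSE)
  }
  rownames(m) <- GESTURES
  m
}

#' Default per-gesture channel patterns
#'
#' Smooth, phase-shifted cosine profiles across the circular channel array:
#' each gesture activates a different subset of forearm channels, giving
#' linearly separable per-gesture envelope patterns with overlap between
#' neighbouring phases.
#'
#' @param n_channels Channels per modality.
#' @return 4 x n_channels matrix, rows in canonical gesture order.
#' @export
default_emg_patterns <- function(n_channels = 8L) {
  g <- seq_along(GESTURES) - 1
  c_ <- seq_len(n_channels) - 1
  m <- 0.7 + 0.25 * cos(outer(-g * pi / 2, 2 * pi * c_ / n_channels, "+"))
  rownames(m) <- GESTURES
  m
}

#' @rdname default_emg_patterns
#' @export
default_fmg_patterns <- function(n_channels = 8L) {
  g <- seq_along(GESTURES) - 1
  c_ <- seq_len(n_channels) - 1
  m <- 0.5 + 0.18 * cos(outer(-g * pi / 2 - pi / 4,
                              2 * pi * c_ / n_channels, "+"))
  rownames(m) <- GESTURES
  m
}

#' Deterministic channel-pattern perturbation tables
#'
#' Fixed, seed-independent tables in \[-1, 1\] that shape how limb position
#' and grasped load distort the per-channel activation pattern beyond the
#' monotone load gain. Both vanish at the neutral training condition
#' (position 2 and 0 g respectively) and grow with distance from it, so the
#' geometry of the "position effect" is reproducible across runs:
#'
#' * `d_pos(p, c) = ((p - 2)/6) * sin(2*pi*(c-1)/n + (p-1)*pi/3 + pi/6)`
#' * `d_load(l, c) = (l/1000) * sin(2*pi*(c-1)/n + pi*l/1000 + pi/6)`
#'
#' @param position Reaching position 1..8.
#' @param load_g Added load in grams.
#' @param n_channels Channels per modality.
#' @return Numeric vector of length `n_channels` in \[-1, 1\].
#' @export
position_perturbation <- function(position, n_channels = 8L) {
  c_ <- seq_len(n_channels) - 1
  ((position - 2) / 6) *
    sin(2 * pi * c_ / n_channels + (position - 1) * pi / 3 + pi / 6)
}

#' @rdname position_perturbation
#' @export
load_perturbation <- function(load_g, n_channels = 8L) {
  c_ <- seq_len(n_channels) - 1
  (load_g / 1000) * sin(2 * pi * c_ / n_channels + pi * load_g / 1000 + pi / 6)
}

#' Per-condition activation amplitudes
#'
#' Evaluates the deterministic part of the signal model for one condition:
#' the EMG plateau envelope gain and the FMG target pressure per channel
#' (see [sim_config()] for the formula).
#'
#' @param gesture,load_g,position The condition.
#' @param config A [sim_config()].
#' @return List with numeric vectors `emg_gains` and `fmg_targets`
#'   (length `n_channels`; FMG targets clipped at 0).
#' @export
compute_activation <- function(gesture, load_g, position, config) {
  validate_conditions(gesture, load_g, position)
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_channels
  pert <- 1 + config$kappa_pos * position_perturbation(position, n) +
    config$kappa_load * load_perturbation(load_g, n)
  load_gain <- 1 + config$load_gain_slope * load_g
  emg_gains <- config$emg_base_amplitude[gesture, ] * load_gain * pert
  fmg_targets <- pmax(
    0, config$fmg_baseline +
      config$fmg_gesture_pattern[gesture, ] * load_gain * pert
  )
  list(emg_gains = as.numeric(emg_gains),
       fmg_targets = as.numeric(fmg_targets))
}

#' Simulate one recording session
#'
#' Renders a schedule of grasp-and-hold trials into continuous 16-channel
#' (8 EMG + 8 FMG) time series at `sample_rate_hz`, following the signal
#' model documented in [sim_config()]. Regenerating with the same seed,
#' schedule and config is bit-identical.
#'
#' @param schedule A `trial_schedule` from [generate_schedule()] (possibly
#'   filtered to a subset of trials; timestamps are honoured as given).
#' @param config A [sim_config()].
#' @param participant_id Identifier stored with the recording.
#' @param seed Non-negative integer seed for the noise streams.
#' @param sample_rate_hz Sampling rate; the armband protocol uses 2000 Hz.
#' @return A `session_recording`: list with `emg` and `fmg`
#'   (n_channels x N matrices), `sample_rate_hz`, `events` (the schedule),
#'   `participant_id` and `seed`.
#' @export
simulate_session <- function(schedule, config = sim_config(),
                             participant_id = "P01", seed = 0,
                             sample_rate_hz = 2000) {
  validate_schedule(schedule)
  stopifnot(inherits(config, "sim_config"))
  stopifnot_scalar_nonneg(seed, "seed")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be > 0", call. = FALSE)
  fs <- sample_rate_hz
  nch <- config$n_channels
  n_samp <- ceiling(schedule_duration_s(schedule) * fs)

  # per-trial, per-channel effort/seating jitter (drawn first so the RNG
  # stream layout is stable: jitter, EMG carrier, FMG noise)
  rec <- with_seed(seed, {
  draw_jitter <- function() {
    if (config$trial_jitter_sd > 0) {
      matrix(exp(stats::rnorm(nch * nrow(schedule), 0,
                              config$trial_jitter_sd)), nrow = nch)
    } else {
      matrix(1, nrow = nch, ncol = nrow(schedule))
    }
  }
  jitter_emg <- draw_jitter()   # muscles and sensors jitter independently
  jitter_fmg <- draw_jitter()

  # per-channel amplitude envelope and noise-free FMG pressure trace
  amp <- matrix(config$noise_sd_emg, nrow = nch, ncol = n_samp)
  fmg <- matrix(0, nrow = nch, ncol = n_samp)
  p_state <- config$fmg_baseline
  prev_end <- 0L
  for (i in seq_len(nrow(schedule))) {
    ev <- schedule[i, ]
    act <- compute_activation(ev$gesture, ev$load_g, ev$position, config)
    act$emg_gains <- act$emg_gains * jitter_emg[, i]
    act$fmg_targets <- pmax(
      0, config$fmg_baseline +
        (act$fmg_targets - config$fmg_baseline) * jitter_fmg[, i]
    )
    i0 <- floor(ev$onset_s * fs) + 1L
    i1 <- floor(ev$offset_s * fs)
    i2 <- min(floor(ev$rest_offset_s * fs), n_samp)
    if (i2 > n_samp || i0 < 1L) {
      stop("event ", i, " lies outside the recording", call. = FALSE)
    }
    if (i0 > prev_end + 1L) {
      # gap before this event: FMG decays toward baseline, EMG stays at floor
      t_gap <- (seq_len(i0 - 1L - prev_end)) / fs
      fmg[, (prev_end + 1L):(i0 - 1L)] <-
        config$fmg_baseline +
        outer(p_state - config$fmg_baseline, exp(-t_gap / config$fmg_decay_tau_s))
      p_state <- fmg[, i0 - 1L]
    }
    # contraction: ramped envelope, FMG rises toward target
    t_rel <- (seq.int(i0, i1) - i0) / fs
    dur <- ev$offset_s - ev$onset_s
    ramp <- if (config$envelope_ramp_s > 0) {
      pmax(0, pmin(1, t_rel / config$envelope_ramp_s,
                   (dur - t_rel) / config$envelope_ramp_s))
    } else {
      rep(1, length(t_rel))
    }
    amp[, i0:i1] <- pmax(outer(act$emg_gains, ramp), config$noise_sd_emg)
    fmg[, i0:i1] <- act$fmg_targets +
      outer(p_state - act$fmg_targets, exp(-t_rel / config$fmg_rise_tau_s))
    p_state <- fmg[, i1]
    # rest: FMG decays toward baseline
    if (i2 >= i1 + 1L) {
      t_rest <- (seq.int(i1 + 1L, i2) - i1) / fs
      fmg[, (i1 + 1L):i2] <- config$fmg_baseline +
        outer(p_state - config$fmg_baseline,
              exp(-t_rest / config$fmg_decay_tau_s))
      p_state <- fmg[, i2]
    }
    prev_end <- i2
  }
  if (prev_end < n_samp) {
    t_gap <- (seq_len(n_samp - prev_end)) / fs
    fmg[, (prev_end + 1L):n_samp] <- config$fmg_baseline +
      outer(p_state - config$fmg_baseline,
            exp(-t_gap / config$fmg_decay_tau_s))
  }
  if (config$fmg_drift_slope != 0) {
    fmg <- fmg + rep(config$fmg_drift_slope * (seq_len(n_samp) / fs),
                     each = nch)
  }

  carrier <- matrix(stats::rnorm(nch * n_samp), nrow = nch)
  if (!is.null(config$emg_band)) {
    carrier <- bandlimit_carrier(carrier, config$emg_band, fs)
  }
  emg <- amp * carrier
  fmg_noisy <- if (config$noise_sd_fmg > 0) {
    fmg + config$noise_sd_fmg * matrix(stats::rnorm(nch * n_samp), nrow = nch)
  } else {
    fmg
  }
  list(emg = emg, fmg = pmax(fmg_noisy, 0))
  })

  structure(
    list(emg = rec$emg, fmg = rec$fmg, sample_rate_hz = fs,
         events = schedule, participant_id = participant_id,
         seed = as.integer(seed)),
    class = "session_recording"
  )
}

# Band-limit a unit-variance white carrier with a 4th-order Butterworth
# band-pass, then restore unit variance per channel so the envelope keeps
# its meaning.
bandlimit_carrier <- function(carrier, band, fs) {
  if (!requireNamespace("signal", quietly = TRUE)) {
    stop("band-limited EMG carriers need the 'signal' package", call. = FALSE)
  }
  ny <- fs / 2
  bf <- signal::butter(4, pmin(band / ny, 0.999), type = "pass")
  t(apply(carrier, 1, function(x) {
    y <- signal::filtfilt(bf, x)
    y / stats::sd(y)
  }))
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> participant %s: %d+%d channels x %d samples @ %g Hz, %d events (seed %d)\n",
    x$participant_id, nrow(x$emg), nrow(x$fmg), ncol(x$emg),
    x$sample_rate_hz, nrow(x$events), x$seed
  ))
  invisible(x)
}
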