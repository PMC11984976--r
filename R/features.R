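#' Time-domain feature primitives
#'
#' The Hudgins-style time-domain set computed per channel per window:
#' mean absolute value (MAV), waveform length (WL), zero crossings (ZC),
#' slope sign changes (SSC) and root mean square (RMS). ZC and SSC take an
#' optional amplitude deadband that suppresses counts driven by the noise
#' floor; the textbook zero-threshold definitions are the defaults.
#'
#' @param x Numeric vector, one channel of one window.
#' @param eps Non-negative amplitude deadband.
#' @return A scalar feature value.
#' @name td-features
NULL

#' @rdname td-features
#' @export
mav <- function(x) {
  if (length(x) == 0L) stop("mav: empty window", call. = FALSE)
  mean(abs(x))
}

#' @rdname td-features
#' @export
rms <- function(x) {
  if (length(x) == 0L) stop("rms: empty window", call. = FALSE)
  sqrt(mean(x^2))
}

#' @rdname td-features
#' @export
waveform_length <- function(x) {
  if (length(x) < 2L) stop("waveform_length: need >= 2 samples", call. = FALSE)
  sum(abs(diff(x)))
}

#' @rdname td-features
#' @export
zero_crossings <- function(x, eps = 0) {
  if (length(x) < 2L) stop("zero_crossings: need >= 2 samples", call. = FALSE)
  stopifnot_scalar_nonneg(eps, "eps")
  a <- x[-length(x)]
  b <- x[-1L]
  # strict sign opposition (exact zeros are sign-neutral) plus deadband
  sum(a * b < 0 & abs(b - a) >= eps)
}

#' @rdname td-features
#' @export
slope_sign_changes <- function(x, eps = 0) {
  if (length(x) < 3L) stop("slope_sign_changes: need >= 3 samples",
                           call. = FALSE)
  stopifnot_scalar_nonneg(eps, "eps")
  n <- length(x)
  d1 <- x[2:(n - 1L)] - x[1:(n - 2L)]
  d2 <- x[2:(n - 1L)] - x[3:n]
  sum(d1 * d2 > 0 & pmax(abs(d1), abs(d2)) >= eps)
}

#' Feature-extraction parameters
#'
#' @param zc_threshold,ssc_threshold Amplitude deadbands for the zero
#'   crossing and slope sign change counts. Defaults are 0 (the textbook
#'   definitions); a small positive value such as 1% of the rest-noise SD
#'   suppresses noise-floor counting.
#' @return A validated list of class `feat_params`.
#' @export
feat_params <- function(zc_threshold = 0, ssc_threshold = 0) {
  stopifnot_scalar_nonneg(zc_threshold, "zc_threshold")
  stopifnot_scalar_nonneg(ssc_threshold, "ssc_threshold")
  structure(list(zc_threshold = zc_threshold, ssc_threshold = ssc_threshold),
            class = "feat_params")
}

EMG_FEATURES <- c("mav", "wl", "zc", "ssc", "rms")

#' Feature column names by modality
#'
#' Ordering is channel-major, then feature in the fixed order
#' (MAV, WL, ZC, SSC, RMS) for EMG; FMG contributes one MAV per channel;
#' the stacked vector is the EMG block followed by the FMG block.
#'
#' @param modality One of `"emg"`, `"fmg"`, `"emg_fmg"`.
#' @param n_channels Channels per modality.
#' @return Character vector of feature names (40 / 8 / 48 for 8 channels).
#' @export
feature_names <- function(modality = c("emg", "fmg", "emg_fmg"),
                          n_channels = 8L) {
  modality <- match.arg(modality)
  emg_cols <- as.vector(t(outer(seq_len(n_channels), EMG_FEATURES,
                                function(c_, f) sprintf("emg%d_%s", c_, f))))
  fmg_cols <- sprintf("fmg%d_mav", seq_len(n_channels))
  switch(modality,
         emg = emg_cols,
         fmg = fmg_cols,
         emg_fmg = c(emg_cols, fmg_cols))
}

# Vectorised Hudgins set over the columns of a W x n matrix.
hudgins_block <- function(X, zc_eps, ssc_eps) {
  w <- nrow(X)
  d <- X[-1L, , drop = FALSE] - X[-w, , drop = FALSE]
  cross <- X[-w, , drop = FALSE] * X[-1L, , drop = FALSE] < 0 &
    abs(d) >= zc_eps
  d1 <- X[2:(w - 1L), , drop = FALSE] - X[1:(w - 2L), , drop = FALSE]
  d2 <- X[2:(w - 1L), , drop = FALSE] - X[3:w, , drop = FALSE]
  ssc <- d1 * d2 > 0 & pmax(abs(d1), abs(d2)) >= ssc_eps
  cbind(mav = colMeans(abs(X)),
        wl = colSums(abs(d)),
        zc = colSums(cross),
        ssc = colSums(ssc),
        rms = sqrt(colMeans(X^2)))
}

#' Extract the feature vector of one window
#'
#' @param window A `signal_window` from [slide_windows()].
#' @param modality `"emg"` (Hudgins set, 5 features x channels), `"fmg"`
#'   (MAV per channel) or `"emg_fmg"` (stacked concatenation, EMG block
#'   first).
#' @param params A [feat_params()].
#' @return Named numeric vector (length 40 / 8 / 48 at 8 channels) with the
#'   window's provenance in attributes `gesture`, `load_g`, `position`,
#'   `repetition`, `participant_id` and `modality`.
#' @export
extract_features <- function(window, modality = c("emg", "fmg", "emg_fmg"),
                             params = feat_params()) {
  modality <- match.arg(modality)
  stopifnot(inherits(window, "signal_window"))
  emg_vec <- function() {
    blk <- hudgins_block(t(window$emg), params$zc_threshold,
                         params$ssc_threshold)
    v <- as.vector(t(blk))     # channel-major, feature order within channel
    names(v) <- feature_names("emg", nrow(window$emg))
    v
  }
  fmg_vec <- function() {
    v <- apply(window$fmg, 1, mav)
    names(v) <- feature_names("fmg", nrow(window$fmg))
    v
  }
  v <- switch(modality,
              emg = emg_vec(),
              fmg = fmg_vec(),
              emg_fmg = c(emg_vec(), fmg_vec()))
  structure(v, gesture = window$gesture, load_g = window$load_g,
            position = window$position, repetition = window$repetition,
            participant_id = window$participant_id, modality = modality)
}

#' Feature table for a whole session
#'
#' Runs segmentation and feature extraction over every event of a
#' recording and returns one tidy row per window with all 48 stacked
#' feature columns; single-modality feature matrices are column subsets
#' (see [feature_names()]).
#'
#' @param recording A `session_recording`.
#' @param seg A [seg_params()].
#' @param feat A [feat_params()].
#' @return A data.frame with provenance columns `participant_id`,
#'   `gesture`, `load_g`, `position`, `condition`, `repetition`,
#'   `window_index`, then the 48 feature columns.
#' @export
featurize_session <- function(recording, seg = seg_params(),
                              feat = feat_params()) {
  stopifnot(inherits(recording, "session_recording"))
  events <- recording$events
  fs <- recording$sample_rate_hz
  w <- seg$window_ms * fs / 1000
  s <- seg$step_ms * fs / 1000
  if (w != round(w) || s != round(s)) {
    stop("window_ms/step_ms must be whole samples at ", fs, " Hz",
         call. = FALSE)
  }
  nch <- nrow(recording$emg)
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    segm <- extract_contraction(recording, events[i, ], seg)
    starts <- window_starts(ncol(segm$emg), as.integer(w), as.integer(s))
    idx <- outer(seq_len(w) - 1L, starts, "+")       # W x n_win sample index
    emg_feat <- matrix(0, length(starts), nch * length(EMG_FEATURES))
    fmg_feat <- matrix(0, length(starts), nch)
    for (c_ in seq_len(nch)) {
      Xe <- matrix(segm$emg[c_, ][idx], nrow = w)
      emg_feat[, (c_ - 1L) * 5L + 1:5] <-
        hudgins_block(Xe, feat$zc_threshold, feat$ssc_threshold)
      Xf <- matrix(segm$fmg[c_, ][idx], nrow = w)
      fmg_feat[, c_] <- colMeans(abs(Xf))
    }
    vals <- cbind(emg_feat, fmg_feat)
    colnames(vals) <- feature_names("emg_fmg", nch)
    rows[[i]] <- cbind(
      data.frame(participant_id = recording$participant_id,
                 gesture = segm$gesture, load_g = segm$load_g,
                 position = segm$position, condition = segm$condition,
                 repetition = segm$repetition,
                 window_index = seq_along(starts),
                 stringsAsFactors = FALSE),
      as.data.frame(vals)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
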