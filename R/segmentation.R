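#' Segmentation parameters
#'
#' @param keep_fraction Fraction of each contraction retained, centred on
#'   the contraction midpoint (0.70 keeps 35% either side of the middle of
#'   the 3 s hold, i.e. 2.1 s, avoiding transition states near grasp onset
#'   and release).
#' @param window_ms Sliding analysis window length in milliseconds.
#' @param step_ms Window increment in milliseconds.
#' @return A validated list of class `seg_params`.
#' @export
#' @examples
#' seg_params()        # 70% keep, 200 ms windows, 50 ms step
seg_params <- function(keep_fraction = 0.70, window_ms = 200, step_ms = 50) {
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1L ||
      keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be in (0, 1]", call. = FALSE)
  }
  if (!(window_ms >= step_ms && step_ms > 0)) {
    stop("need window_ms >= step_ms > 0", call. = FALSE)
  }
  structure(list(keep_fraction = keep_fraction, window_ms = window_ms,
                 step_ms = step_ms),
            class = "seg_params")
}

#' Extract the central portion of one contraction
#'
#' Finds the midpoint of the event's contraction phase and keeps
#' `keep_fraction` of the samples centred on it (half the discarded samples
#' on each side). Timestamps are half-open `[onset, offset)` seconds;
#' sample index of a timestamp t is `floor(t * rate)` (0-based).
#'
#' @param recording A `session_recording`.
#' @param event One row of the recording's `events` table.
#' @param params A [seg_params()].
#' @return A `contraction_segment`: list with `emg`/`fmg`
#'   (n_channels x M matrices, M = round(keep_fraction * duration * rate)),
#'   and the event's `gesture`, `load_g`, `position`, `condition`,
#'   `repetition` plus `participant_id`.
#' @export
extract_contraction <- function(recording, event, params = seg_params()) {
  stopifnot(inherits(recording, "session_recording"))
  fs <- recording$sample_rate_hz
  n_samp <- ncol(recording$emg)
  s0 <- floor(event$onset_s * fs)                      # 0-based
  n_contr <- round((event$offset_s - event$onset_s) * fs)
  if (s0 < 0 || s0 + n_contr > n_samp) {
    stop("event [", event$onset_s, ", ", event$offset_s,
         ") s lies outside the recording (", n_samp, " samples @ ", fs,
         " Hz)", call. = FALSE)
  }
  # round-half-up so the retained span is stable across platforms
  m <- floor(params$keep_fraction * n_contr + 0.5)
  lead <- floor((n_contr - m) / 2 + 0.5)
  idx <- (s0 + lead + 1L):(s0 + lead + m)              # back to 1-based
  structure(
    list(emg = recording$emg[, idx, drop = FALSE],
         fmg = recording$fmg[, idx, drop = FALSE],
         gesture = event$gesture, load_g = event$load_g,
         position = event$position,
         condition = condition_label(event$gesture, event$load_g,
                                     event$position),
         repetition = event$repetition,
         participant_id = recording$participant_id,
         sample_rate_hz = fs),
    class = "contraction_segment"
  )
}

#' Window start indices for a sliding window
#'
#' @param n_samples Segment length in samples.
#' @param window_samples,step_samples Window and step in samples.
#' @return Integer vector of 1-based start indices,
#'   `floor((n - w)/s) + 1` of them.
#' @keywords internal
window_starts <- function(n_samples, window_samples, step_samples) {
  if (n_samples < window_samples) {
    stop("segment of ", n_samples, " samples is shorter than one window (",
         window_samples, " samples)", call. = FALSE)
  }
  n_win <- floor((n_samples - window_samples) / step_samples) + 1L
  seq.int(1L, by = step_samples, length.out = n_win)
}

#' Cut sliding windows from a contraction segment
#'
#' Windows are cut within each repetition's segment separately, so no
#' window ever spans a repetition boundary and every window carries an
#' unambiguous repetition label for leave-one-repetition-out
#' cross-validation. At 2000 Hz the defaults give 400-sample windows with
#' a 100-sample step: a 2.1 s segment yields 39 windows.
#'
#' @param segment A `contraction_segment`.
#' @param params A [seg_params()]; `window_ms` and `step_ms` must convert
#'   to whole numbers of samples at the segment's rate.
#' @return List of `signal_window` objects, each with `emg`/`fmg`
#'   (n_channels x W), the segment's labels and a 1-based `window_index`.
#' @export
slide_windows <- function(segment, params = seg_params()) {
  stopifnot(inherits(segment, "contraction_segment"))
  fs <- segment$sample_rate_hz
  w <- params$window_ms * fs / 1000
  s <- params$step_ms * fs / 1000
  if (w != round(w) || s != round(s)) {
    stop("window_ms/step_ms must be whole samples at ", fs, " Hz",
         call. = FALSE)
  }
  starts <- window_starts(ncol(segment$emg), as.integer(w), as.integer(s))
  lapply(seq_along(starts), function(k) {
    idx <- starts[k]:(starts[k] + w - 1L)
    structure(
      list(emg = segment$emg[, idx, drop = FALSE],
           fmg = segment$fmg[, idx, drop = FALSE],
           gesture = segment$gesture, load_g = segment$load_g,
           position = segment$position, condition = segment$condition,
           repetition = segment$repetition,
           participant_id = segment$participant_id,
           window_index = k),
      class = "signal_window"
    )
  })
}
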