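#' Generate a randomized trial schedule
#'
#' Builds the 480-trial session schedule: every combination of hand grasp,
#' added load and reaching position appears exactly three times, with the
#' three repetitions of a condition performed consecutively (the
#' manipulandum stays put while a grasp is repeated). The nesting order of
#' the protocol is preserved — grasps form the outermost blocks, loads the
#' middle blocks and positions the innermost — and the order of levels at
#' every nesting depth is permuted by the seeded generator, emulating the
#' randomized block order used to spread fatigue evenly over conditions.
#'
#' Each trial is 3 s of contraction followed by 3 s of rest; timestamps tile
#' the session contiguously from 0 s.
#'
#' @param seed Non-negative integer seed for the block-order permutation.
#' @param contraction_s,rest_s Durations of the contraction and rest phases
#'   in seconds.
#' @return A `trial_schedule` data.frame with 480 rows and columns
#'   `gesture`, `load_g`, `position`, `condition`, `repetition`,
#'   `onset_s` (contraction onset), `offset_s` (contraction offset) and
#'   `rest_offset_s`.
#' @export
#' @examples
#' sched <- generate_schedule(seed = 0)
#' nrow(sched)        # 480
#' table(sched$gesture)
generate_schedule <- function(seed, contraction_s = 3, rest_s = 3) {
  stopifnot_scalar_nonneg(seed, "seed")
  blocks <- with_seed(seed, {
    out <- vector("list", length(GESTURES) * length(LOADS_G))
    i <- 0L
    for (g in sample(GESTURES)) {
      for (l in sample(LOADS_G)) {
        i <- i + 1L
        out[[i]] <- data.frame(
          gesture = g, load_g = l, position = sample(POSITIONS),
          stringsAsFactors = FALSE
        )
      }
    }
    out
  })
  sched <- do.call(rbind, blocks)
  # three consecutive repetitions of each scheduled condition
  sched <- sched[rep(seq_len(nrow(sched)), each = N_REPETITIONS), ]
  sched$repetition <- rep_len(seq_len(N_REPETITIONS), nrow(sched))
  trial_s <- contraction_s + rest_s
  sched$condition <- condition_label(sched$gesture, sched$load_g,
                                     sched$position)
  sched$onset_s <- (seq_len(nrow(sched)) - 1) * trial_s
  sched$offset_s <- sched$onset_s + contraction_s
  sched$rest_offset_s <- sched$offset_s + rest_s
  rownames(sched) <- NULL
  sched <- sched[, c("gesture", "load_g", "position", "condition",
                     "repetition", "onset_s", "offset_s", "rest_offset_s")]
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' Restrict a schedule to a subset of conditions
#'
#' Keeps the trials matching the requested levels and re-tiles their
#' timestamps contiguously from 0 s, preserving the original trial order
#' and phase durations. Useful for simulating reduced designs (e.g. only
#' the extreme conditions) without rendering the full 48-minute session.
#'
#' @param schedule A `trial_schedule`.
#' @param gestures,loads_g,positions Levels to keep (default: all).
#' @return A re-timed `trial_schedule`.
#' @export
filter_schedule <- function(schedule, gestures = GESTURES,
                            loads_g = LOADS_G, positions = POSITIONS) {
  keep <- schedule$gesture %in% gestures &
    schedule$load_g %in% loads_g & schedule$position %in% positions
  sub <- schedule[keep, , drop = FALSE]
  if (!nrow(sub)) stop("no trials left after filtering", call. = FALSE)
  contraction_s <- sub$offset_s - sub$onset_s
  rest_s <- sub$rest_offset_s - sub$offset_s
  sub$onset_s <- cumsum(c(0, (contraction_s + rest_s)[-nrow(sub)]))
  sub$offset_s <- sub$onset_s + contraction_s
  sub$rest_offset_s <- sub$offset_s + rest_s
  rownames(sub) <- NULL
  sub
}

#' Total duration of a schedule in seconds
#' @param schedule A `trial_schedule`.
#' @return Scalar seconds.
#' @export
schedule_duration_s <- function(schedule) {
  max(schedule$rest_offset_s)
}

validate_schedule <- function(schedule) {
  req <- c("gesture", "load_g", "position", "repetition",
           "onset_s", "offset_s", "rest_offset_s")
  miss <- setdiff(req, names(schedule))
  if (length(miss)) {
    stop("schedule is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(schedule) == 0L) stop("schedule is empty", call. = FALSE)
  validate_conditions(schedule$gesture, schedule$load_g, schedule$position)
  invisible(TRUE)
}
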