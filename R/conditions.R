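#' Experimental factor levels
#'
#' The grasp-and-hold protocol crosses four hand grasps, five added loads
#' (grams on top of a 53 g manipulandum) and eight reaching positions, each
#' repeated three times, for 4 x 5 x 8 x 3 = 480 trials per participant.
#'
#' @name condition-levels
#' @keywords internal
NULL

#' @rdname condition-levels
#' @export
GESTURES <- c("key", "pulp_pinch", "power", "tripod")

#' @rdname condition-levels
#' @export
LOADS_G <- c(0L, 250L, 500L, 750L, 1000L)

#' @rdname condition-levels
#' @export
POSITIONS <- 1:8

#' Mass of the unloaded manipulandum in grams (metadata only; load levels
#' refer to added weight).
#' @rdname condition-levels
#' @export
MANIPULANDUM_MASS_G <- 53

N_REPETITIONS <- 3L
N_CONDITIONS <- 160L

#' Canonical condition grid
#'
#' Returns the 160 experimental conditions in canonical order:
#' gesture-major (key, pulp_pinch, power, tripod), then load ascending,
#' then position 1..8. This ordering is used for the rows/columns of the
#' 160-class confusion matrix and for deterministic label ordering
#' everywhere else.
#'
#' @return A data.frame with columns `gesture`, `load_g`, `position` and
#'   `condition` (the canonical label string, e.g. `"key|0g|p2"`), 160 rows.
#' @export
#' @examples
#' head(condition_grid())
condition_grid <- function() {
  grid <- expand.grid(
    position = POSITIONS,
    load_g = LOADS_G,
    gesture = GESTURES,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )[, c("gesture", "load_g", "position")]
  grid$condition <- condition_label(grid$gesture, grid$load_g, grid$position)
  rownames(grid) <- NULL
  grid
}

#' Canonical condition label strings
#'
#' @param gesture character vector of gesture names.
#' @param load_g integer vector of added loads in grams.
#' @param position integer vector of reaching positions (1..8).
#' @return Character vector like `"power|500g|p7"`.
#' @export
condition_label <- function(gesture, load_g, position) {
  validate_conditions(gesture, load_g, position)
  sprintf("%s|%dg|p%d", gesture, as.integer(load_g), as.integer(position))
}

#' Canonical ordering of the 160 condition labels
#' @return Character vector of length 160.
#' @export
condition_levels <- function() condition_grid()$condition

validate_conditions <- function(gesture, load_g, position) {
  bad_g <- setdiff(unique(gesture), GESTURES)
  if (length(bad_g)) {
    stop("unknown gesture(s): ", paste(bad_g, collapse = ", "),
         " (expected one of ", paste(GESTURES, collapse = ", "), ")",
         call. = FALSE)
  }
  bad_l <- setdiff(unique(load_g), LOADS_G)
  if (length(bad_l)) {
    stop("unknown load_g value(s): ", paste(bad_l, collapse = ", "),
         " (expected one of ", paste(LOADS_G, collapse = ", "), ")",
         call. = FALSE)
  }
  bad_p <- setdiff(unique(position), POSITIONS)
  if (length(bad_p)) {
    stop("position out of range 1..8: ", paste(bad_p, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
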