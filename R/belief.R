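#' Belief state of the exploring cell
#'
#' The six conditioning variables of the decision models, plus the leading
#' edge position on each arm: the previous move direction, whether it was
#' rewarded, and per-arm success/failure counts `A_R, A_L, B_R, B_L`. Each
#' count includes one pseudo-observation, the Beta(1, 1) uniform prior on
#' the arm's food density, so `A` and `B` never drop below 1 and
#' `A + B - 2` equals the number of sites discovered on that arm.
#'
#' @param arm_length Number of sites per arm; `Inf` for a stationary bandit
#'   with no arm exhaustion.
#' @return A `belief_state` object: list with fields `last_move`
#'   (`"left"`, `"right"` or `NA`), `last_rewarded` (logical or `NA`),
#'   `A_R`, `A_L`, `B_R`, `B_L`, `pos_R`, `pos_L`, `arm_length`.
#' @examples
#' s <- init_state()
#' s$A_R / (s$A_R + s$B_R)  # posterior mean food density = 0.5
#' @export
init_state <- function(arm_length = Inf) {
  structure(
    list(last_move = NA_character_, last_rewarded = NA,
         A_R = 1, A_L = 1, B_R = 1, B_L = 1,
         pos_R = 0L, pos_L = 0L, arm_length = arm_length),
    class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf(
    "<belief_state> last=%s A_R=%g B_R=%g A_L=%g B_L=%g pos=(L %d, R %d)\n",
    ifelse(is.na(x$last_move), "none", x$last_move),
    x$A_R, x$B_R, x$A_L, x$B_L, x$pos_L, x$pos_R))
  invisible(x)
}

#' Consume the forced first site on both arms
#'
#' The first site of either arm always carries food so that exploration
#' starts on both arms; this registers those two observations: both leading
#' edges move to site 1 and both success counts gain one observation. The
#' previous-move variable stays unset (neither arm was "chosen").
#'
#' @param state A fresh [init_state()] (both positions 0).
#' @param treatment A [treatment()] supplying the arm length.
#' @return The updated `belief_state`.
#' @export
initialize_on_arena <- function(state, treatment) {
  if (state$pos_R != 0L || state$pos_L != 0L) {
    stop("state already initialized on an arena", call. = FALSE)
  }
  state$arm_length <- length(treatment$hq_arm)
  state$A_R <- state$A_R + 1
  state$A_L <- state$A_L + 1
  state$pos_R <- 1L
  state$pos_L <- 1L
  state
}

#' Record one move in the belief state
#'
#' Advances the moved arm's leading edge by one site and increments that
#' arm's success count (if the new site was rewarding) or failure count.
#'
#' @param state A `belief_state`.
#' @param move `"left"` or `"right"`.
#' @param rewarded Logical: did the new site carry food? With
#'   `graded = TRUE`, pass the reward magnitude via `reward` instead.
#' @param reward Optional reward magnitude (used when `graded = TRUE`;
#'   `rewarded` then defaults to `reward > 0`).
#' @param graded If `TRUE`, successes accumulate `reward / ref_magnitude`
#'   instead of 1, letting graded (non-binary) rewards weight the counts.
#' @param ref_magnitude Reference concentration for graded increments
#'   (default 0.05, the binary treatments' reward concentration).
#' @return The updated `belief_state`.
#' @export
update_state <- function(state, move, rewarded = NULL, reward = NULL,
                         graded = FALSE, ref_magnitude = 0.05) {
  move <- match.arg(move, c("left", "right"))
  if (is.null(rewarded)) {
    if (is.null(reward)) stop("supply `rewarded` or `reward`", call. = FALSE)
    rewarded <- reward > 0
  }
  inc <- if (graded && rewarded) (reward %||% ref_magnitude) / ref_magnitude else 1
  if (move == "right") {
    if (state$pos_R + 1L > state$arm_length) {
      stop("move past the end of the right arm", call. = FALSE)
    }
    state$pos_R <- state$pos_R + 1L
    if (rewarded) state$A_R <- state$A_R + inc else state$B_R <- state$B_R + 1
  } else {
    if (state$pos_L + 1L > state$arm_length) {
      stop("move past the end of the left arm", call. = FALSE)
    }
    state$pos_L <- state$pos_L + 1L
    if (rewarded) state$A_L <- state$A_L + inc else state$B_L <- state$B_L + 1
  }
  state$last_move <- move
  state$last_rewarded <- rewarded
  state
}
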