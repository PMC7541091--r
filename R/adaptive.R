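#' Configuration of a two-stage transformed up-down staircase
#'
#' The battery's staircases follow an n-down/1-up rule (difficulty increases
#' after `n_down` consecutive correct responses, decreases after one error)
#' with unequal step sizes: the easier-going ("up") step exceeds the
#' harder-going ("down") step by `up_down_ratio` in the adaptation domain.
#' On the exponential scale steps are multiplicative factors and the ratio is
#' applied in the log domain (up factor = down factor ^ ratio); on the linear
#' scale steps are additive (up = ratio * down). The first stage uses large
#' steps until `stage1_reversals` reversals, then the second stage uses steps
#' 1/5 the size (exponent 1/5 on the exponential scale) until
#' `stage2_reversals` further reversals, which ends the track.
#'
#' @param scale `"exponential"` (multiplicative steps) or `"linear"`.
#' @param start starting value of the adaptive parameter, in native units.
#' @param step1 stage-1 down step: multiplicative factor (> 1) on the
#'   exponential scale, additive amount on the linear scale.
#' @param step2 stage-2 down step; defaults to 1/5 of `step1` in the
#'   adaptation domain (`step1^(1/5)` or `step1 / 5`).
#' @param up_down_ratio up:down step-size ratio in the adaptation domain.
#' @param n_down number of consecutive correct responses required before a
#'   harder step.
#' @param stage1_reversals reversals ending stage 1.
#' @param stage2_reversals stage-2 reversals ending the track.
#' @param minimum,maximum bounds on the adaptive parameter (native units).
#' @param harder direction in which the task gets harder: `"smaller"` (gap,
#'   modulation depth) or `"larger"` (masker level).
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(scale = c("exponential", "linear"), start,
                             step1, step2 = NULL, up_down_ratio = 2,
                             n_down = 2, stage1_reversals = 3,
                             stage2_reversals = 6, minimum, maximum,
                             harder = c("smaller", "larger")) {
  scale <- match.arg(scale)
  harder <- match.arg(harder)
  if (up_down_ratio <= 0) stop("up:down ratio must be positive")
  if (scale == "exponential" && step1 <= 1) {
    stop("exponential-scale steps must be factors > 1")
  }
  if (scale == "linear" && step1 <= 0) stop("linear-scale steps must be > 0")
  if (is.null(step2)) {
    step2 <- if (scale == "exponential") step1^(1 / 5) else step1 / 5
  }
  if (!(minimum < start && start <= maximum)) {
    stop("bounds must satisfy minimum < start <= maximum")
  }
  structure(
    list(scale = scale, start = start, step1 = step1, step2 = step2,
         up_down_ratio = up_down_ratio, n_down = n_down,
         stage1_reversals = stage1_reversals,
         stage2_reversals = stage2_reversals,
         minimum = minimum, maximum = maximum, harder = harder),
    class = "staircase_config"
  )
}

#' Initialise a staircase track
#'
#' @param cfg a [staircase_config()].
#' @return an object of class `staircase_state` holding the current value,
#'   stage, consecutive-correct counter, reversal log, full trial history,
#'   and a `finished` flag.
#' @export
staircase_new <- function(cfg) {
  structure(
    list(cfg = cfg, value = cfg$start, stage = 1L, n_correct = 0L,
         last_direction = 0L,
         rev_stage = integer(), rev_value = numeric(),
         h_value = numeric(), h_correct = logical(), h_stage = integer(),
         h_reversal = logical(),
         value_changed = TRUE, finished = FALSE),
    class = "staircase_state"
  )
}

#' Reversal log of a staircase track
#'
#' @param state a `staircase_state`.
#' @return data frame with columns `stage` and `value` (the post-step
#'   parameter value at each reversal).
#' @export
staircase_reversals <- function(state) {
  data.frame(stage = state$rev_stage, value = state$rev_value)
}

#' Trial-by-trial history of a staircase track
#'
#' @param state a `staircase_state`.
#' @return data frame with columns `trial`, `value` (the value the trial
#'   was presented at), `correct`, `stage`, `reversal`.
#' @export
staircase_history <- function(state) {
  data.frame(trial = seq_along(state$h_value), value = state$h_value,
             correct = state$h_correct, stage = state$h_stage,
             reversal = state$h_reversal)
}

staircase_step_value <- function(cfg, value, stage, direction) {
  # direction: -1 harder, +1 easier; step sizes are "down" (harder) steps
  step <- if (stage == 1L) cfg$step1 else cfg$step2
  sgn <- if (cfg$harder == "smaller") direction else -direction
  new <- if (cfg$scale == "exponential") {
    f <- if (direction > 0) step^cfg$up_down_ratio else step
    if (sgn > 0) value * f else value / f
  } else {
    a <- if (direction > 0) step * cfg$up_down_ratio else step
    value + sgn * a
  }
  min(max(new, cfg$minimum), cfg$maximum)
}

#' Advance a staircase by one scored trial
#'
#' Applies the n-down/1-up transformed rule: after `n_down` consecutive
#' correct responses the parameter moves one down-step toward harder; after
#' any error it moves one (larger) up-step toward easier. A movement whose
#' direction differs from the previous movement logs a reversal carrying the
#' parameter value after that trial's step (the value the track turns back
#' from); the first movement is never a reversal. The third reversal
#' switches to stage 2 (the reversal itself is logged as stage 1 and its
#' step already uses the stage-2 size) and the sixth stage-2 reversal
#' finishes the track. Values are clamped to the configured bounds;
#' consecutive identical clamped values log at most one reversal.
#'
#' @param state a `staircase_state`.
#' @param correct logical; was the response correct?
#' @return the updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  if (state$finished) stop("cannot update a finished staircase")
  cfg <- state$cfg
  pre <- state$value
  stage_logged <- state$stage
  direction <- 0L
  if (isTRUE(correct)) {
    state$n_correct <- state$n_correct + 1L
    if (state$n_correct >= cfg$n_down) {
      direction <- -1L
      state$n_correct <- 0L
    }
  } else {
    direction <- 1L
    state$n_correct <- 0L
  }
  is_reversal <- FALSE
  if (direction != 0L) {
    flip <- state$last_direction != 0L && direction != state$last_direction
    if (flip && state$stage == 1L &&
        sum(state$rev_stage == 1L) + 1L >= cfg$stage1_reversals) {
      state$stage <- 2L
    }
    new_value <- staircase_step_value(cfg, pre, state$stage, direction)
    if (flip) {
      at_bound <- new_value <= cfg$minimum || new_value >= cfg$maximum
      dup <- !state$value_changed && length(state$rev_value) > 0 &&
        new_value == state$rev_value[length(state$rev_value)] && at_bound
      if (!dup) {
        is_reversal <- TRUE
        state$rev_stage <- c(state$rev_stage, stage_logged)
        state$rev_value <- c(state$rev_value, new_value)
        state$value_changed <- FALSE
        if (sum(state$rev_stage == 2L) >= cfg$stage2_reversals) {
          state$finished <- TRUE
        }
      } else {
        # un-switch a stage transition tied to a suppressed duplicate
        if (stage_logged == 1L) state$stage <- 1L
      }
    }
    if (new_value != pre) state$value_changed <- TRUE
    state$value <- new_value
    state$last_direction <- direction
  }
  state$h_value <- c(state$h_value, pre)
  state$h_correct <- c(state$h_correct, isTRUE(correct))
  state$h_stage <- c(state$h_stage, stage_logged)
  state$h_reversal <- c(state$h_reversal, is_reversal)
  state
}

#' Threshold estimate from a finished staircase
#'
#' The geometric mean of the stage-2 reversal values, in the native units of
#' the adaptive parameter (the single estimator used for every staircase
#' assessment, whatever its adaptation scale).
#'
#' @param state a finished `staircase_state`.
#' @return the threshold in native parameter units.
#' @export
staircase_threshold <- function(state) {
  if (!state$finished) stop("staircase has not finished")
  v <- state$rev_value[state$rev_stage == 2L]
  if (any(v <= 0)) stop("nonpositive reversal value; geometric mean undefined")
  exp(mean(log(v)))
}

#' Replay a response sequence through a fresh staircase
#'
#' @param cfg a [staircase_config()].
#' @param corrects logical vector of responses, in trial order.
#' @return the resulting `staircase_state`.
#' @export
staircase_replay <- function(cfg, corrects) {
  state <- staircase_new(cfg)
  for (k in corrects) state <- staircase_update(state, k)
  state
}

#' Asymptotic percent correct of an n-down/1-up staircase
#'
#' Drift-balance equilibrium of the transformed up-down rule with an up:down
#' step-size ratio `r`: the track is stationary where the expected step
#' displacement vanishes, at `p* = (r / (1 + r))^(1 / n_down)`. With equal
#' steps (`r = 1`) this reduces to the classic targets (70.7% for 2-down,
#' 79.4% for 3-down); unequal steps shift the target upward.
#'
#' @param n_down number of consecutive correct responses per down step.
#' @param ratio up:down step-size ratio in the adaptation domain.
#' @return the targeted percent correct (0-100).
#' @examples
#' convergence_target(2, 2)    # 81.65
#' convergence_target(2, 1.5)  # 77.46
#' convergence_target(3, 1)    # 79.37
#' @export
convergence_target <- function(n_down, ratio) {
  if (ratio <= 0) stop("step-size ratio must be positive")
  if (n_down < 1) stop("n_down must be at least 1")
  100 * (ratio / (1 + ratio))^(1 / n_down)
}

#' Fixed masker-level schedule for progressive tracking
#'
#' The speech-on-speech assessments use a fixed 20-trial progression: the
#' target stays at 65 dB SPL while the masker level rises from 55 to
#' 73 dB SPL in 2-dB steps every two trials, giving two responses at each of
#' ten target-to-masker ratios (TMR, +10 down to -8 dB).
#'
#' @param target_level target level in dB SPL.
#' @param masker_start,masker_end first and last masker levels in dB SPL.
#' @param step_db masker level increment in dB.
#' @param trials_per_level trials at each masker level.
#' @return a data frame with columns `trial`, `masker_level`, `tmr`.
#' @export
progressive_schedule <- function(target_level = 65, masker_start = 55,
                                 masker_end = 73, step_db = 2,
                                 trials_per_level = 2) {
  levels <- seq(masker_start, masker_end, by = step_db)
  masker <- rep(levels, each = trials_per_level)
  data.frame(trial = seq_along(masker), masker_level = masker,
             tmr = target_level - masker)
}

#' Score a progressive track
#'
#' The TMR threshold is 10 dB minus the number of correct responses, so an
#' all-incorrect session scores +10 dB and an all-correct session -10 dB.
#'
#' @param responses logical (or 0/1) vector of exactly 20 scored responses.
#' @return TMR threshold in dB.
#' @export
progressive_score <- function(responses) {
  if (length(responses) != 20) stop("exactly 20 scored responses are required")
  10 - sum(as.logical(responses))
}

#' Spatial release from masking
#'
#' The colocated-minus-separated TMR threshold difference, in dB: positive
#' values indicate a benefit from spatial separation of the maskers.
#'
#' @param colocated_thr,separated_thr TMR thresholds in dB, each within
#'   -10 to +10.
#' @return spatial release in dB (range -20 to +20).
#' @export
spatial_release <- function(colocated_thr, separated_thr) {
  if (abs(colocated_thr) > 10 || abs(separated_thr) > 10) {
    stop("progressive-track thresholds must lie in [-10, 10] dB")
  }
  colocated_thr - separated_thr
}
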