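#' The ten-assessment battery definitions
#'
#' Returns the default battery: two tone-in-noise tests (no-notch, notch),
#' three temporal-fine-structure tests (temporal gap, diotic FM, dichotic
#' FM), three modulation tests (TM, SM, STM) and two speech-on-speech tests
#' (colocated, separated). Each definition bundles the stimulus parameters,
#' the adaptive procedure with its published step sizes, bounds and starting
#' values, the native measurement units, and the block the assessment is run
#' in.
#'
#' @param up_down_ratio up:down step-size ratio for the staircase
#'   assessments (2 in the repeatability condition, 1.5 in the headphone and
#'   noise conditions).
#' @return a named list of `assessment_definition` objects, length 10.
#' @export
default_battery <- function(up_down_ratio = 2) {
  sc <- function(...) staircase_config(up_down_ratio = up_down_ratio, ...)
  defs <- list(
    no_notch = list(
      block = "tone_in_noise", units = "dB SPL (masker)", direction = -1,
      stimulus = list(notch = FALSE, n_components = 10000,
                      band = c(1200, 2800), duration_ms = 500,
                      target_freq = 2000, target_level = 45),
      procedure = sc(scale = "linear", start = 35, step1 = 6, step2 = 2,
                     minimum = 25, maximum = 90, harder = "larger")
    ),
    notch = list(
      block = "tone_in_noise", units = "dB SPL (masker)", direction = -1,
      stimulus = list(notch = TRUE, n_components = 10000,
                      bands = rbind(c(800, 1600), c(2400, 3200)),
                      duration_ms = 500, target_freq = 2000,
                      target_level = 45),
      procedure = sc(scale = "linear", start = 35, step1 = 6, step2 = 2,
                     minimum = 25, maximum = 90, harder = "larger")
    ),
    gap = list(
      block = "tfs", units = "ms", direction = 1,
      stimulus = list(burst_freq = 500, burst_dur_ms = 4, level = 80),
      procedure = sc(scale = "exponential", start = 20, step1 = 2^(1 / 2),
                     step2 = 2^(1 / 10), minimum = 0, maximum = 100)
    ),
    diotic_fm = list(
      block = "tfs", units = "Hz", direction = 1,
      stimulus = list(rate = 2, dichotic = FALSE, duration_ms = 400,
                      level = 75, carrier_range = c(460, 550)),
      procedure = sc(scale = "exponential", start = 6, step1 = 2^(1 / 2),
                     step2 = 2^(1 / 10), minimum = 0, maximum = 10000)
    ),
    dichotic_fm = list(
      block = "tfs", units = "Hz", direction = 1,
      stimulus = list(rate = 2, dichotic = TRUE, duration_ms = 400,
                      level = 75, carrier_range = c(460, 550)),
      procedure = sc(scale = "exponential", start = 3, step1 = 2^(1 / 2),
                     step2 = 2^(1 / 10), minimum = 0, maximum = 10000)
    ),
    tm = list(
      block = "stm", units = "M (dB)", direction = 1,
      stimulus = list(tm_rate = 4, sm_density = 0, band = c(400, 8000),
                      duration_ms = 500, level = 65),
      procedure = sc(scale = "linear", start = 6, step1 = 0.5, step2 = 0.1,
                     minimum = 0.2, maximum = 40)
    ),
    sm = list(
      block = "stm", units = "M (dB)", direction = 1,
      stimulus = list(tm_rate = 0, sm_density = 2, band = c(400, 8000),
                      duration_ms = 500, level = 65),
      procedure = sc(scale = "linear", start = 6, step1 = 0.5, step2 = 0.1,
                     minimum = 0.2, maximum = 40)
    ),
    stm = list(
      block = "stm", units = "M (dB)", direction = 1,
      stimulus = list(tm_rate = 4, sm_density = 2, band = c(400, 8000),
                      duration_ms = 500, level = 65, random_direction = TRUE),
      procedure = sc(scale = "linear", start = 6, step1 = 0.5, step2 = 0.1,
                     minimum = 0.2, maximum = 40)
    ),
    srm_colocated = list(
      block = "srm", units = "dB TMR", direction = 1,
      stimulus = list(separated = FALSE, target_level = 65),
      procedure = progressive_schedule()
    ),
    srm_separated = list(
      block = "srm", units = "dB TMR", direction = 1,
      stimulus = list(separated = TRUE, target_level = 65),
      procedure = progressive_schedule()
    )
  )
  defs <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    d$name <- nm
    d$n_practice <- 5L
    structure(d, class = "assessment_definition")
  })
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  defs
}

#' Screening task
#'
#' Ten two-cue 2AFC trials of a 2-kHz tone at 45 dB SPL; the screen is
#' passed with at least nine correct responses.
#'
#' @param observer a linear-domain [simulated_observer()] whose psychometric
#'   function is defined on tone level in dB SPL, or a function of the tone
#'   level returning a logical response.
#' @param level screening tone level in dB SPL.
#' @param n_trials number of screening trials.
#' @return a list with `passed` (logical) and `n_correct`.
#' @export
run_screening <- function(observer, level = 45, n_trials = 10) {
  answer <- if (is.function(observer)) observer else {
    function(x) respond(observer, x)
  }
  correct <- vapply(seq_len(n_trials), function(i) isTRUE(answer(level)),
                    logical(1))
  list(passed = sum(correct) >= n_trials - 1, n_correct = sum(correct))
}

practice_value <- function(def) {
  proc <- def$procedure
  if (inherits(proc, "staircase_config")) {
    v <- proc$start
    for (i in 1:4) v <- staircase_step_value(proc, v, 1L, +1L)
    # 4 stage-1 steps easier than the start, clamped to the bounds; note the
    # easier step includes the up:down ratio, keeping practice clearly easy
    v
  } else {
    max(proc$tmr)
  }
}

#' Run one full battery session on a set of simulated observers
#'
#' Runs the screening task, then the four testing blocks in order
#' (tone-in-noise, temporal fine structure, modulation, speech-on-speech),
#' with the assessment order inside each block shuffled per session. Each
#' assessment is preceded by five non-adaptive practice trials at an easy
#' parameter value. Thresholds are returned in native units; tracks that
#' fail to finish propagate as missing thresholds with a reason.
#'
#' @param observers named list of [simulated_observer()]s, one per
#'   assessment name in `battery`.
#' @param battery a battery from [default_battery()]; when `NULL` it is
#'   built with the step-size ratio implied by `condition` (2:1 for
#'   repeatability, 1.5:1 otherwise).
#' @param subject_id,session,condition session metadata; `condition` is one
#'   of `"repeatability"`, `"headphone"`, `"noise"`.
#' @param screening_observer observer for [run_screening()]; when `NULL` the
#'   screen is recorded as passed with 10/10 (an attentive listener at a
#'   clearly audible level).
#' @param require_screening error when the screen is failed.
#' @return an object of class `session_result`: subject/session metadata,
#'   screening outcome, named `thresholds` vector, `missing` reasons, and a
#'   long `trials` log (one row per practice and adaptive trial).
#' @export
run_battery <- function(observers, battery = NULL, subject_id = "s1",
                        session = 1L,
                        condition = c("repeatability", "headphone", "noise"),
                        screening_observer = NULL,
                        require_screening = TRUE) {
  condition <- match.arg(condition)
  if (is.null(battery)) {
    battery <- default_battery(
      up_down_ratio = if (condition == "repeatability") 2 else 1.5
    )
  }
  if (is.null(screening_observer)) {
    screening <- list(passed = TRUE, n_correct = 10L)
  } else {
    screening <- run_screening(screening_observer)
  }
  if (!screening$passed && require_screening) {
    stop(sprintf("screening failed (%d/10 correct)", screening$n_correct))
  }
  blocks <- c("tone_in_noise", "tfs", "stm", "srm")
  block_of <- vapply(battery, `[[`, character(1), "block")
  order <- unlist(lapply(blocks, function(b) {
    nms <- names(battery)[block_of == b]
    if (length(nms) > 1) sample(nms) else nms
  }))
  thresholds <- numeric(0)
  missing <- character(0)
  logs <- list()
  for (nm in order) {
    def <- battery[[nm]]
    obs <- observers[[nm]]
    if (is.null(obs)) stop(sprintf("no observer supplied for '%s'", nm))
    proc <- def$procedure
    pv <- practice_value(def)
    px <- if (inherits(proc, "staircase_config")) to_domain(pv, proc$scale) else pv
    practice <- vapply(seq_len(def$n_practice), function(i) respond(obs, px),
                       logical(1))
    logs[[length(logs) + 1]] <- data.frame(
      assessment = nm, phase = "practice", trial = seq_along(practice),
      value = pv, correct = practice, stage = NA_integer_, reversal = FALSE
    )
    res <- tryCatch(simulate_track(obs, proc), error = function(e) e)
    if (inherits(res, "error")) {
      missing[nm] <- conditionMessage(res)
      next
    }
    thresholds[nm] <- res$threshold
    h <- if (inherits(proc, "staircase_config")) {
      hh <- staircase_history(res$track)
      data.frame(assessment = nm, phase = "adaptive",
                 trial = hh$trial, value = hh$value, correct = hh$correct,
                 stage = hh$stage, reversal = hh$reversal)
    } else {
      data.frame(assessment = nm, phase = "adaptive",
                 trial = res$track$trial, value = res$track$tmr,
                 correct = res$track$correct, stage = NA_integer_,
                 reversal = FALSE)
    }
    logs[[length(logs) + 1]] <- h
  }
  trials <- do.call(rbind, logs)
  trials$target_position <- sample(2:3, nrow(trials), replace = TRUE)
  trials <- cbind(subject = subject_id, session = as.integer(session),
                  condition = condition, trials)
  structure(
    list(subject_id = subject_id, session = as.integer(session),
         condition = condition, passed_screening = screening$passed,
         screening_correct = screening$n_correct,
         thresholds = thresholds, missing = missing, trials = trials),
    class = "session_result"
  )
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result: %s, session %d, %s condition>\n",
              x$subject_id, x$session, x$condition))
  cat(sprintf("  screening: %s (%d/10)\n",
              if (x$passed_screening) "passed" else "failed",
              x$screening_correct))
  for (nm in names(x$thresholds)) {
    cat(sprintf("  %-14s %8.3f\n", nm, x$thresholds[nm]))
  }
  if (length(x$missing)) {
    cat("  missing:", paste(names(x$missing), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a session result to the long analysis format
#'
#' @param result a `session_result`.
#' @param battery the battery the session was run with (for units).
#' @return a data frame with columns `subject`, `session`, `condition`,
#'   `assessment`, `value`, `units`.
#' @export
session_to_long <- function(result, battery = default_battery()) {
  nms <- names(result$thresholds)
  data.frame(
    subject = result$subject_id, session = result$session,
    condition = result$condition, assessment = nms,
    value = unname(result$thresholds),
    units = vapply(battery[nms], `[[`, character(1), "units")
  )
}
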