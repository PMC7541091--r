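#' Parametric simulated listener
#'
#' A simulated observer answers two-cue 2AFC trials through a logistic
#' psychometric function defined on the track's adaptation domain: log2 of
#' the native parameter for exponential-scale tracks, the native (dB) value
#' for linear-scale tracks. The probability of a correct response is
#'
#'   `p(x) = gamma + (1 - gamma - lambda) * F(direction * (x - alpha) / beta)`
#'
#' with `F` the standard logistic, `gamma` the 2AFC guess rate, and `lambda`
#' the lapse rate. `direction` is +1 when larger parameter values are easier
#' (gap, modulation depth, TMR) and -1 when they are harder (masker level).
#'
#' @param alpha psychometric location (p = midpoint) in the adaptation domain.
#' @param beta slope parameter (same domain units); larger is shallower.
#' @param gamma guess rate (0.5 for 2AFC).
#' @param lambda lapse rate.
#' @param direction +1 or -1 (see above).
#' @param scale adaptation domain this observer lives on.
#' @return an object of class `simulated_observer`.
#' @export
simulated_observer <- function(alpha, beta, gamma = 0.5, lambda = 0.02,
                               direction = 1,
                               scale = c("exponential", "linear")) {
  scale <- match.arg(scale)
  if (beta <= 0) stop("beta must be positive")
  if (lambda < 0 || lambda >= 0.5) stop("lambda must lie in [0, 0.5)")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
         direction = direction, scale = scale),
    class = "simulated_observer"
  )
}

#' Probability of a correct response at a stimulus value
#'
#' @param obs a [simulated_observer()].
#' @param x stimulus value in the observer's adaptation domain.
#' @return probability of a correct response.
#' @export
percent_correct_at <- function(obs, x) {
  stopifnot(all(is.finite(x)))
  obs$gamma + (1 - obs$gamma - obs$lambda) *
    plogis(obs$direction * (x - obs$alpha) / obs$beta)
}

#' Stimulus value at which the observer reaches a given percent correct
#'
#' Analytic inversion of the psychometric function; used to locate the
#' staircase's convergence point for a known observer.
#'
#' @param obs a [simulated_observer()].
#' @param p_percent target percent correct (0-100).
#' @return the value in the adaptation domain.
#' @export
observer_point <- function(obs, p_percent) {
  q <- (p_percent / 100 - obs$gamma) / (1 - obs$gamma - obs$lambda)
  if (q <= 0 || q >= 1) stop("requested percent correct is unattainable")
  obs$alpha + obs$direction * obs$beta * qlogis(q)
}

#' Draw one Bernoulli response
#'
#' @param obs a [simulated_observer()].
#' @param x stimulus value in the adaptation domain.
#' @return logical; `TRUE` for a correct response. Uses R's global RNG, so
#'   sequences are reproducible under `set.seed()`.
#' @export
respond <- function(obs, x) {
  runif(1) < percent_correct_at(obs, x)
}

to_domain <- function(value, scale) {
  if (scale == "exponential") log2(value) else value
}

#' Run an adaptive or progressive track on a simulated observer
#'
#' For a [staircase_config()] procedure the observer answers trials until the
#' track finishes; the threshold is the geometric mean of the stage-2
#' reversals, in native units. For a progressive schedule (data frame from
#' [progressive_schedule()]) the observer answers the 20 fixed-TMR trials and
#' the threshold is the progressive score in dB.
#'
#' @param obs a [simulated_observer()].
#' @param procedure a [staircase_config()] or a [progressive_schedule()]
#'   data frame.
#' @param max_trials safety cap on staircase length.
#' @return a list with elements `threshold` (native units) and `track` (the
#'   finished `staircase_state`, or a data frame of progressive responses).
#' @export
simulate_track <- function(obs, procedure, max_trials = 1000) {
  if (inherits(procedure, "staircase_config")) {
    if (obs$scale != procedure$scale) {
      stop(sprintf("observer domain (%s) does not match procedure scale (%s)",
                   obs$scale, procedure$scale))
    }
    state <- staircase_new(procedure)
    for (i in seq_len(max_trials)) {
      x <- to_domain(state$value, procedure$scale)
      state <- staircase_update(state, respond(obs, x))
      if (state$finished) break
    }
    if (!state$finished) {
      stop("staircase did not finish within `max_trials` trials")
    }
    list(threshold = staircase_threshold(state), track = state)
  } else if (is.data.frame(procedure) && "tmr" %in% names(procedure)) {
    if (obs$scale != "linear") {
      stop("progressive tracks require a linear-domain observer")
    }
    correct <- vapply(procedure$tmr, function(v) respond(obs, v), logical(1))
    track <- cbind(procedure, correct = correct)
    list(threshold = progressive_score(correct), track = track)
  } else {
    stop("`procedure` must be a staircase_config or a progressive schedule")
  }
}
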