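#' Per-assessment presets for the synthetic cohort generator
#'
#' A table of generative parameters for each of the ten assessments, in
#' analysis units (log2 ms, log2 Hz, M dB, or TMR dB): the population mean
#' threshold, the between-subject SD, the within-subject session-to-session
#' SD, the systematic session-2 shift (negative = improvement for
#' threshold-type measures), a psychometric slope `beta` used when full
#' adaptive tracks are simulated, and the task's difficulty direction.
#' The values are presets shaped to resemble a young normal-hearing cohort;
#' they are a simulation default, not empirical ground truth, and every
#' column can be edited before being passed to [cohort_config()].
#'
#' @return a data frame with columns `assessment`, `scale`, `direction`,
#'   `mean`, `between_sd`, `within_sd`, `shift`, `beta`.
#' @export
cohort_presets <- function() {
  data.frame(
    assessment = c("gap", "diotic_fm", "dichotic_fm", "tm", "sm", "stm",
                   "no_notch", "notch", "srm_colocated", "srm_separated"),
    scale = c("exponential", "exponential", "exponential", "linear", "linear",
              "linear", "linear", "linear", "linear", "linear"),
    direction = c(1, 1, 1, 1, 1, 1, -1, -1, 1, 1),
    mean = c(1.30, 2.67, -0.97, 1.55, 1.61, 0.95,
             -11.43, -31.67, 2.12, -3.91),
    between_sd = c(1.23, 0.55, 0.84, 0.60, 0.67, 0.26,
                   1.26, 2.18, 1.24, 2.53),
    within_sd = c(1.11, 0.60, 0.79, 0.58, 0.57, 0.43,
                  1.61, 2.67, 1.55, 2.02),
    shift = c(-0.12, -0.06, 0.01, -0.13, -0.16, 0.01,
              -0.83, -0.77, -0.36, -1.12),
    beta = c(0.5, 0.5, 0.5, 0.8, 0.8, 0.8, 2.0, 2.0, 2.0, 2.0),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic two-session cohort
#'
#' @param n_subjects number of simulated subjects.
#' @param presets per-assessment generative parameters, as returned (and
#'   optionally edited) from [cohort_presets()].
#' @param outlier_rate probability, per subject and assessment, of injecting
#'   an outlying session (alpha offset beyond 3 between-subject SDs in one
#'   randomly chosen session); within 0-0.1.
#' @param ability_correlation equicorrelation of subject abilities across
#'   assessments (a shared general-ability factor); 0 draws every
#'   assessment independently.
#' @param lapse observer lapse rate used when full tracks are simulated.
#' @param condition study condition label; selects the staircase step-size
#'   ratio in track-level simulation (2:1 for repeatability, 1.5:1
#'   otherwise).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 150, presets = cohort_presets(),
                          outlier_rate = 0, ability_correlation = 0.3,
                          lapse = 0.02,
                          condition = c("repeatability", "headphone",
                                        "noise")) {
  condition <- match.arg(condition)
  if (outlier_rate < 0 || outlier_rate > 0.1) {
    stop("outlier_rate must lie in [0, 0.1]")
  }
  if (ability_correlation < 0 || ability_correlation > 1) {
    stop("ability_correlation must lie in [0, 1]")
  }
  if (any(presets$between_sd < 0) || any(presets$within_sd < 0)) {
    stop("SDs must be non-negative")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), presets = presets,
         outlier_rate = outlier_rate,
         ability_correlation = ability_correlation, lapse = lapse,
         condition = condition),
    class = "cohort_config"
  )
}

#' Generate per-subject, per-session observer locations
#'
#' Subject-level thresholds are drawn as
#' `Normal(mean, between_sd)` per assessment; each session adds independent
#' `Normal(0, within_sd)` noise, and session 2 adds the systematic shift.
#' Outliers, when requested, displace one randomly chosen session by more
#' than 3 between-subject SDs.
#'
#' @param cfg a [cohort_config()].
#' @return a long data frame with columns `subject`, `assessment`,
#'   `session`, `alpha` (the session's true threshold location in analysis
#'   units), and `outlier`.
#' @export
generate_cohort <- function(cfg) {
  p <- cfg$presets
  rows <- list()
  rho <- cfg$ability_correlation
  general <- rnorm(cfg$n_subjects)   # shared-ability factor, unit variance
  for (i in seq_len(nrow(p))) {
    # lower analysis-unit values are better on every assessment, so the
    # shared factor enters with a common sign
    z <- sqrt(rho) * general + sqrt(1 - rho) * rnorm(cfg$n_subjects)
    subj_alpha <- p$mean[i] + p$between_sd[i] * z
    for (s in 1:2) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("s%03d", seq_len(cfg$n_subjects)),
        assessment = p$assessment[i], session = s,
        alpha = subj_alpha + rnorm(cfg$n_subjects, 0, p$within_sd[i]) +
          if (s == 2) p$shift[i] else 0,
        outlier = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (cfg$outlier_rate > 0) {
    for (i in seq_len(nrow(p))) {
      hit <- which(runif(cfg$n_subjects) < cfg$outlier_rate)
      for (j in hit) {
        s <- sample(1:2, 1)
        k <- out$assessment == p$assessment[i] &
          out$subject == sprintf("s%03d", j) & out$session == s
        off <- sample(c(-1, 1), 1) * (3.5 + abs(rnorm(1))) * p$between_sd[i]
        out$alpha[k] <- out$alpha[k] + off
        out$outlier[k] <- TRUE
      }
    }
  }
  out
}

analysis_to_native <- function(assessment, value) {
  tab <- analysis_unit_table()
  tr <- tab$transform[match(assessment, tab$assessment)]
  ifelse(tr == "log2", 2^value, ifelse(tr == "tmr", 45 - value, value))
}

# place a progressive-track observer's midpoint so its expected score
# equals the nominal TMR threshold
progressive_alpha_for <- function(threshold, beta, gamma, lambda,
                                  schedule = progressive_schedule()) {
  expected_score <- function(m) {
    obs <- simulated_observer(m, beta, gamma = gamma, lambda = lambda,
                              scale = "linear")
    10 - sum(percent_correct_at(obs, schedule$tmr))
  }
  lo <- min(schedule$tmr) - 10; hi <- max(schedule$tmr) + 10
  # expected_score is increasing in m; clamp to the attainable score range
  thr <- min(max(threshold, expected_score(lo) + 0.05),
             expected_score(hi) - 0.05)
  stats::uniroot(function(m) expected_score(m) - thr, c(lo, hi))$root
}

#' Simulate a complete two-session study
#'
#' Runs the generative cohort model through either of two measurement
#' models. `"direct"` reports each session's true threshold location as the
#' measured value, so measurement spread equals the configured
#' within-subject SD exactly - the mode used to validate the reliability
#' pipeline. `"tracks"` runs the full battery per subject and session with
#' simulated observers whose convergence points are placed at the session's
#' threshold location, adding realistic adaptive-track estimation noise.
#'
#' @param cfg a [cohort_config()].
#' @param mode `"direct"` or `"tracks"`.
#' @return a long data frame with columns `subject`, `session`,
#'   `condition`, `assessment`, `value` (native units) and `units`, ready
#'   for [to_analysis_units()] and [test_retest_report()].
#' @export
simulate_study <- function(cfg, mode = c("direct", "tracks")) {
  mode <- match.arg(mode)
  cohort <- generate_cohort(cfg)
  tab <- analysis_unit_table()
  units <- tab$units[match(cohort$assessment, tab$assessment)]
  if (mode == "direct") {
    out <- data.frame(
      subject = cohort$subject, session = cohort$session,
      condition = cfg$condition, assessment = cohort$assessment,
      value = analysis_to_native(cohort$assessment, cohort$alpha),
      units = units
    )
    return(out[order(out$subject, out$session, out$assessment), ])
  }
  ratio <- if (cfg$condition == "repeatability") 2 else 1.5
  battery <- default_battery(up_down_ratio = ratio)
  p_star <- convergence_target(2, ratio)
  presets <- cfg$presets
  rows <- list()
  for (subj in unique(cohort$subject)) {
    for (s in 1:2) {
      slice <- cohort[cohort$subject == subj & cohort$session == s, ]
      observers <- list()
      for (i in seq_len(nrow(slice))) {
        nm <- slice$assessment[i]
        pr <- presets[presets$assessment == nm, ]
        if (nm %in% c("srm_colocated", "srm_separated")) {
          a <- progressive_alpha_for(slice$alpha[i], pr$beta, 1 / 32,
                                     cfg$lapse)
          observers[[nm]] <- simulated_observer(a, pr$beta, gamma = 1 / 32,
                                                lambda = cfg$lapse,
                                                scale = "linear")
        } else {
          # analysis-unit threshold -> adaptation-domain target at p*
          thr_adapt <- if (nm %in% c("no_notch", "notch")) {
            45 - slice$alpha[i]        # TMR -> masker level, dB SPL
          } else slice$alpha[i]        # log2 units coincide with the domain
          obs0 <- simulated_observer(0, pr$beta, lambda = cfg$lapse,
                                     direction = pr$direction,
                                     scale = pr$scale)
          a <- thr_adapt - (observer_point(obs0, p_star) - 0)
          observers[[nm]] <- simulated_observer(a, pr$beta,
                                                lambda = cfg$lapse,
                                                direction = pr$direction,
                                                scale = pr$scale)
        }
      }
      res <- run_battery(observers, battery = battery, subject_id = subj,
                         session = s, condition = cfg$condition)
      rows[[length(rows) + 1]] <- session_to_long(res, battery)
    }
  }
  do.call(rbind, rows)
}
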