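#' Convert a log-scale modulation depth to 20*log10(m) units
#'
#' Modulation thresholds measured as a mid-to-peak depth `M` on a
#' logarithmic amplitude scale (dB) are converted to the linear-depth
#' convention of the older literature, where the sinusoidal depth
#' `m` within 0-1 is expressed as `20*log10(m)`:
#'
#'   `20 * log10((10^(M/10) - 1) / (10^(M/10) + 1))`
#'
#' The conversion is strictly increasing, always negative, tends to
#' `-Inf` as `M -> 0` and to `0` from below as `M -> Inf`.
#'
#' @param m_db mid-to-peak log-scale depth `M` in dB; must be positive.
#' @return depth in `20*log10(m)` dB (vectorised).
#' @examples
#' depth_to_20logm(0.95)  # -19.26
#' @export
depth_to_20logm <- function(m_db) {
  if (any(m_db <= 0)) {
    stop("depth must be positive (the conversion tends to -Inf at 0)")
  }
  r <- 10^(m_db / 10)
  20 * log10((r - 1) / (r + 1))
}

analysis_unit_table <- function() {
  data.frame(
    assessment = c("gap", "diotic_fm", "dichotic_fm", "tm", "sm", "stm",
                   "no_notch", "notch", "srm_colocated", "srm_separated"),
    transform = c("log2", "log2", "log2", "identity", "identity", "identity",
                  "tmr", "tmr", "identity", "identity"),
    units = c("log2 (ms)", "log2 (Hz)", "log2 (Hz)", "M (dB)", "M (dB)",
              "M (dB)", "TMR (dB)", "TMR (dB)", "TMR (dB)", "TMR (dB)"),
    stringsAsFactors = FALSE
  )
}

#' Transform native-unit thresholds to analysis units
#'
#' Temporal-fine-structure thresholds (ms or Hz) are transformed to log2
#' units; tone-in-noise masker levels are converted to target-to-masker
#' ratios (`TMR = target level - masker level`, target 45 dB SPL);
#' modulation depths and speech-task TMRs pass through unchanged.
#' Nonpositive values under a log transform are flagged and excluded with a
#' reason rather than silently dropped.
#'
#' @param data long-format data frame with at least `assessment` and
#'   `value` columns (native units).
#' @param target_level tone level of the tone-in-noise tests, dB SPL.
#' @return `data` with `value` replaced by the transformed value and added
#'   columns `units` and `excluded_reason` (NA when usable).
#' @export
to_analysis_units <- function(data, target_level = 45) {
  tab <- analysis_unit_table()
  if (!all(data$assessment %in% tab$assessment)) {
    bad <- setdiff(unique(data$assessment), tab$assessment)
    stop("unknown assessment(s): ", paste(bad, collapse = ", "))
  }
  i <- match(data$assessment, tab$assessment)
  out <- data
  out$units <- tab$units[i]
  out$excluded_reason <- NA_character_
  tr <- tab$transform[i]
  v <- data$value
  neg_log <- tr == "log2" & v <= 0
  out$excluded_reason[neg_log] <- "nonpositive value under log2 transform"
  newv <- v
  ok_log <- tr == "log2" & !neg_log
  newv[ok_log] <- log2(v[ok_log])
  newv[neg_log] <- NA_real_
  newv[tr == "tmr"] <- target_level - v[tr == "tmr"]
  out$value <- newv
  out
}

#' Single-pass 3-SD outlier mask
#'
#' Marks values deviating more than `k` sample standard deviations from the
#' mean, with mean and SD computed once from all values (the candidate
#' included). A value at exactly `k` SD is kept; the rule is a single pass
#' and deliberately not iterated. Intended to be applied per assessment and
#' condition.
#'
#' @param values numeric vector (length >= 3).
#' @param k rejection threshold in SDs.
#' @return logical inclusion mask (`TRUE` = keep).
#' @export
reject_outliers <- function(values, k = 3) {
  if (length(values) < 3) stop("at least 3 values are required")
  s <- sd(values)
  if (s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= k * s
}

#' Bland-Altman limits of agreement with companion paired statistics
#'
#' For paired session measurements the bias is `mean(s2 - s1)` (negative
#' bias means better second-session performance for threshold-type
#' measures) and the 95% limits of agreement are `bias +/- 1.96 * SD` of
#' the paired differences. The same pairs yield the Pearson correlation, a
#' paired t-test, and the paired Cohen's d (`bias / SD(differences)`).
#'
#' @param s1,s2 numeric vectors of session-1 and session-2 values for the
#'   same subjects, in the same order.
#' @return an object of class `loa_result` with elements `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `r`, `r_p`, `t`, `t_p`, `d`, `df`.
#' @export
bland_altman <- function(s1, s2) {
  if (length(s1) != length(s2)) stop("sessions must be paired (equal length)")
  keep <- is.finite(s1) & is.finite(s2)
  s1 <- s1[keep]; s2 <- s2[keep]
  n <- length(s1)
  if (n < 2) stop("at least 2 complete pairs are required")
  d <- s2 - s1
  bias <- mean(d)
  sdd <- sd(d)
  if (sdd > 0) {
    tt <- t.test(s2, s1, paired = TRUE)
    if (n >= 3 && sd(s1) > 0 && sd(s2) > 0) {
      ct <- stats::cor.test(s1, s2)
      r <- unname(ct$estimate); r_p <- ct$p.value
    } else {
      r <- NA_real_; r_p <- NA_real_
    }
    t_stat <- unname(tt$statistic); t_p <- tt$p.value
    cohend <- bias / sdd
  } else {
    r <- if (sd(s1) > 0) unname(cor(s1, s2)) else NA_real_
    r_p <- NA_real_
    t_stat <- if (bias == 0) 0 else Inf
    t_p <- if (bias == 0) 1 else 0
    cohend <- 0
  }
  structure(
    list(n = n, bias = bias, sd_diff = sdd,
         loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
         r = r, r_p = r_p, t = t_stat, t_p = t_p, d = cohend, df = n - 1L),
    class = "loa_result"
  )
}

#' @export
print.loa_result <- function(x, ...) {
  cat(sprintf(
    "<loa_result: n %d, bias %.3f, LoA [%.3f, %.3f], r %.2f, t %.2f, d %.2f>\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$r, x$t, x$d
  ))
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient over the columns of an item matrix,
#' computed from the covariance matrix of complete cases:
#' `alpha = k / (k - 1) * (1 - sum(item variances) / variance of the sum)`.
#'
#' @param mat numeric matrix, subjects in rows, items in columns.
#' @return Cronbach's alpha.
#' @export
cronbach_alpha <- function(mat) {
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  k <- ncol(mat)
  if (k < 2 || nrow(mat) < 3) stop("need >= 2 items and >= 3 complete subjects")
  total_var <- var(rowSums(mat))
  if (total_var == 0) stop("zero variance in total score")
  k / (k - 1) * (1 - sum(apply(mat, 2, var)) / total_var)
}

#' Composite z-scores across assessments
#'
#' Each assessment column is z-scored against its own mean and SD over the
#' included subjects, and the composite is the per-subject mean of the
#' z-scores across assessments. Internal consistency of the composite is
#' summarised with Cronbach's alpha over the columns.
#'
#' @param threshold_matrix numeric matrix in analysis units, subjects in
#'   rows, assessments in named columns; missing cells allowed.
#' @return a list with `z_matrix`, `composite` (per-subject mean z) and
#'   `cronbach_alpha`.
#' @export
composite_scores <- function(threshold_matrix) {
  m <- as.matrix(threshold_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and >= 2 assessments")
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    stop("zero-variance assessment column(s): ",
         paste(colnames(m)[which(sds == 0 | is.na(sds))], collapse = ", "))
  }
  z <- scale(m)
  list(z_matrix = z,
       composite = rowMeans(z, na.rm = TRUE),
       cronbach_alpha = cronbach_alpha(z))
}

#' Test-retest reliability report
#'
#' The full two-session reliability pipeline: per assessment, subjects with
#' both sessions are paired and summarised with [bland_altman()]; a
#' composite z-score row is appended (z-scoring pooled over sessions, then
#' per-subject-session mean across assessments). Also returns the
#' mean-versus-difference data behind a limits-of-agreement plot.
#'
#' @param data long-format data frame with columns `subject`, `session`
#'   (1 or 2), `assessment`, `value` (analysis units), and optionally
#'   `units`.
#' @return a list of class `retest_report`: `table` (one row per assessment
#'   plus `"composite"`, columns `assessment`, `n`, `bias`, `loa_low`,
#'   `loa_high`, `units`, `r`, `r_p`, `t`, `t_p`, `d`, `df`), `loa` (the
#'   underlying `loa_result`s), `plot_data` (`assessment`, `subject`,
#'   `mean`, `diff`), `composite` (the [composite_scores()] output on
#'   session-averaged values) and `dropped` (subjects lacking a session).
#' @export
test_retest_report <- function(data) {
  stopifnot(all(c("subject", "session", "assessment", "value") %in% names(data)))
  units <- if ("units" %in% names(data)) {
    tapply(as.character(data$units), data$assessment, `[`, 1)
  } else NULL
  assessments <- unique(data$assessment)
  # z-score pooled over sessions for the composite
  zdata <- data
  for (a in assessments) {
    i <- zdata$assessment == a
    zdata$value[i] <- as.vector(scale(zdata$value[i]))
  }
  pair_up <- function(d) {
    s1 <- d[d$session == 1, c("subject", "value")]
    s2 <- d[d$session == 2, c("subject", "value")]
    m <- merge(s1, s2, by = "subject", suffixes = c("_1", "_2"))
    m[is.finite(m$value_1) & is.finite(m$value_2), ]
  }
  rows <- list(); loas <- list(); plot_rows <- list(); dropped <- character(0)
  for (a in assessments) {
    d <- data[data$assessment == a, ]
    m <- pair_up(d)
    dropped <- union(dropped, setdiff(unique(d$subject), m$subject))
    loa <- bland_altman(m$value_1, m$value_2)
    loas[[a]] <- loa
    rows[[a]] <- data.frame(
      assessment = a, n = loa$n, bias = loa$bias, loa_low = loa$loa_low,
      loa_high = loa$loa_high,
      units = if (is.null(units)) NA_character_ else unname(units[a]),
      r = loa$r, r_p = loa$r_p, t = loa$t, t_p = loa$t_p, d = loa$d,
      df = loa$df
    )
    plot_rows[[a]] <- data.frame(
      assessment = a, subject = m$subject,
      mean = (m$value_1 + m$value_2) / 2, diff = m$value_2 - m$value_1
    )
  }
  # composite per subject and session
  comp <- stats::aggregate(value ~ subject + session, data = zdata, FUN = mean)
  mc <- pair_up(cbind(comp, assessment = "composite"))
  loa_c <- bland_altman(mc$value_1, mc$value_2)
  loas[["composite"]] <- loa_c
  rows[["composite"]] <- data.frame(
    assessment = "composite", n = loa_c$n, bias = loa_c$bias,
    loa_low = loa_c$loa_low, loa_high = loa_c$loa_high, units = "z",
    r = loa_c$r, r_p = loa_c$r_p, t = loa_c$t, t_p = loa_c$t_p, d = loa_c$d,
    df = loa_c$df
  )
  plot_rows[["composite"]] <- data.frame(
    assessment = "composite", subject = mc$subject,
    mean = (mc$value_1 + mc$value_2) / 2, diff = mc$value_2 - mc$value_1
  )
  # composite internals on session-averaged values
  avg <- stats::aggregate(value ~ subject + assessment, data = data, FUN = mean)
  wide <- stats::reshape(avg, idvar = "subject", timevar = "assessment",
                         direction = "wide")
  rownames(wide) <- wide$subject
  wide$subject <- NULL
  colnames(wide) <- sub("^value\\.", "", colnames(wide))
  composite <- composite_scores(as.matrix(wide))
  if (length(dropped)) {
    message(length(dropped), " subject(s) lacked a session for >=1 assessment")
  }
  structure(
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         loa = loas, plot_data = do.call(rbind, plot_rows),
         composite = composite, dropped = dropped),
    class = "retest_report"
  )
}

#' @export
print.retest_report <- function(x, ...) {
  cat("Test-retest reliability report\n")
  tab <- x$table
  tab$bias <- round(tab$bias, 3)
  tab$loa_low <- round(tab$loa_low, 2); tab$loa_high <- round(tab$loa_high, 2)
  tab$r <- round(tab$r, 2); tab$t <- round(tab$t, 2); tab$d <- round(tab$d, 2)
  print(tab[, c("assessment", "bias", "loa_low", "loa_high", "units", "r",
                "t", "d", "df")], row.names = FALSE)
  cat(sprintf("Composite Cronbach's alpha: %.2f\n", x$composite$cronbach_alpha))
  invisible(x)
}
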