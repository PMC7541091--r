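#' Multichannel sampled-audio container
#'
#' An `audio_buffer` holds sampled audio as a numeric matrix (one column per
#' channel, full-scale amplitude +/- 1.0) together with its sample rate. All
#' synthesizers in the package emit this type. Samples must be finite and are
#' not allowed to exceed full scale: clipping is treated as an error by the
#' level-setting machinery, never as silent saturation.
#'
#' @param samples numeric vector (mono, duplicated to stereo if
#'   `n_channels = 2`) or matrix with one column per channel.
#' @param sample_rate sampling rate in Hz.
#' @param n_channels number of channels when `samples` is a vector.
#' @return an object of class `audio_buffer` with elements `samples`
#'   (matrix), `sample_rate`, `n_channels`, and `duration` (seconds).
#' @examples
#' b <- audio_buffer(sin(2 * pi * 1000 * seq(0, 0.01, by = 1 / 44100)) * 0.5)
#' b$duration
#' @export
audio_buffer <- function(samples, sample_rate = 44100, n_channels = 2L) {
  if (is.vector(samples)) {
    samples <- matrix(rep(samples, n_channels), ncol = n_channels)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric vector or matrix")
  }
  if (any(!is.finite(samples))) stop("audio samples must be finite")
  if (max(abs(samples)) > 1 + 1e-12) {
    stop(sprintf(
      "samples exceed full scale (peak %.4f > 1.0); refusing to clip",
      max(abs(samples))
    ))
  }
  structure(
    list(
      samples = samples,
      sample_rate = sample_rate,
      n_channels = ncol(samples),
      duration = nrow(samples) / sample_rate
    ),
    class = "audio_buffer"
  )
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf(
    "<audio_buffer: %d ch, %d frames @ %g Hz (%.1f ms), peak %.3f FS>\n",
    x$n_channels, nrow(x$samples), x$sample_rate, 1000 * x$duration,
    max(abs(x$samples))
  ))
  invisible(x)
}

#' Digital-to-acoustic level calibration map
#'
#' Maps digital RMS level (dB re full scale) to sound pressure level. The
#' single parameter is the SPL produced by a signal with an RMS of 0 dBFS
#' (RMS 1.0). The default of 100 dB SPL keeps every stimulus level used by
#' the battery (45-80 dB SPL) at least 20 dB below full scale.
#'
#' @param dbfs_to_dbspl_offset dB SPL produced by a 0 dBFS-RMS signal.
#' @return an object of class `calibration_map`.
#' @export
calibration_map <- function(dbfs_to_dbspl_offset = 100) {
  if (!is.finite(dbfs_to_dbspl_offset)) stop("calibration offset must be finite")
  structure(list(offset = dbfs_to_dbspl_offset), class = "calibration_map")
}

rms <- function(x) sqrt(mean(x^2))

#' Measure the calibrated level of a buffer
#'
#' @param buffer an [audio_buffer()].
#' @param cal a [calibration_map()].
#' @return level in dB SPL (RMS over all channels and frames).
#' @export
measure_level <- function(buffer, cal = calibration_map()) {
  r <- rms(buffer$samples)
  if (r == 0) return(-Inf)
  cal$offset + 20 * log10(r)
}

#' Scale a buffer to a requested sound pressure level
#'
#' Pure scaling: the waveform shape is unchanged and the resulting RMS level,
#' mapped through the calibration, equals the requested level to within
#' 0.01 dB. Scaling that would push any sample past full scale is an error
#' (fail-fast clipping policy).
#'
#' @inheritParams measure_level
#' @param level requested level in dB SPL.
#' @return a rescaled [audio_buffer()].
#' @export
set_rms_level <- function(buffer, level, cal = calibration_map()) {
  stopifnot(inherits(buffer, "audio_buffer"))
  r <- rms(buffer$samples)
  if (r == 0) stop("cannot set the level of a silent (zero-RMS) buffer")
  target_rms <- 10^((level - cal$offset) / 20)
  g <- target_rms / r
  peak <- max(abs(buffer$samples)) * g
  if (peak > 1 + 1e-12) {
    stop(sprintf(
      "requested %.1f dB SPL would clip (peak %.3f FS, overshoot %.2f dB)",
      level, peak, 20 * log10(peak)
    ))
  }
  audio_buffer(buffer$samples * g, buffer$sample_rate)
}

#' Assemble a two-cue two-alternative forced-choice trial
#'
#' Builds the four-interval sequence used by the battery: a standard cue,
#' two alternatives (the target in position 2 or 3, a freshly drawn standard
#' in the other slot), and a closing standard cue. Inter-stimulus intervals
#' are carried as timing metadata and rendered as true digital zeros by
#' [render_trial()].
#'
#' @param standard an [audio_buffer()], a list of three buffers, or a
#'   zero-argument function returning a fresh standard each call (use a
#'   function when the standard must be re-drawn per interval, as for the
#'   random-carrier FM standards).
#' @param target the target [audio_buffer()].
#' @param position 1-based interval index of the target, 2 or 3.
#' @param isi_ms inter-stimulus interval in ms.
#' @param iti_s inter-trial interval in s (metadata only).
#' @return an object of class `trial_sequence` with elements `intervals`
#'   (list of 4 buffers), `target_position`, `isi_ms`, `iti_s`.
#' @export
assemble_trial <- function(standard, target, position, isi_ms = 250, iti_s = 1) {
  if (!position %in% c(2L, 3L)) stop("target position must be 2 or 3")
  draw <- if (is.function(standard)) {
    standard
  } else if (is.list(standard) && !inherits(standard, "audio_buffer")) {
    stopifnot(length(standard) == 3)
    i <- 0L
    function() { i <<- i + 1L; standard[[i]] }
  } else {
    function() standard
  }
  std1 <- draw()
  inner_std <- draw()
  std4 <- draw()
  for (b in list(std1, inner_std, std4)) {
    if (b$sample_rate != target$sample_rate || b$n_channels != target$n_channels) {
      stop("standard and target must share sample rate and channel count")
    }
  }
  intervals <- vector("list", 4)
  intervals[[1]] <- std1
  intervals[[4]] <- std4
  intervals[[position]] <- target
  intervals[[if (position == 2L) 3L else 2L]] <- inner_std
  structure(
    list(intervals = intervals, target_position = as.integer(position),
         isi_ms = isi_ms, iti_s = iti_s),
    class = "trial_sequence"
  )
}

#' Render a trial sequence to a single buffer
#'
#' Concatenates the four intervals with `isi_ms` of digital silence between
#' consecutive intervals (the inter-trial interval is metadata and is not
#' rendered).
#'
#' @param trial a `trial_sequence` from [assemble_trial()].
#' @return an [audio_buffer()].
#' @export
render_trial <- function(trial) {
  sr <- trial$intervals[[1]]$sample_rate
  nch <- trial$intervals[[1]]$n_channels
  gap <- matrix(0, nrow = round(trial$isi_ms / 1000 * sr), ncol = nch)
  pieces <- list()
  for (i in seq_along(trial$intervals)) {
    pieces[[length(pieces) + 1]] <- trial$intervals[[i]]$samples
    if (i < length(trial$intervals)) pieces[[length(pieces) + 1]] <- gap
  }
  audio_buffer(do.call(rbind, pieces), sr)
}

#' Raised-cosine onset/offset ramps
#'
#' @param samples numeric matrix of audio samples.
#' @param ramp_ms ramp duration in ms (applied at both ends).
#' @param sample_rate sampling rate in Hz.
#' @return the ramped sample matrix.
#' @keywords internal
apply_ramps <- function(samples, ramp_ms, sample_rate) {
  n <- nrow(samples)
  nr <- round(ramp_ms / 1000 * sample_rate)
  if (nr * 2 > n) stop("ramps longer than the signal")
  if (nr == 0) return(samples)
  w <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  env <- c(w, rep(1, n - 2 * nr), rev(w))
  samples * env
}
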