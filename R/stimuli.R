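#' Temporal-gap stimulus
#'
#' Two 4-ms, 500-Hz tone bursts separated by a silent gap, presented
#' diotically at 80 dB SPL. The standard is the same pair of bursts with no
#' gap. The gap is defined between the zero-envelope offset of the first
#' burst and the onset of the second; each burst carries a full raised-cosine
#' (Hann) envelope to limit spectral splatter. The level is set so that the
#' burst portions have the requested RMS level.
#'
#' @param gap_ms gap duration in ms (adaptive parameter), within 0-100.
#' @param burst_freq tone-burst frequency in Hz.
#' @param burst_dur_ms tone-burst duration in ms.
#' @param level presentation level in dB SPL.
#' @param cal a [calibration_map()].
#' @param sample_rate sampling rate in Hz.
#' @return a diotic [audio_buffer()].
#' @export
synth_gap <- function(gap_ms = 20, burst_freq = 500, burst_dur_ms = 4,
                      level = 80, cal = calibration_map(),
                      sample_rate = 44100) {
  if (gap_ms < 0 || gap_ms > 100) stop("gap must lie in [0, 100] ms")
  nb <- round(burst_dur_ms / 1000 * sample_rate)
  t <- (seq_len(nb) - 1) / sample_rate
  env <- 0.5 * (1 - cos(2 * pi * (seq_len(nb) - 0.5) / nb))
  burst <- sin(2 * pi * burst_freq * t) * env
  target_rms <- 10^((level - cal$offset) / 20)
  burst <- burst * target_rms / rms(burst)
  gap <- rep(0, round(gap_ms / 1000 * sample_rate))
  audio_buffer(c(burst, gap, burst), sample_rate)
}

#' Frequency-modulation stimulus
#'
#' A tone whose instantaneous frequency is
#' `carrier + depth * sin(2*pi*rate*t + phi0)`. In the diotic variant both
#' ears receive identical signals; in the dichotic variant the modulator is
#' sign-inverted in the right ear, producing a continuously shifting
#' interaural phase difference. A depth of 0 yields the pure-tone standard;
#' the carrier is drawn uniformly from 460-550 Hz per stimulus (re-draw it
#' per interval to defeat pitch-matching strategies).
#'
#' @param depth_hz peak frequency deviation in Hz (adaptive parameter).
#' @param carrier carrier frequency in Hz; drawn uniformly from
#'   `carrier_range` when `NULL`.
#' @param rate modulation rate in Hz.
#' @param dichotic logical; invert the modulator in the right ear.
#' @param duration_ms stimulus duration in ms.
#' @param level presentation level in dB SPL.
#' @param phi0 modulator starting phase in radians; drawn uniformly from
#'   `[0, 2*pi)` when `NULL` to prevent onset-phase cues.
#' @param carrier_range range the random carrier is drawn from, in Hz.
#' @param ramp_ms raised-cosine on/off ramp duration in ms.
#' @param cal a [calibration_map()].
#' @param sample_rate sampling rate in Hz.
#' @return a stereo [audio_buffer()] with attribute `"carrier"`.
#' @export
synth_fm <- function(depth_hz, carrier = NULL, rate = 2, dichotic = FALSE,
                     duration_ms = 400, level = 75, phi0 = NULL,
                     carrier_range = c(460, 550), ramp_ms = 10,
                     cal = calibration_map(), sample_rate = 44100) {
  if (depth_hz < 0) stop("modulation depth must be non-negative")
  if (is.null(carrier)) carrier <- runif(1, carrier_range[1], carrier_range[2])
  if (is.null(phi0)) phi0 <- runif(1, 0, 2 * pi)
  n <- round(duration_ms / 1000 * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  chan <- function(d) {
    # phase integral of carrier + d*sin(2*pi*rate*t + phi0)
    ph <- 2 * pi * carrier * t -
      d / rate * (cos(2 * pi * rate * t + phi0) - cos(phi0))
    sin(ph)
  }
  left <- chan(depth_hz)
  right <- if (dichotic) chan(-depth_hz) else left
  s <- apply_ramps(cbind(left, right), ramp_ms, sample_rate)
  out <- set_rms_level(audio_buffer(s, sample_rate), level, cal)
  attr(out, "carrier") <- carrier
  out
}

mod_noise_components <- function(n, sample_rate, band) {
  df <- sample_rate / n
  k <- seq(ceiling(band[1] / df), floor(band[2] / df))
  freqs <- k * df
  list(k = k, freqs = freqs, x_oct = log2(freqs / band[1]))
}

#' Modulated broadband-noise stimulus
#'
#' Flat-spectrum noise over 0.4-8 kHz built in the frequency domain from the
#' maximum number of components the sampling rate allows (all FFT bins in
#' band, random Rayleigh amplitudes and uniform phases). A sinusoidal gain
#' surface is applied per component on a logarithmic amplitude scale,
#'
#'   `G(t, x) = M * sin(2*pi*(tm_rate*t +/- sm_density*x) + phase)` dB,
#'
#' with `x = log2(f / 400)` octaves, so the modulation depth `M` is measured
#' from the middle of the amplitude range to the peak. `tm_rate > 0` alone
#' gives temporal modulation, `sm_density > 0` alone spectral modulation, and
#' both together spectro-temporal modulation whose ripple drifts upward or
#' downward in frequency according to `direction`. Depth 0 reproduces the
#' unmodulated standard.
#'
#' @param depth_m modulation depth `M` in dB (mid-to-peak, log-amplitude
#'   scale), within 0-40.
#' @param tm_rate temporal modulation rate in Hz (0 for none).
#' @param sm_density spectral modulation density in cycles/octave (0 for none).
#' @param direction ripple drift direction for spectro-temporal modulation.
#' @param mod_phase modulation starting phase in radians; random when `NULL`.
#' @param duration_ms stimulus duration in ms.
#' @param level presentation level in dB SPL.
#' @param band noise band in Hz.
#' @param ramp_ms raised-cosine ramp duration in ms.
#' @param cal a [calibration_map()].
#' @param sample_rate sampling rate in Hz.
#' @return a diotic [audio_buffer()].
#' @export
synth_modulated_noise <- function(depth_m = 0, tm_rate = 0, sm_density = 0,
                                  direction = c("up", "down"),
                                  mod_phase = NULL, duration_ms = 500,
                                  level = 65, band = c(400, 8000),
                                  ramp_ms = 10, cal = calibration_map(),
                                  sample_rate = 44100) {
  direction <- match.arg(direction)
  if (depth_m < 0 || depth_m > 40) stop("modulation depth must lie in [0, 40] dB")
  if (is.null(mod_phase)) mod_phase <- runif(1, 0, 2 * pi)
  n <- round(duration_ms / 1000 * sample_rate)
  comp <- mod_noise_components(n, sample_rate, band)
  m <- length(comp$freqs)
  amps <- sqrt(rnorm(m)^2 + rnorm(m)^2)           # Rayleigh
  phases <- runif(m, 0, 2 * pi)
  sm_sign <- if (direction == "up") -1 else 1     # ridge x = (tm/sm) * t moves up
  ifft_sum <- function(a) {
    spec <- complex(length.out = n)
    spec[comp$k + 1] <- a * exp(1i * phases)
    Re(fft(spec, inverse = TRUE))
  }
  if (depth_m == 0) {
    s <- ifft_sum(amps)
  } else if (tm_rate == 0 && sm_density > 0) {
    gain_db <- depth_m * sin(2 * pi * sm_sign * sm_density * comp$x_oct + mod_phase)
    s <- ifft_sum(amps * 10^(gain_db / 20))
  } else if (tm_rate > 0 && sm_density == 0) {
    t <- (seq_len(n) - 1) / sample_rate
    s <- ifft_sum(amps) * 10^(depth_m * sin(2 * pi * tm_rate * t + mod_phase) / 20)
  } else {
    s <- component_sum(comp$freqs, amps, phases, n, sample_rate, depth_m,
                       tm_rate, sm_sign, sm_density, comp$x_oct, mod_phase)
  }
  s <- s / (max(abs(s)) * 1.2)                    # headroom before level-setting
  s <- apply_ramps(matrix(s, ncol = 1), ramp_ms, sample_rate)
  set_rms_level(audio_buffer(as.vector(s), sample_rate), level, cal)
}

#' Notched-noise masker and tonal target
#'
#' The masker is a sum of 10,000 sinusoidal components with log-uniform
#' frequency spacing and per-component power proportional to 1/f, giving a
#' -3 dB/octave power slope, random phases, and RMS level `masker_level`.
#' Without a notch the band is 1.2-2.8 kHz; with a notch the components
#' occupy 0.8-1.6 and 2.4-3.2 kHz (component counts split in proportion to
#' each band's logarithmic width), leaving an 0.8-kHz notch centred on the
#' 2-kHz target. The target is a 2-kHz tone at 45 dB SPL.
#'
#' @param masker_level masker RMS level in dB SPL (adaptive parameter),
#'   within 25-90.
#' @param notch logical; include the spectral notch.
#' @param n_components number of sinusoidal components.
#' @param duration_ms duration in ms for masker and target.
#' @param target_freq target tone frequency in Hz.
#' @param target_level target tone level in dB SPL.
#' @param ramp_ms raised-cosine ramp duration in ms.
#' @param cal a [calibration_map()].
#' @param sample_rate sampling rate in Hz.
#' @return list with [audio_buffer()] elements `masker` and `target`.
#' @export
synth_notched_noise <- function(masker_level = 35, notch = FALSE,
                                n_components = 10000, duration_ms = 500,
                                target_freq = 2000, target_level = 45,
                                ramp_ms = 10, cal = calibration_map(),
                                sample_rate = 44100) {
  if (masker_level < 25 || masker_level > 90) {
    stop("masker level must lie in [25, 90] dB SPL")
  }
  bands <- if (notch) rbind(c(800, 1600), c(2400, 3200)) else rbind(c(1200, 2800))
  logw <- log(bands[, 2] / bands[, 1])
  counts <- round(n_components * logw / sum(logw))
  counts[1] <- counts[1] + (n_components - sum(counts))
  freqs <- unlist(lapply(seq_len(nrow(bands)), function(i) {
    exp(runif(counts[i], log(bands[i, 1]), log(bands[i, 2])))
  }))
  amps <- 1 / sqrt(freqs)                       # power ~ 1/f: -3 dB/octave
  phases <- runif(n_components, 0, 2 * pi)
  n <- round(duration_ms / 1000 * sample_rate)
  s <- component_sum(freqs, amps, phases, n, sample_rate,
                     0, 0, 1, 0, numeric(length(freqs)), 0)
  s <- s / (max(abs(s)) * 1.2)
  s <- apply_ramps(matrix(s, ncol = 1), ramp_ms, sample_rate)
  masker <- set_rms_level(audio_buffer(as.vector(s), sample_rate),
                          masker_level, cal)
  t <- (seq_len(n) - 1) / sample_rate
  tone <- apply_ramps(matrix(sin(2 * pi * target_freq * t), ncol = 1),
                      ramp_ms, sample_rate)
  target <- set_rms_level(audio_buffer(as.vector(tone), sample_rate),
                          target_level, cal)
  list(masker = masker, target = target)
}

#' Response grid for the speech-on-speech task
#'
#' @return a data frame of all color/number response cells (4 colors by
#'   8 numbers, 32 cells).
#' @export
srm_grid <- function() {
  expand.grid(color = c("blue", "red", "white", "green"),
              number = 1:8, stringsAsFactors = FALSE)
}

#' Speech-on-speech masking trial record with placeholder audio
#'
#' Builds the structured record for one trial of the spatialized
#' speech-on-speech task: a target sentence (call sign "Charlie", one color,
#' one number) with two simultaneous maskers, each at an azimuth of 0 degrees
#' (colocated) or +/-45 degrees (separated). The rendered audio is a
#' schematic placeholder - labelled tone complexes panned by azimuth - not
#' recorded speech; psychometric behaviour on this task is modelled at the
#' target-to-masker-ratio level by the observer module.
#'
#' @param target_color,target_number target keywords (see [srm_grid()]).
#' @param masker_keywords list of two `c(color, number)` pairs.
#' @param target_level target RMS level in dB SPL.
#' @param masker_level per-masker RMS level in dB SPL.
#' @param separated logical; maskers at +/-45 degrees instead of 0.
#' @param duration_ms placeholder audio duration in ms.
#' @param cal a [calibration_map()].
#' @param sample_rate sampling rate in Hz.
#' @return list with elements `record` (keywords, levels, azimuths, tmr,
#'   grid size) and `audio` (placeholder stereo [audio_buffer()]).
#' @export
synth_srm_trial <- function(target_color, target_number,
                            masker_keywords = list(c("red", 2), c("green", 7)),
                            target_level = 65, masker_level = 55,
                            separated = FALSE, duration_ms = 400,
                            cal = calibration_map(), sample_rate = 44100) {
  grid <- srm_grid()
  if (!target_color %in% grid$color) stop("unknown target color")
  if (!target_number %in% grid$number) stop("unknown target number")
  if (length(masker_keywords) != 2) stop("exactly two maskers are required")
  azimuths <- if (separated) c(0, -45, 45) else c(0, 0, 0)
  if (!all(azimuths %in% c(0, -45, 45))) stop("azimuths must be 0 or +/-45 deg")
  n <- round(duration_ms / 1000 * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  pan <- function(az) switch(as.character(az),
                             "0" = c(1, 1) / sqrt(2), "-45" = c(1, 0), "45" = c(0, 1))
  voice <- function(f0, level, az) {
    x <- rowSums(sapply(f0 * 1:4, function(f) sin(2 * pi * f * t))) / 4
    x <- as.vector(apply_ramps(matrix(x, ncol = 1), 10, sample_rate))
    g <- 10^((level - cal$offset) / 20) / rms(x)
    outer(x * g, pan(az))
  }
  mix <- voice(110, target_level, azimuths[1]) +
    voice(130, masker_level, azimuths[2]) +
    voice(150, masker_level, azimuths[3])
  peak <- max(abs(mix))
  if (peak > 1) stop(sprintf("SRM placeholder mix clips (peak %.2f FS)", peak))
  list(
    record = list(
      call_sign = "Charlie",
      target = list(color = target_color, number = as.integer(target_number)),
      maskers = masker_keywords,
      levels = c(target = target_level, masker = masker_level),
      azimuths = azimuths,
      tmr = target_level - masker_level,
      grid_cells = nrow(grid)
    ),
    audio = audio_buffer(mix, sample_rate)
  )
}
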