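# Independent signal-analysis oracles used to verify rendered stimuli.
# These deliberately avoid the synthesis code paths: depths and frequencies
# are re-measured from the waveforms alone.

# analytic signal via frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# instantaneous frequency (Hz) from the analytic-signal phase derivative
instantaneous_frequency <- function(x, fs) {
  z <- analytic_signal(x)
  dph <- Arg(z[-1] * Conj(z[-length(z)]))
  dph * fs / (2 * pi)
}

# interaural phase difference between two channels
ipd_trace <- function(left, right) {
  Arg(analytic_signal(left) * Conj(analytic_signal(right)))
}

# fitted amplitude of a sinusoid at known frequency in (t, y) data
fit_sinusoid_amplitude <- function(t, y, freq) {
  X <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  co <- coef(lm(y ~ X))
  sqrt(sum(co[2:3]^2))
}

# short-window RMS envelope in dB, interior windows only (ramps excluded)
db_envelope <- function(x, fs, win_s = 0.010, trim_s = 0.02) {
  win <- round(win_s * fs)
  nwin <- floor(length(x) / win)
  env <- vapply(seq_len(nwin), function(i) {
    sqrt(mean(x[((i - 1) * win + 1):(i * win)]^2))
  }, numeric(1))
  tc <- (seq_len(nwin) - 0.5) * win / fs
  keep <- tc > trim_s & tc < length(x) / fs - trim_s
  list(t = tc[keep], db = 20 * log10(env[keep]))
}

# per-bin amplitude spectrum in dB with frequency axis
db_spectrum <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  f <- (0:(n - 1)) * fs / n
  keep <- seq_len(floor(n / 2))
  list(f = f[keep], db = 20 * log10(Mod(X[keep]) + 1e-300),
       power = Mod(X[keep])^2)
}

band_power_db <- function(spec, lo, hi) {
  s <- spec$f >= lo & spec$f <= hi
  10 * log10(mean(spec$power[s]))
}

# deterministic responder: answers from a fixed probability via global RNG
constant_p_responder <- function(p) {
  function() runif(1) < p
}

# brute-force numeric oracle for the log-depth -> 20 log10(m) conversion:
# sample the modulated amplitude envelope 10^(M*sin(theta)/20), measure the
# linear modulation depth (max - min) / (max + min), express as 20 log10(m)
numeric_depth_conversion <- function(m_db) {
  theta <- seq(0, 2 * pi, length.out = 40001)  # includes pi/2 and 3*pi/2
  env <- 10^(m_db * sin(theta) / 20)
  m_lin <- (max(env) - min(env)) / (max(env) + min(env))
  20 * log10(m_lin)
}
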