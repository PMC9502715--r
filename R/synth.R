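# Synthetic sound sources: a speech-like modulated source, a weakly
# modulated broadband interferer, and stationary speech-shaped noise.
# These stand in for recorded corpora so every experiment ships with
# known ground truth.

#' Speech-like test source
#'
#' Synthesizes a single-channel speech-like signal: a glottal-style pulse
#' train with a drifting fundamental (100-220 Hz), filtered through
#' randomly drawn formant-like resonances per "phone" segment
#' (40-200 ms), with a syllabic (2-8 Hz) amplitude modulation and silent
#' gaps. The deep envelope modulation is the property that separates
#' speech from the weakly modulated interferer downstream.
#'
#' @param duration_s duration in seconds (> 0).
#' @param sample_rate sampling rate in Hz.
#' @param seed integer RNG seed; the same seed reproduces the waveform.
#' @return numeric vector of `duration_s * sample_rate` samples, unit RMS.
#' @export
synth_speechlike <- function(duration_s, sample_rate = 16000, seed = 1) {
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  n <- round(duration_s * sample_rate)
  with_seed(seed, {
    # voiced excitation: pulse train with drifting f0
    f0 <- 100 + 120 * cumsum_bounded(stats::rnorm(n, 0, 0.004))
    phase <- cumsum(f0) / sample_rate
    exc <- numeric(n)
    exc[which(diff(floor(phase)) > 0) + 1L] <- 1
    exc <- exc + 0.02 * stats::rnorm(n)  # aspiration noise

    # segment-wise formant filtering (phone-like spectral variation)
    out <- numeric(n)
    pos <- 1L
    while (pos <= n) {
      seg_len <- round(stats::runif(1, 0.04, 0.2) * sample_rate)
      idx <- pos:min(n, pos + seg_len - 1L)
      seg <- exc[idx]
      voiced <- stats::runif(1) > 0.25
      if (!voiced) seg <- stats::rnorm(length(idx))  # fricative-like burst
      freqs <- c(stats::runif(1, 300, 800), stats::runif(1, 900, 2200),
                 stats::runif(1, 2300, 3200))
      for (fc in freqs) seg <- resonator(seg, fc, bw = 0.08 * fc + 50, sample_rate)
      # na.rm guards the degenerate 1-sample trailing segment (sd = NA)
      out[idx] <- seg / max(1e-12, stats::sd(seg), na.rm = TRUE)
      pos <- pos + seg_len
    }

    # syllabic envelope with silent gaps
    env <- syllabic_envelope(n, sample_rate)
    x <- out * env
    x / sqrt(mean(x^2))
  })
}

#' Weakly modulated broadband interferer
#'
#' Synthesizes a stationary, broadband, weakly modulated noise source in
#' the spirit of machine noise (e.g. a vacuum cleaner): white noise with a
#' mild spectral tilt plus a low-frequency motor hum, and a shallow
#' (about 5%) slow amplitude modulation. Its spectral flatness exceeds
#' and its envelope modulation depth falls well below those of
#' [synth_speechlike()].
#'
#' @inheritParams synth_speechlike
#' @return numeric vector of samples, unit RMS.
#' @export
synth_interferer <- function(duration_s, sample_rate = 16000, seed = 1) {
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  n <- round(duration_s * sample_rate)
  with_seed(seed, {
    broad <- shape_spectrum(stats::rnorm(n), sample_rate, tilt_db_oct = -1.5)
    hum <- resonator(stats::rnorm(n), 90, bw = 30, sample_rate)
    x <- broad / stats::sd(broad) + 0.3 * hum / stats::sd(hum)
    am <- 1 + 0.05 * sin(2 * pi * 7 * seq_len(n) / sample_rate)
    x <- x * am
    x / sqrt(mean(x^2))
  })
}

#' Stationary speech-shaped noise
#'
#' Gaussian noise spectrally shaped toward the long-term average speech
#' spectrum (flat up to ~500 Hz, then rolling off); stationary, no
#' envelope modulation. Building block of the diffuse noise field.
#'
#' @inheritParams synth_speechlike
#' @return numeric vector of samples, unit RMS.
#' @export
speech_shaped_noise <- function(duration_s, sample_rate = 16000, seed = 1) {
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  n <- round(duration_s * sample_rate)
  with_seed(seed, {
    x <- stats::rnorm(n)
    nfft <- next_pow2(n)
    f <- seq(0, sample_rate / 2, length.out = nfft / 2 + 1)
    # LTASS-like magnitude: high-pass below 100 Hz, -6 dB/oct above 500 Hz
    h <- (f / 100) / sqrt(1 + (f / 100)^2) / sqrt(1 + (f / 500)^2)
    hfull <- c(h, rev(h[2:(nfft / 2)]))
    y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) * hfull, inverse = TRUE)) / nfft
    y <- y[seq_len(n)]
    y / sqrt(mean(y^2))
  })
}

# bounded random walk in [-1, 1] via tanh squashing
cumsum_bounded <- function(steps) tanh(cumsum(steps))

# Second-order resonator (constant peak gain) at center frequency fc.
resonator <- function(x, fc, bw, sample_rate) {
  r <- exp(-pi * bw / sample_rate)
  theta <- 2 * pi * fc / sample_rate
  a <- c(1, -2 * r * cos(theta), r^2)
  as.numeric(signal::filter(signal::Arma(b = 1 - r, a = a), x))
}

# Apply a broadband spectral tilt (dB per octave) in the frequency domain.
shape_spectrum <- function(x, sample_rate, tilt_db_oct) {
  n <- length(x)
  nfft <- next_pow2(n)
  f <- seq(0, sample_rate / 2, length.out = nfft / 2 + 1)
  h <- (pmax(f, 50) / 1000)^(tilt_db_oct / 6.02)  # amplitude slope in dB/octave
  hfull <- c(h, rev(h[2:(nfft / 2)]))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) * hfull, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Syllabic-rate (2-8 Hz) envelope with silent gaps; mean ~ o(1).
syllabic_envelope <- function(n, sample_rate) {
  lf <- stats::rnorm(ceiling(n / 64) + 8)
  lf <- stats::filter(lf, rep(1 / 8, 8), sides = 2)
  lf <- lf[!is.na(lf)]
  env <- stats::approx(seq_along(lf), lf, xout = seq(1, length(lf), length.out = n))$y
  env <- env - stats::quantile(env, 0.25)     # ~25% of time in silent gaps
  env <- pmax(env, 0)^1.5
  env / max(env)
}
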