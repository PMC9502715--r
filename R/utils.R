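# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible sub-seed; stays inside the 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629L + 1)
}

stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

db_to_pow <- function(db) 10^(db / 10)

next_pow2 <- function(n) 2^ceiling(log2(n))

# FFT-based linear convolution.
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- next_pow2(n)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                       stats::fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Envelope modulation index
#'
#' Rectifies the signal, low-passes it with a moving average (default
#' 32 ms) and returns the coefficient of variation (sd/mean) of the
#' resulting envelope. Deeply modulated speech-like signals score high;
#' stationary noises score near zero.
#'
#' @param x numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param win_s smoothing window in seconds.
#' @return scalar modulation index.
#' @export
modulation_index <- function(x, sample_rate, win_s = 0.032) {
  env <- abs(x)
  w <- max(1L, round(win_s * sample_rate))
  env <- stats::filter(env, rep(1 / w, w), sides = 2)
  env <- env[!is.na(env)]
  stats::sd(env) / mean(env)
}

#' Spectral flatness
#'
#' Geometric over arithmetic mean of the power spectrum (DC and mirror
#' excluded); 1 for white noise, near 0 for tonal/formant-dominated
#' signals.
#'
#' @param x numeric waveform.
#' @return scalar flatness in (0, 1].
#' @export
spectral_flatness <- function(x) {
  p <- Mod(stats::fft(x))^2
  p <- p[2:floor(length(p) / 2)]  # drop DC and mirror
  p <- pmax(p, .Machine$double.xmin)
  exp(mean(log(p))) / mean(p)
}
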