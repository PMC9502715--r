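# Short-time Fourier analysis/synthesis with a square-root Hann window
# pair at 50% overlap (COLA-compliant: analysis x synthesis windows sum
# to one), used by the beamformer.

# Periodic Hann window.
hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Short-time Fourier transform
#'
#' Square-root Hann analysis window, hop = `win_len / 2`. The signal is
#' zero-padded by one window on both ends so that [istft()] reconstructs
#' it exactly (up to numerical precision).
#'
#' @param x numeric vector.
#' @param win_len window length in samples (default 512).
#' @return list with `spec` (bins x frames complex matrix, bins =
#'   `win_len/2 + 1`), `win_len`, `hop`, `n_orig`.
#' @export
stft <- function(x, win_len = 512) {
  hop <- win_len %/% 2
  w <- sqrt(hann_periodic(win_len))
  xp <- c(numeric(win_len), x, numeric(2 * win_len))
  n_frames <- (length(xp) - win_len) %/% hop + 1L
  nb <- win_len %/% 2 + 1L
  spec <- matrix(0 + 0i, nb, n_frames)
  for (t in seq_len(n_frames)) {
    seg <- xp[(t - 1L) * hop + seq_len(win_len)] * w
    spec[, t] <- stats::fft(seg)[seq_len(nb)]
  }
  structure(list(spec = spec, win_len = win_len, hop = hop, n_orig = length(x)),
            class = "stft")
}

#' Inverse short-time Fourier transform
#'
#' Overlap-add with the square-root Hann synthesis window matching
#' [stft()].
#'
#' @param s an `stft` object (the `spec` slot may have been modified).
#' @param n_out output length; defaults to the analyzed signal length.
#' @return numeric vector.
#' @export
istft <- function(s, n_out = s$n_orig) {
  win_len <- s$win_len
  hop <- s$hop
  w <- sqrt(hann_periodic(win_len))
  n_frames <- ncol(s$spec)
  y <- numeric((n_frames - 1L) * hop + win_len)
  for (t in seq_len(n_frames)) {
    full <- c(s$spec[, t], Conj(rev(s$spec[2:(win_len %/% 2), t])))
    seg <- Re(stats::fft(full, inverse = TRUE)) / win_len
    idx <- (t - 1L) * hop + seq_len(win_len)
    y[idx] <- y[idx] + seg * w
  }
  y[win_len + seq_len(n_out)]
}
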