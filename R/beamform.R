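# Frequency-domain MVDR beamforming over a grid of steering sectors,
# with an isotropic (direction-averaged) noise covariance.

#' Free-field steering vectors
#'
#' Computes the relative transfer function of the array for each azimuth
#' and frequency bin under the plane-wave model:
#' `d_m(alpha, w) = exp(-i w (tau_m - tau_ref))`, so the reference channel
#' is 1 at every bin and all magnitudes are 1. When an impulse-response
#' set is supplied, `d` is its frequency response normalized to the
#' reference channel instead.
#'
#' @param geometry an [array_geometry()].
#' @param azimuth_grid steering azimuths in degrees.
#' @param n_fft STFT size; bins are `0 .. n_fft/2`.
#' @param reference_channel index normalized to 1 (default 1, front-left).
#' @param ir_set optional [load_ir_set()] result.
#' @return object of class `steering_set`: `d` (complex array mics x bins
#'   x sectors), `azimuth_grid`, `freqs_hz`, `n_fft`, `reference_channel`.
#' @export
steering_vectors <- function(geometry, azimuth_grid = seq(-90, 90, by = 10),
                             n_fft = 512, reference_channel = 1, ir_set = NULL) {
  if (length(azimuth_grid) < 1L) stop("azimuth_grid is empty")
  m <- nrow(geometry$mic_positions)
  nb <- n_fft %/% 2 + 1L
  freqs <- seq(0, geometry$sample_rate / 2, length.out = nb)
  d <- array(0 + 0i, dim = c(m, nb, length(azimuth_grid)))
  for (a in seq_along(azimuth_grid)) {
    if (is.null(ir_set)) {
      tau <- plane_wave_delays(geometry, azimuth_grid[a])
      tau <- tau - tau[reference_channel]
      d[, , a] <- exp(-2i * pi * outer(tau, freqs))
    } else {
      k <- which.min(abs(angular_diff(ir_set$azimuths, azimuth_grid[a])))
      ir <- ir_set$irs[[k]]
      H <- apply(ir, 2, function(h) stats::fft(c(h, numeric(n_fft - length(h))))[seq_len(nb)])
      d[, , a] <- t(H) / rep(H[, reference_channel], each = m)
    }
  }
  structure(list(d = d, azimuth_grid = azimuth_grid, freqs_hz = freqs,
                 n_fft = n_fft, reference_channel = reference_channel),
            class = "steering_set")
}

#' Isotropic noise covariance
#'
#' Direction-averaged covariance of a spatially isotropic noise field:
#' `R(w) = (1/K) sum_alpha d(alpha, w) d(alpha, w)^H`, computed over a
#' full-circle azimuth grid, plus diagonal loading
#' `loading * tr(R)/M * I` for invertibility.
#'
#' @param steering a [steering_vectors()] set over a full-circle grid
#'   (>= 36 directions recommended).
#' @param loading relative diagonal loading factor (> 0, default 1e-3).
#' @return object of class `noise_covariance`: `R` (list of Hermitian
#'   matrices per bin), `freqs_hz`, `loading`.
#' @export
isotropic_covariance <- function(steering, loading = 1e-3) {
  if (loading <= 0) stop("loading must be > 0")
  m <- dim(steering$d)[1]
  nb <- dim(steering$d)[2]
  K <- dim(steering$d)[3]
  R <- vector("list", nb)
  for (f in seq_len(nb)) {
    D <- matrix(steering$d[, f, ], m, K)
    Rf <- (D %*% Conj(t(D))) / K
    Rf <- (Rf + Conj(t(Rf))) / 2  # enforce exact Hermitian symmetry
    R[[f]] <- Rf + diag(loading * Re(sum(diag(Rf))) / m, m)
  }
  structure(list(R = R, freqs_hz = steering$freqs_hz, loading = loading),
            class = "noise_covariance")
}

#' MVDR weights for one steering vector
#'
#' `w = R^-1 d / (d^H R^-1 d)`; satisfies the distortionless constraint
#' `w^H d = 1` and minimizes output noise power `w^H R w` among all
#' distortionless weights.
#'
#' @param d complex steering vector.
#' @param R Hermitian positive-definite noise covariance matrix.
#' @return complex weight vector.
#' @export
mvdr_weights <- function(d, R) {
  Rinv_d <- tryCatch(solve(R, d), error = function(e)
    stop("singular noise covariance: ", conditionMessage(e), call. = FALSE))
  denom <- sum(Conj(d) * Rinv_d)
  Rinv_d / denom
}

#' MVDR beamformer bank over the steering grid
#'
#' @param steering a [steering_vectors()] set (the beamforming grid).
#' @param covariance an [isotropic_covariance()] on the same bins.
#' @return object of class `beamformer_bank`: `w` (mics x bins x sectors),
#'   plus the grid metadata.
#' @export
beamformer_bank <- function(steering, covariance) {
  if (length(covariance$R) != dim(steering$d)[2]) {
    stop("covariance bins do not match the steering set")
  }
  w <- array(0 + 0i, dim = dim(steering$d))
  for (a in seq_len(dim(steering$d)[3])) {
    for (f in seq_len(dim(steering$d)[2])) {
      w[, f, a] <- mvdr_weights(steering$d[, f, a], covariance$R[[f]])
    }
  }
  structure(list(w = w, azimuth_grid = steering$azimuth_grid,
                 freqs_hz = steering$freqs_hz, n_fft = steering$n_fft),
            class = "beamformer_bank")
}

#' Apply the beamformer bank to a multichannel signal
#'
#' STFT analysis of every channel (square-root Hann, 50% overlap), the
#' per-bin inner product `Y(w, t) = w^H(alpha, w) X(w, t)` per steering
#' sector, and overlap-add resynthesis — one single-channel waveform per
#' sector.
#'
#' @param sig an [mc_signal()].
#' @param bank a [beamformer_bank()].
#' @return list of numeric vectors, one per sector, named by azimuth.
#' @export
beamform_all <- function(sig, bank) {
  m <- nrow(sig$samples)
  if (m != dim(bank$w)[1]) stop("channel count does not match beamformer bank")
  S <- lapply(seq_len(m), function(ch) stft(sig$samples[ch, ], bank$n_fft))
  nb <- dim(bank$w)[2]
  if (nrow(S[[1]]$spec) != nb) stop("STFT bins do not match beamformer bank")
  out <- vector("list", dim(bank$w)[3])
  for (a in seq_len(dim(bank$w)[3])) {
    Y <- matrix(0 + 0i, nb, ncol(S[[1]]$spec))
    for (ch in seq_len(m)) {
      Y <- Y + Conj(bank$w[ch, , a]) * S[[ch]]$spec
    }
    ys <- S[[1]]; ys$spec <- Y
    out[[a]] <- istft(ys)
  }
  names(out) <- as.character(bank$azimuth_grid)
  out
}
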