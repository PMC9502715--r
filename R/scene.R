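# Scene construction: fractional-delay spatialization under a free-field
# plane-wave model, diffuse noise fields, calibrated SNR mixing and a
# synthetic reverberant tail.

#' Spatialize a single-channel source to a microphone array
#'
#' Renders a far-field plane wave from the given azimuth: each channel is
#' the source delayed by tau_m = -(p_m . u(azimuth)) / c, applied as an
#' exact fractional delay in the frequency domain. By default a
#' first-order low-pass head-shadow attenuation is applied to
#' microphones on the side of the head away from the source; besides the
#' level cue, its angle-dependent phase response mimics part of the head
#' diffraction structure that measured impulse responses would carry.
#' Set `head_shadow = FALSE` for the pure free-field delay model.
#'
#' Alternatively, a measured multichannel impulse-response set can be used
#' via [load_ir_set()] and the `ir_set` argument, in which case the source
#' is convolved with the impulse responses for the nearest stored azimuth.
#'
#' @param source numeric vector, single-channel source signal.
#' @param azimuth_deg source azimuth in degrees, within [-180, 180].
#' @param geometry an [array_geometry()].
#' @param head_shadow logical; apply a simple contralateral low-pass.
#' @param ir_set optional impulse-response set from [load_ir_set()].
#' @return an [mc_signal()] with one channel per microphone.
#' @export
spatialize <- function(source, azimuth_deg, geometry, head_shadow = TRUE,
                       ir_set = NULL) {
  if (length(source) == 0L) stop("source signal is empty")
  stopifnot_scalar(azimuth_deg, "azimuth_deg")
  if (abs(azimuth_deg) > 180) stop("azimuth_deg must be within [-180, 180]")
  fs <- geometry$sample_rate
  m <- nrow(geometry$mic_positions)

  if (!is.null(ir_set)) {
    k <- which.min(abs(angular_diff(ir_set$azimuths, azimuth_deg)))
    ir <- ir_set$irs[[k]]
    if (ncol(ir) != m) stop("impulse-response channel count does not match geometry")
    n <- length(source)
    out <- t(vapply(seq_len(m), function(ch) fft_conv(source, ir[, ch])[seq_len(n)],
                    numeric(n)))
    return(mc_signal(out, geometry))
  }

  delays <- plane_wave_delays(geometry, azimuth_deg) * fs
  # shift by a common offset so every channel delay is non-negative: a
  # global delay is physically immaterial but keeps all content inside
  # the output window
  delays <- delays - min(delays)
  margin <- ceiling(max(delays)) + 8L
  n <- length(source)
  npad <- next_pow2(n + 2L * margin)
  X <- stats::fft(c(numeric(margin), source, numeric(npad - n - margin)))
  freqs <- c(0:(npad / 2), -(npad / 2 - 1):-1) / npad  # cycles/sample
  out <- matrix(0, m, n)
  for (ch in seq_len(m)) {
    ph <- exp(-2i * pi * freqs * delays[ch])
    if (npad %% 2 == 0) ph[npad / 2 + 1] <- Re(ph[npad / 2 + 1])  # keep output real
    y <- Re(stats::fft(X * ph, inverse = TRUE)) / npad
    out[ch, ] <- y[margin + seq_len(n)]
  }
  if (head_shadow) out <- apply_head_shadow(out, azimuth_deg, geometry)
  mc_signal(out, geometry)
}

# First-order low-pass plus broadband attenuation on microphones on the
# far side of the head, scaled with source laterality.
apply_head_shadow <- function(samples, azimuth_deg, geometry) {
  fs <- geometry$sample_rate
  a <- azimuth_deg * pi / 180
  src_y <- -sin(a)  # +y is the left side of the head
  lat <- abs(sin(a))
  for (ch in seq_len(nrow(samples))) {
    mic_y <- geometry$mic_positions[ch, 2]
    if (sign(mic_y) != 0 && sign(src_y) != 0 && sign(mic_y) != sign(src_y)) {
      fc <- 4000 - 2500 * lat  # stronger shadow for more lateral sources
      alpha <- exp(-2 * pi * fc / fs)
      samples[ch, ] <- as.numeric(signal::filter(signal::Arma(1 - alpha, c(1, -alpha)),
                                                 samples[ch, ])) * (1 - 0.3 * lat)
    }
  }
  samples
}

angular_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  d
}

#' Load a user-supplied impulse-response set
#'
#' Reads one multichannel WAV per azimuth (channel count must match the
#' intended geometry). File names must contain the integer azimuth in
#' degrees, e.g. `ir_-30.wav`, `ir_40.wav`.
#'
#' @param paths character vector of WAV paths.
#' @param azimuths optional numeric azimuths; parsed from file names when
#'   omitted.
#' @return a list with `azimuths` and `irs` (list of samples x channels
#'   matrices), class `ir_set`.
#' @export
load_ir_set <- function(paths, azimuths = NULL) {
  if (is.null(azimuths)) {
    azimuths <- as.numeric(sub(".*?(-?[0-9]+)\\.wav$", "\\1", basename(paths)))
    if (any(is.na(azimuths))) stop("cannot parse azimuths from file names; pass `azimuths`")
  }
  irs <- lapply(paths, function(p) read_wav(p)$samples)
  structure(list(azimuths = azimuths, irs = irs), class = "ir_set")
}

#' Diffuse speech-shaped noise field
#'
#' Superimposes independent stationary speech-shaped noise sources from
#' `n_directions` equally spaced azimuths covering the full horizontal
#' circle, each spatialized with the plane-wave model and power-equalized,
#' emulating a spatially diffuse noise field.
#'
#' @param duration_s duration in seconds.
#' @param geometry an [array_geometry()].
#' @param n_directions number of equally spaced directions (default 19).
#' @param seed integer RNG seed.
#' @return an [mc_signal()].
#' @export
diffuse_noise <- function(duration_s, geometry, n_directions = 19, seed = 1) {
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  if (n_directions < 2) stop("n_directions must be >= 2")
  az <- seq(0, 360 - 360 / n_directions, by = 360 / n_directions)
  az <- ifelse(az > 180, az - 360, az)
  acc <- NULL
  for (k in seq_len(n_directions)) {
    src <- speech_shaped_noise(duration_s, geometry$sample_rate,
                               seed = sub_seed(seed, k))
    sig <- spatialize(src, az[k], geometry)
    acc <- if (is.null(acc)) sig$samples else acc + sig$samples
  }
  acc <- acc / sqrt(mean(acc^2))
  mc_signal(acc, geometry)
}

#' Mix target and noise at a calibrated SNR
#'
#' Scales the noise so that the ratio of target power to noise power on the
#' reference channel equals `snr_db`. Target power is measured over
#' target-active samples only (10 ms frames whose energy is within 40 dB of
#' the loudest frame), so silent gaps in the speech-like target do not
#' deflate the nominal SNR; noise power is measured over the same samples.
#'
#' @param target,noise [mc_signal()] objects of equal shape and rate.
#' @param snr_db desired SNR in dB.
#' @param reference_channel channel index used for the power measurement.
#' @return an [mc_signal()], `target + g * noise`. The applied noise gain
#'   is attached as attribute `"noise_gain"`.
#' @export
mix_at_snr <- function(target, noise, snr_db, reference_channel = 1) {
  if (!identical(dim(target$samples), dim(noise$samples))) {
    stop("target and noise must have identical shapes")
  }
  if (target$sample_rate != noise$sample_rate) stop("sample rates differ")
  stopifnot_scalar(snr_db, "snr_db")
  tref <- target$samples[reference_channel, ]
  nref <- noise$samples[reference_channel, ]
  active <- active_sample_mask(tref, target$sample_rate)
  p_t <- mean(tref[active]^2)
  p_n <- mean(nref[active]^2)
  if (p_n <= 0) stop("noise is silent on the reference channel; cannot scale")
  g <- sqrt(p_t / (p_n * db_to_pow(snr_db)))
  out <- mc_signal(target$samples + g * noise$samples, target$geometry,
                   target$sample_rate)
  attr(out, "noise_gain") <- g
  out
}

# Samples belonging to 10 ms frames whose energy is within 40 dB of the
# maximum frame energy.
active_sample_mask <- function(x, sample_rate, frame_s = 0.01, range_db = 40) {
  w <- max(1L, round(frame_s * sample_rate))
  nfr <- floor(length(x) / w)
  e <- colSums(matrix(x[seq_len(nfr * w)]^2, nrow = w))
  keep <- e > max(e) * db_to_pow(-range_db)
  mask <- rep(FALSE, length(x))
  mask[seq_len(nfr * w)] <- rep(keep, each = w)
  mask
}

#' Synthetic reverberation
#'
#' Convolves each channel with a synthetic room impulse response: a unit
#' direct path followed by an exponentially decaying Gaussian tail whose
#' decay rate matches the requested reverberation time (amplitude decays by
#' 60 dB over `t60_s`). `t60_s = 0` returns the input unchanged.
#'
#' @param sig an [mc_signal()].
#' @param t60_s reverberation time in seconds (>= 0).
#' @param seed integer RNG seed (tail noise).
#' @param drr_db direct-to-reverberant energy ratio in dB (default 0).
#' @return an [mc_signal()].
#' @export
apply_reverb <- function(sig, t60_s, seed = 1, drr_db = 0) {
  stopifnot_scalar(t60_s, "t60_s")
  if (t60_s < 0) stop("t60_s must be >= 0")
  if (t60_s == 0) return(sig)
  fs <- sig$sample_rate
  n <- ncol(sig$samples)
  out <- sig$samples
  for (ch in seq_len(nrow(out))) {
    ir <- reverb_impulse_response(t60_s, fs, seed = sub_seed(seed, ch), drr_db = drr_db)
    out[ch, ] <- fft_conv(sig$samples[ch, ], ir)[seq_len(n)]
  }
  mc_signal(out, sig$geometry, fs)
}

#' Synthetic room impulse response
#'
#' Unit direct impulse plus a random-phase exponentially decaying tail
#' starting after 5 ms, with amplitude envelope 10^(-3 t / t60) and total
#' tail energy set by `drr_db` relative to the direct path.
#'
#' @inheritParams apply_reverb
#' @param sample_rate sampling rate in Hz.
#' @return numeric impulse-response vector.
#' @export
reverb_impulse_response <- function(t60_s, sample_rate, seed = 1, drr_db = 0) {
  stopifnot_scalar(t60_s, "t60_s", positive = TRUE)
  with_seed(seed, {
    gap <- round(0.005 * sample_rate)
    nt <- round(1.2 * t60_s * sample_rate)
    t <- seq_len(nt) / sample_rate
    tail <- stats::rnorm(nt) * 10^(-3 * t / t60_s)
    tail <- tail * sqrt(db_to_pow(-drr_db) / sum(tail^2))
    c(1, numeric(gap - 1L), tail)
  })
}

#' Build one scene from a declarative spec
#'
#' Composes source synthesis, spatialization, diffuse-noise generation or
#' interferer placement, reverberation and SNR mixing according to a
#' [scene_spec()], and returns the mixture together with its ground truth.
#'
#' @param spec a [scene_spec()].
#' @param geometry an [array_geometry()].
#' @param reference_channel reference channel for the SNR calibration.
#' @return list with `signal` (an [mc_signal()]) and `truth` (list with
#'   `target_azimuth_deg`, `interferer_azimuth_deg` (NA for diffuse noise),
#'   `noise_kind`, `snr_db`, `room`, `seed`).
#' @export
build_scene <- function(spec, geometry = bte_geometry(), reference_channel = 1) {
  fs <- geometry$sample_rate
  src <- synth_speechlike(spec$duration_s, fs, seed = sub_seed(spec$seed, 1))
  target <- spatialize(src, spec$target_azimuth_deg, geometry)
  noise <- if (spec$noise_kind == "diffuse") {
    diffuse_noise(spec$duration_s, geometry, seed = sub_seed(spec$seed, 2))
  } else {
    intf <- synth_interferer(spec$duration_s, fs, seed = sub_seed(spec$seed, 2))
    spatialize(intf, spec$interferer_azimuth_deg, geometry)
  }
  if (spec$t60_s > 0) {
    target <- apply_reverb(target, spec$t60_s, seed = sub_seed(spec$seed, 3))
    noise <- apply_reverb(noise, spec$t60_s, seed = sub_seed(spec$seed, 4))
  }
  mixed <- mix_at_snr(target, noise, spec$snr_db, reference_channel)
  truth <- list(target_azimuth_deg = spec$target_azimuth_deg,
                interferer_azimuth_deg = if (spec$noise_kind == "localized")
                  spec$interferer_azimuth_deg else NA_real_,
                noise_kind = spec$noise_kind, snr_db = spec$snr_db,
                room = spec$room, seed = spec$seed)
  list(signal = mixed, truth = truth)
}

#' Enumerate a scene grid
#'
#' Expands the full experiment grid (rooms x noise kinds x SNRs x
#' utterances) into a list of [scene_spec()]s with distinct seeds, one
#' scene per utterance and condition.
#'
#' @param n_utterances scenes per condition.
#' @param snrs_db SNR grid in dB (default -10 to +20 in 5 dB steps).
#' @param rooms room conditions.
#' @param noise_kinds noise conditions.
#' @param target_azimuth_deg,interferer_azimuth_deg source positions.
#' @param duration_s scene duration.
#' @param seed base seed; every scene derives a distinct sub-seed.
#' @return list of `scene_spec` objects.
#' @export
scene_grid <- function(n_utterances = 10, snrs_db = seq(-10, 20, by = 5),
                       rooms = c("anechoic", "reverberant"),
                       noise_kinds = c("diffuse", "localized"),
                       target_azimuth_deg = -30, interferer_azimuth_deg = 40,
                       duration_s = 2.5, seed = 1) {
  grid <- expand.grid(u = seq_len(n_utterances), snr = snrs_db, room = rooms,
                      noise = noise_kinds, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    scene_spec(target_azimuth_deg = target_azimuth_deg,
               noise_kind = grid$noise[i],
               interferer_azimuth_deg = interferer_azimuth_deg,
               snr_db = grid$snr[i], room = grid$room[i],
               duration_s = duration_s, seed = sub_seed(seed, i))
  })
}
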