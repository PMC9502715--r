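#' Microphone array geometry
#'
#' Describes a head-mounted microphone array: 3-D microphone positions in
#' meters relative to the head center, the sampling rate and the speed of
#' sound. The coordinate convention is x forward, y to the left, z up;
#' azimuth 0 degrees is straight ahead and positive azimuths are to the
#' right of the listener (so a talker on the left-hand side sits at a
#' negative azimuth).
#'
#' @param mic_positions numeric matrix, one row per microphone, columns
#'   x/y/z in meters.
#' @param sample_rate sampling rate in Hz.
#' @param speed_of_sound speed of sound in m/s (default 343).
#' @return an object of class `array_geometry`.
#' @export
array_geometry <- function(mic_positions, sample_rate = 16000, speed_of_sound = 343) {
  mic_positions <- as.matrix(mic_positions)
  if (ncol(mic_positions) == 2L) mic_positions <- cbind(mic_positions, 0)
  if (nrow(mic_positions) < 2L) stop("geometry needs at least 2 microphones")
  if (ncol(mic_positions) != 3L) stop("mic_positions must have 3 columns (x, y, z)")
  if (!all(is.finite(mic_positions))) stop("mic_positions must be finite")
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  stopifnot_scalar(speed_of_sound, "speed_of_sound", positive = TRUE)
  ap <- max(stats::dist(mic_positions))
  if (ap <= 0) stop("array aperture must be > 0 (all microphones coincide)")
  structure(list(mic_positions = mic_positions, sample_rate = sample_rate,
                 speed_of_sound = speed_of_sound, aperture = ap),
            class = "array_geometry")
}

#' Default 6-microphone behind-the-ear geometry
#'
#' Two lateral triplets of microphones at +/- 9 cm from the head center
#' (left and right ear), each triplet spanning 2 cm front-to-back, matching
#' a behind-the-ear hearing-aid form factor. Channel order: left front,
#' left mid, left rear, right front, right mid, right rear.
#'
#' @inheritParams array_geometry
#' @return an `array_geometry` with 6 microphones.
#' @export
bte_geometry <- function(sample_rate = 16000, speed_of_sound = 343) {
  pos <- rbind(
    c( 0.01,  0.09, 0), c(0.00,  0.09, 0), c(-0.01,  0.09, 0),
    c( 0.01, -0.09, 0), c(0.00, -0.09, 0), c(-0.01, -0.09, 0))
  rownames(pos) <- c("LF", "LM", "LR", "RF", "RM", "RR")
  array_geometry(pos, sample_rate, speed_of_sound)
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("array_geometry: %d mics, aperture %.3f m, fs %g Hz, c %g m/s\n",
              nrow(x$mic_positions), x$aperture, x$sample_rate, x$speed_of_sound))
  invisible(x)
}

#' Plane-wave arrival delays
#'
#' Far-field arrival delay of each microphone for a plane wave from the
#' given azimuth (degrees, measured clockwise from the front so positive
#' azimuths are to the listener's right): `tau_m = -(p_m . u) / c`.
#'
#' @param geometry an [array_geometry()].
#' @param azimuth_deg source azimuth in degrees.
#' @return numeric vector of delays in seconds (relative, may be negative).
#' @export
plane_wave_delays <- function(geometry, azimuth_deg) {
  a <- azimuth_deg * pi / 180
  u <- c(cos(a), -sin(a), 0)  # positive azimuth -> right (negative y)
  -as.numeric(geometry$mic_positions %*% u) / geometry$speed_of_sound
}

#' Multichannel audio signal
#'
#' A channels x time matrix of amplitudes tied to an [array_geometry()].
#'
#' @param samples numeric matrix, channels in rows, samples in columns.
#' @param geometry an `array_geometry`; channel count must match.
#' @param sample_rate sampling rate in Hz; defaults to the geometry's.
#' @return an object of class `mc_signal`.
#' @export
mc_signal <- function(samples, geometry, sample_rate = geometry$sample_rate) {
  samples <- as.matrix(samples)
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (nrow(samples) != nrow(geometry$mic_positions)) {
    stop(sprintf("channel count (%d) does not match geometry mic count (%d)",
                 nrow(samples), nrow(geometry$mic_positions)))
  }
  structure(list(samples = samples, sample_rate = sample_rate, geometry = geometry),
            class = "mc_signal")
}

#' @export
print.mc_signal <- function(x, ...) {
  cat(sprintf("mc_signal: %d channels x %d samples (%.2f s at %g Hz)\n",
              nrow(x$samples), ncol(x$samples),
              ncol(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Duration of a multichannel signal in seconds
#' @param x an `mc_signal`.
#' @return duration in seconds.
#' @export
duration_s <- function(x) ncol(x$samples) / x$sample_rate

#' Declarative scene description
#'
#' Describes one simulated acoustic scene: a speech-like target at a known
#' azimuth plus either a diffuse speech-shaped noise field or a localized
#' weakly modulated broadband interferer, at a given SNR, optionally
#' reverberant.
#'
#' @param target_azimuth_deg target azimuth in degrees within [-90, 90]
#'   (default -30).
#' @param noise_kind `"diffuse"` or `"localized"`.
#' @param interferer_azimuth_deg interferer azimuth for localized noise
#'   (default +40).
#' @param snr_db signal-to-noise ratio in dB on the reference channel.
#' @param room `"anechoic"` or `"reverberant"`.
#' @param t60_s reverberation time in seconds (0 for anechoic).
#' @param duration_s scene duration in seconds.
#' @param seed integer RNG seed.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(target_azimuth_deg = -30, noise_kind = c("diffuse", "localized"),
                       interferer_azimuth_deg = 40, snr_db = 0,
                       room = c("anechoic", "reverberant"), t60_s = NULL,
                       duration_s = 2.5, seed = 1) {
  noise_kind <- match.arg(noise_kind)
  room <- match.arg(room)
  if (is.null(t60_s)) t60_s <- if (room == "reverberant") 0.5 else 0
  stopifnot_scalar(target_azimuth_deg, "target_azimuth_deg")
  stopifnot_scalar(interferer_azimuth_deg, "interferer_azimuth_deg")
  stopifnot_scalar(snr_db, "snr_db")
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar(t60_s, "t60_s")
  if (abs(target_azimuth_deg) > 90 || abs(interferer_azimuth_deg) > 90) {
    stop("source azimuths must lie in the frontal hemisphere [-90, 90]")
  }
  if (room == "anechoic" && t60_s != 0) stop("anechoic rooms require t60_s = 0")
  if (t60_s < 0) stop("t60_s must be >= 0")
  structure(list(target_azimuth_deg = target_azimuth_deg, noise_kind = noise_kind,
                 interferer_azimuth_deg = interferer_azimuth_deg, snr_db = snr_db,
                 room = room, t60_s = t60_s, duration_s = duration_s,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("scene_spec: target %g deg, %s noise%s, SNR %g dB, %s (t60 %g s), %.1f s, seed %d\n",
              x$target_azimuth_deg, x$noise_kind,
              if (x$noise_kind == "localized") sprintf(" at %g deg", x$interferer_azimuth_deg) else "",
              x$snr_db, x$room, x$t60_s, x$duration_s, x$seed))
  invisible(x)
}

#' Write / read a scene_spec as plain key: value text
#'
#' @param spec a `scene_spec`.
#' @param path file path.
#' @return `read_scene_spec` returns a `scene_spec`.
#' @export
write_scene_spec <- function(spec, path) {
  fields <- c("target_azimuth_deg", "noise_kind", "interferer_azimuth_deg",
              "snr_db", "room", "t60_s", "duration_s", "seed")
  writeLines(sprintf("%s: %s", fields, vapply(spec[fields], as.character, "")), path)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  kv <- read_kv_file(path)
  num <- function(k) as.numeric(kv[[k]])
  scene_spec(target_azimuth_deg = num("target_azimuth_deg"),
             noise_kind = kv[["noise_kind"]],
             interferer_azimuth_deg = num("interferer_azimuth_deg"),
             snr_db = num("snr_db"), room = kv[["room"]], t60_s = num("t60_s"),
             duration_s = num("duration_s"), seed = as.integer(num("seed")))
}

# Parse "key: value" lines into a named list of strings.
read_kv_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  stats::setNames(lapply(kv, `[`, 3L), trimws(vapply(kv, `[`, "", 2L)))
}
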