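# Fusion of the DOA probability profile with the rescaled ASQM profile
# into the joint spatial speech likelihood, argmax direction estimation,
# and hit-rate scoring.

#' Direction profile
#'
#' One scalar per azimuth sector: an ASQM profile, a DOA probability
#' profile, a rescaled ASQM probability, or the fused likelihood.
#'
#' @param values numeric vector, one value per sector.
#' @param azimuth_grid strictly increasing sector azimuths in degrees.
#' @param semantics one of `"ASQM"`, `"P_DOA"`, `"P_ASQM"`, `"P_s"`.
#' @return an object of class `direction_profile`.
#' @export
direction_profile <- function(values, azimuth_grid,
                              semantics = c("ASQM", "P_DOA", "P_ASQM", "P_s")) {
  semantics <- match.arg(semantics)
  if (length(values) != length(azimuth_grid)) stop("values and grid lengths differ")
  if (length(azimuth_grid) && any(diff(azimuth_grid) <= 0)) {
    stop("azimuth_grid must be strictly increasing")
  }
  if (!all(is.finite(values))) stop("profile values must be finite")
  if (semantics != "ASQM" && (any(values < -1e-9) || any(values > 1 + 1e-9))) {
    stop("probability-tagged profiles must lie in [0, 1]")
  }
  structure(list(values = as.numeric(values), azimuth_grid = azimuth_grid,
                 semantics = semantics),
            class = "direction_profile")
}

#' @export
print.direction_profile <- function(x, ...) {
  cat(sprintf("direction_profile [%s], %d sectors; argmax at %g deg\n",
              x$semantics, length(x$values),
              x$azimuth_grid[which.max(x$values)]))
  invisible(x)
}

#' Rescale an ASQM profile to a per-utterance probability
#'
#' Min-max rescaling `(x - min) / (max - min)` over the sectors of one
#' utterance. A degenerate constant profile maps to all-ones (flagged),
#' so the subsequent fusion falls back to the DOA profile alone: a flat
#' quality profile carries no directional information.
#'
#' @param profile an ASQM [direction_profile()].
#' @return a `direction_profile` with semantics `"P_ASQM"`; attribute
#'   `"degenerate"` is TRUE for a constant input.
#' @export
rescale_asqm <- function(profile) {
  x <- profile$values
  if (!length(x)) stop("empty profile")
  if (length(x) < 2L) stop("need at least 2 sectors")
  rng <- max(x) - min(x)
  degenerate <- rng == 0
  y <- if (degenerate) rep(1, length(x)) else (x - min(x)) / rng
  out <- direction_profile(y, profile$azimuth_grid, semantics = "P_ASQM")
  attr(out, "degenerate") <- degenerate
  out
}

#' Joint spatial speech likelihood
#'
#' Elementwise product `P_s(alpha) = P_ASQM(alpha) * P_DOA(alpha)`.
#'
#' @param p_asqm a `P_ASQM` [direction_profile()].
#' @param p_doa a `P_DOA` [direction_profile()] on the same grid.
#' @return a `direction_profile` with semantics `"P_s"`.
#' @export
fuse_profiles <- function(p_asqm, p_doa) {
  if (!isTRUE(all.equal(p_asqm$azimuth_grid, p_doa$azimuth_grid))) {
    stop("azimuth grids differ")
  }
  direction_profile(p_asqm$values * p_doa$values, p_doa$azimuth_grid,
                    semantics = "P_s")
}

#' Argmax direction estimate
#'
#' Returns the azimuth of the maximizing sector; exact ties resolve to
#' the lowest azimuth and are flagged via attribute `"tie"`.
#'
#' @param profile a [direction_profile()].
#' @return the estimated azimuth (degrees).
#' @export
estimate_direction <- function(profile) {
  x <- profile$values
  if (!length(x)) stop("empty profile")
  if (any(is.na(x))) stop("NaN/NA in profile")
  i <- which.max(x)  # which.max takes the first (lowest-azimuth) maximum
  out <- profile$azimuth_grid[i]
  attr(out, "tie") <- sum(x == x[i]) > 1L
  out
}

#' Localization hit rate
#'
#' Percentage of records whose estimate falls in the true source's
#' sector. With the 10 degree sector grid this equals a tolerance of
#' +/-5 degrees around the true position.
#'
#' @param estimates numeric vector of estimated sector azimuths.
#' @param truths numeric vector of true sector azimuths (recycled if
#'   length 1); every truth must lie on `grid`.
#' @param grid the sector grid the estimates live on.
#' @return hit rate in percent (0..100).
#' @export
hit_rate <- function(estimates, truths, grid = seq(-90, 90, by = 10)) {
  if (!length(estimates)) stop("no records")
  truths <- rep_len(truths, length(estimates))
  if (!all(truths %in% grid)) stop("true sector(s) off the grid")
  100 * mean(estimates == truths)
}

#' Evaluate all localization methods on a set of scenes
#'
#' For each scene: builds it, computes the time-averaged DOA profile,
#' beamforms all sectors, computes each requested ASQM profile, forms the
#' rescaled and fused profiles, and records the argmax estimate of every
#' method. Methods are `"DOA"`, `"ASQM_<m>"` and `"DOAxASQM_<m>"` for
#' each measure `m`.
#'
#' @param scenes list of [scene_spec()]s.
#' @param doa_model a [train_doa_model()] fit.
#' @param bank a [beamformer_bank()].
#' @param provider posteriorgram provider, `function(waveform) ->`
#'   [posteriorgram()].
#' @param measures character subset of `c("mm", "map", "ient")`.
#' @param geometry the array geometry scenes are rendered with.
#' @param filters matched filter set, required when `"map"` is evaluated.
#' @param config an [mm_config()].
#' @return long-format data.frame: one row per scene x method with the
#'   scene condition, estimate, hit indicator and (for localized scenes)
#'   whether the interferer sector was selected.
#' @export
evaluate_methods <- function(scenes, doa_model, bank, provider,
                             measures = c("mm"), geometry = bte_geometry(),
                             filters = NULL, config = mm_config()) {
  rows <- list()
  for (si in seq_along(scenes)) {
    spec <- scenes[[si]]
    scene <- tryCatch(build_scene(spec, geometry), error = function(e)
      stop(sprintf("scene %d: %s", si, conditionMessage(e)), call. = FALSE))
    p_doa <- average_map(probability_map(scene$signal, doa_model))
    profiles <- list(DOA = p_doa)
    if (length(measures)) {
      bf <- beamform_all(scene$signal, bank)
      for (m in measures) {
        asqm <- asqm_profile(bf, provider, measure = m, config = config,
                             filters = filters)
        p_asqm <- rescale_asqm(asqm)
        profiles[[paste0("ASQM_", m)]] <- p_asqm
        profiles[[paste0("DOAxASQM_", m)]] <- fuse_profiles(p_asqm, p_doa)
      }
    }
    for (method in names(profiles)) {
      est <- estimate_direction(profiles[[method]])
      rows[[length(rows) + 1L]] <- data.frame(
        scene = si, snr_db = spec$snr_db, room = spec$room,
        noise_kind = spec$noise_kind, seed = spec$seed,
        true_azimuth = scene$truth$target_azimuth_deg,
        interferer_azimuth = scene$truth$interferer_azimuth_deg,
        method = method, estimate = as.numeric(est),
        hit = as.integer(est == scene$truth$target_azimuth_deg),
        interferer_selected = if (is.na(scene$truth$interferer_azimuth_deg))
          NA_integer_ else as.integer(est == scene$truth$interferer_azimuth_deg))
    }
  }
  do.call(rbind, rows)
}

#' Summarize hit rates per condition and method
#'
#' Aggregates an [evaluate_methods()] long table into a wide table
#' mirroring the experiment layout: one row per room x noise kind x SNR,
#' one column per method (hit rate in percent), plus the
#' interferer-selection rate per method for localized scenes.
#'
#' @param long a data.frame from [evaluate_methods()].
#' @return a data.frame of hit rates.
#' @export
summarize_hit_rates <- function(long) {
  agg <- stats::aggregate(cbind(hit = long$hit) ~ method + snr_db + room + noise_kind,
                          data = long, FUN = function(x) 100 * mean(x))
  wide <- stats::reshape(agg, idvar = c("snr_db", "room", "noise_kind"),
                         timevar = "method", direction = "wide")
  names(wide) <- sub("^hit\\.", "", names(wide))
  loc <- long[long$noise_kind == "localized", ]
  if (nrow(loc)) {
    vc <- stats::aggregate(cbind(vc = loc$interferer_selected) ~ method + snr_db + room +
                             noise_kind, data = loc, FUN = function(x) 100 * mean(x))
    vcw <- stats::reshape(vc, idvar = c("snr_db", "room", "noise_kind"),
                          timevar = "method", direction = "wide")
    wide <- merge(wide, vcw, by = c("snr_db", "room", "noise_kind"), all.x = TRUE)
  }
  wide[order(wide$noise_kind, wide$room, wide$snr_db), ]
}
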