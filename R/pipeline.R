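# End-to-end experiment orchestration: configuration validation, model
# training, scene-grid evaluation and table output.

config_defaults <- function() {
  list(seed = NULL, n_utterances = 10, snrs_db = seq(-10, 20, by = 5),
       rooms = c("anechoic", "reverberant"),
       noise_kinds = c("diffuse", "localized"),
       target_azimuth_deg = -30, interferer_azimuth_deg = 40,
       duration_s = 2.5, measures = "mm", doa_members = 3,
       classifier_train_s = 60, classifier_hidden = 16, classifier_maxit = 120,
       out_dir = NA_character_)
}

#' Validate an experiment configuration
#'
#' Accepts a named list (or the flat `key: value` text parsed from a
#' config file; multi-valued fields are space-separated) and returns a
#' typed, range-checked configuration. Unknown keys and a missing seed
#' are rejected by name.
#'
#' @param raw named list of configuration values.
#' @return a validated list of class `experiment_config`.
#' @export
validate_config <- function(raw) {
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  if (is.null(cfg$seed)) stop("config key `seed` is required")
  num_keys <- c("seed", "n_utterances", "snrs_db", "target_azimuth_deg",
                "interferer_azimuth_deg", "duration_s", "doa_members",
                "classifier_train_s", "classifier_hidden", "classifier_maxit")
  for (k in num_keys) {
    v <- if (is.character(cfg[[k]])) as.numeric(strsplit(trimws(cfg[[k]]), "\\s+")[[1]])
         else as.numeric(cfg[[k]])
    if (any(is.na(v))) stop("config key `", k, "` is not numeric")
    cfg[[k]] <- v
  }
  for (k in c("rooms", "noise_kinds", "measures")) {
    if (is.character(cfg[[k]]) && length(cfg[[k]]) == 1L) {
      cfg[[k]] <- strsplit(trimws(cfg[[k]]), "\\s+")[[1]]
    }
  }
  if (!all(cfg$rooms %in% c("anechoic", "reverberant"))) stop("invalid `rooms`")
  if (!all(cfg$noise_kinds %in% c("diffuse", "localized"))) stop("invalid `noise_kinds`")
  if (!all(cfg$measures %in% c("mm", "map", "ient"))) stop("invalid `measures`")
  if (cfg$n_utterances < 1) stop("`n_utterances` must be >= 1")
  if (cfg$duration_s <= 0) stop("`duration_s` must be > 0")
  structure(cfg, class = "experiment_config")
}

#' Read an experiment config from flat key: value text
#'
#' @param path config file path.
#' @return a validated `experiment_config`.
#' @export
read_experiment_config <- function(path) validate_config(read_kv_file(path))

#' Train the full localization system
#'
#' Convenience constructor for the three trained/derived components the
#' experiment pipeline needs: the phoneme classifier, the MVDR
#' beamformer bank, and the bagged DOA model (see
#' [train_default_doa_model()]). Deterministic given `seed`.
#'
#' @param geometry an [array_geometry()].
#' @param seed base RNG seed; all training randomness derives from it.
#' @param n_members DOA ensemble members (default 3).
#' @param classifier optional pre-trained [train_phoneme_classifier()]
#'   fit; trained from the seed when omitted.
#' @param verbose print stage progress.
#' @return list with `doa_model`, `classifier`, `bank`.
#' @export
train_localization_system <- function(geometry = bte_geometry(), seed = 1,
                                      n_members = 3, classifier = NULL,
                                      verbose = FALSE) {
  if (is.null(classifier)) {
    if (verbose) message("training phoneme classifier ...")
    classifier <- train_default_phoneme_classifier(seed = sub_seed(seed, 102))
  }
  bank <- beamformer_bank(steering_vectors(geometry),
                          isotropic_covariance(steering_vectors(geometry,
                                                                seq(0, 355, by = 5))))
  if (verbose) message(sprintf("training DOA model (%d-member bag) ...", n_members))
  doa_model <- train_default_doa_model(geometry, seed = seed,
                                       n_members = n_members)
  list(doa_model = doa_model, classifier = classifier, bank = bank)
}

#' Run the scaled-down localization experiment end-to-end
#'
#' Trains the DOA model and the phoneme classifier (plus matched filters
#' when `"map"` is among the measures) from the configured seeds, builds
#' the scene grid (utterances x rooms x noise kinds x SNRs), evaluates
#' every localization method on every scene and aggregates hit rates.
#' Fully deterministic under a fixed configuration.
#'
#' @param config an [validate_config()] result (or a raw named list).
#' @param doa_model,classifier optional pre-trained components; trained
#'   from the config seed when omitted.
#' @param verbose print stage progress to stderr.
#' @return list with `long` (per-scene records), `summary` (hit-rate
#'   table), `doa_model`, `classifier`, `config`. When `out_dir` is set,
#'   `results_long.csv`, `results_summary.csv` and `run_log.txt` are
#'   written there.
#' @export
run_experiment <- function(config, doa_model = NULL, classifier = NULL,
                           verbose = TRUE) {
  if (!inherits(config, "experiment_config")) config <- validate_config(config)
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("[%5.1fs] %s", as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   sprintf(fmt, ...))
    if (verbose) message(msg)
    log_lines <<- c(log_lines, msg)
  }
  geometry <- bte_geometry()
  say("config: seed=%d, %d utterances x %d SNRs x %d rooms x %d noise kinds",
      config$seed, config$n_utterances, length(config$snrs_db),
      length(config$rooms), length(config$noise_kinds))

  if (is.null(classifier)) {
    say("training phoneme classifier (%g s synthetic stream)", config$classifier_train_s)
    classifier <- train_default_phoneme_classifier(
      train_s = config$classifier_train_s, hidden = config$classifier_hidden,
      maxit = config$classifier_maxit, seed = sub_seed(config$seed, 102))
  }
  if (is.null(doa_model)) {
    say("training DOA model (19 sectors, SNRs -15/0/+15 dB, %d-member bag)",
        config$doa_members)
    sys <- train_localization_system(geometry, seed = config$seed,
                                     n_members = config$doa_members,
                                     classifier = classifier)
    doa_model <- sys$doa_model
  }
  provider <- function(x) posteriors(classifier, x, geometry$sample_rate)
  filters <- NULL
  if ("map" %in% config$measures) {
    say("learning matched phoneme filters from clean synthetic stream")
    inv <- phone_inventory()
    stream <- synth_phone_stream(inv, 60, geometry$sample_rate,
                                 seed = sub_seed(config$seed, 103))
    pg <- synth_posteriorgram(stream$frame_labels, class_labels = inv$label)
    filters <- learn_map_filters(pg, stream$frame_labels)
  }
  steering <- steering_vectors(geometry)
  iso <- isotropic_covariance(steering_vectors(geometry, seq(0, 355, by = 5)))
  bank <- beamformer_bank(steering, iso)

  scenes <- scene_grid(n_utterances = config$n_utterances,
                       snrs_db = config$snrs_db, rooms = config$rooms,
                       noise_kinds = config$noise_kinds,
                       target_azimuth_deg = config$target_azimuth_deg,
                       interferer_azimuth_deg = config$interferer_azimuth_deg,
                       duration_s = config$duration_s,
                       seed = sub_seed(config$seed, 104))
  say("evaluating %d scenes", length(scenes))
  long <- evaluate_methods(scenes, doa_model, bank, provider,
                           measures = config$measures, geometry = geometry,
                           filters = filters)
  summary <- summarize_hit_rates(long)
  say("done: %d scene records", length(unique(long$scene)))
  if (!is.na(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(long, file.path(config$out_dir, "results_long.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(config$out_dir, "results_summary.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }
  list(long = long, summary = summary, doa_model = doa_model,
       classifier = classifier, config = config, log = log_lines)
}
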