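# Single-ended ASR-based speech quality measures computed on phoneme
# posteriorgrams: the M-Measure (mean temporal divergence), matched
# phoneme (MaP) filtering with event counting, and inverse entropy.

#' M-Measure configuration
#'
#' @param delta_grid_ms temporal distances in ms (default 50..800 step 50).
#' @param epsilon probability floor applied before the divergence.
#' @param divergence `"symmetric_kl"` (mean of both KL directions,
#'   default) or `"kl"` (forward KL of the earlier frame from the later).
#' @return a list of class `mm_config`.
#' @export
mm_config <- function(delta_grid_ms = seq(50, 800, by = 50), epsilon = 1e-10,
                      divergence = c("symmetric_kl", "kl")) {
  if (any(delta_grid_ms <= 0)) stop("all delta values must be > 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(delta_grid_ms = delta_grid_ms, epsilon = epsilon,
                 divergence = match.arg(divergence)),
            class = "mm_config")
}

# KL divergence D(p || q) in bits, rows of floored/renormalized matrices.
kl_rows <- function(P, Q) rowSums(P * (log2(P) - log2(Q)))

#' M-Measure of a posteriorgram
#'
#' For each temporal distance `dt` in the grid computes the mean
#' divergence between posterior vectors `dt` apart,
#' `M(dt) = 1/(T - dt) * sum_t D(P(t - dt), P(t))`, and returns the mean
#' of `M(dt)` over the grid as the utterance-level scalar. Degraded
#' (temporally smeared, less sparse) posteriorgrams yield lower values.
#'
#' Posteriorgrams shorter than the largest grid distance are scored on
#' the feasible part of the grid and flagged (`restricted_grid`).
#'
#' @param pg a [posteriorgram()].
#' @param config an [mm_config()].
#' @return object of class `asqm_result` with `measure = "MM"`, scalar
#'   `value` and the per-distance curve in `diagnostics`.
#' @export
m_measure <- function(pg, config = mm_config()) {
  P <- pmax(pg$probs, config$epsilon)
  P <- P / rowSums(P)
  n <- nrow(P)
  lags <- unique(pmax(1L, round(config$delta_grid_ms / (pg$hop_s * 1000))))
  feasible <- lags[lags < n]
  if (!length(feasible)) stop("posteriorgram shorter than the smallest temporal distance")
  restricted <- length(feasible) < length(lags)
  curve <- vapply(feasible, function(L) {
    A <- P[seq_len(n - L), , drop = FALSE]
    B <- P[(L + 1):n, , drop = FALSE]
    d <- switch(config$divergence,
                kl = kl_rows(A, B),
                symmetric_kl = 0.5 * (kl_rows(A, B) + kl_rows(B, A)))
    mean(d)
  }, numeric(1))
  structure(list(measure = "MM", value = mean(curve),
                 diagnostics = list(delta_frames = feasible, curve = curve,
                                    restricted_grid = restricted)),
            class = "asqm_result")
}

#' @export
print.asqm_result <- function(x, ...) {
  cat(sprintf("asqm_result [%s]: %.6g\n", x$measure, x$value))
  invisible(x)
}

#' Learn matched phoneme filters from clean posteriorgrams
#'
#' For each phone class, collects all its occurrences (runs of identical
#' frame labels) in the clean data, centers each occurrence's activation
#' trace on its midpoint, averages the traces over occurrences, and
#' stores the time-reversed average as the filter. Each filter's
#' normalization constant is chosen so that convolving the filter with
#' the class's average clean trace peaks at exactly 1.
#'
#' @param pgs list of clean [posteriorgram()]s.
#' @param labels list of frame-label vectors aligned with `pgs`.
#' @param support_frames filter length in frames (default 51, i.e. 510 ms).
#' @return object of class `matched_filter_set`: `filters`
#'   (support x classes matrix, normalization folded in), `class_labels`,
#'   `support_frames`.
#' @export
learn_map_filters <- function(pgs, labels, support_frames = 51) {
  if (inherits(pgs, "posteriorgram")) { pgs <- list(pgs); labels <- list(labels) }
  classes <- pgs[[1]]$class_labels
  half <- support_frames %/% 2
  acc <- matrix(0, support_frames, length(classes), dimnames = list(NULL, classes))
  counts <- stats::setNames(numeric(length(classes)), classes)
  for (u in seq_along(pgs)) {
    P <- pgs[[u]]$probs
    lab <- as.character(labels[[u]])
    if (length(lab) != nrow(P)) stop("labels must align with posteriorgram frames")
    runs <- rle(lab)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in seq_along(runs$values)) {
      cl <- runs$values[r]
      if (!cl %in% classes) next
      mid <- (starts[r] + ends[r]) %/% 2
      idx <- (mid - half):(mid + half)
      tr <- numeric(support_frames)
      ok <- idx >= 1 & idx <= nrow(P)
      tr[ok] <- P[idx[ok], cl]
      acc[, cl] <- acc[, cl] + tr
      counts[cl] <- counts[cl] + 1
    }
  }
  missing <- classes[counts == 0]
  if (length(missing)) stop("class(es) with no occurrences: ",
                            paste(missing, collapse = ", "))
  filters <- acc
  for (cl in classes) {
    avg <- acc[, cl] / counts[cl]
    h <- rev(avg)
    peak <- max(fft_conv(h, avg))
    filters[, cl] <- h / peak
  }
  structure(list(filters = filters, class_labels = classes,
                 support_frames = support_frames),
            class = "matched_filter_set")
}

#' Count phonetic events by matched filtering
#'
#' Convolves each class's activation trace with its learned filter and
#' counts local maxima strictly above the threshold, enforcing a minimum
#' peak separation of half the filter support. The utterance-level
#' scalar is the total event count over all classes.
#'
#' @param pg a [posteriorgram()].
#' @param filters a [learn_map_filters()] set covering the classes of `pg`.
#' @param threshold event threshold on the filter output (default 0.5).
#' @return object of class `asqm_result` with `measure = "MaP"`, integer
#'   `value` and per-class counts in `diagnostics`.
#' @export
map_events <- function(pg, filters, threshold = 0.5) {
  if (!all(pg$class_labels %in% filters$class_labels)) {
    stop("filter set does not cover the posteriorgram classes")
  }
  half <- filters$support_frames %/% 2
  min_sep <- max(1L, filters$support_frames %/% 2)
  counts <- stats::setNames(integer(length(pg$class_labels)), pg$class_labels)
  for (cl in pg$class_labels) {
    a <- pg$probs[, cl]
    y <- fft_conv(a, filters$filters[, cl])
    # "same" alignment: the filter is centered on the activation
    y <- y[half + seq_len(length(a))]
    counts[cl] <- count_peaks(y, threshold, min_sep)
  }
  structure(list(measure = "MaP", value = sum(counts),
                 diagnostics = list(per_class = counts, threshold = threshold)),
            class = "asqm_result")
}

# Local maxima strictly above `threshold`, at least `min_sep` frames
# apart (greedy, highest first).
count_peaks <- function(y, threshold, min_sep) {
  n <- length(y)
  if (n < 3L) return(sum(y > threshold) > 0)
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n] &
                     y[2:(n - 1)] > threshold) + 1L
  if (!length(is_peak)) return(0L)
  ord <- is_peak[order(y[is_peak], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  length(kept)
}

#' Inverse entropy of a posteriorgram
#'
#' Computes the average frame-wise entropy
#' `Hbar = (1/T) sum_t sum_ph -P_ph(t) log2 P_ph(t)` (with 0 log 0 = 0)
#' and returns its negation as the quality scalar, so that cleaner
#' (sparser) posteriorgrams score higher. Any strictly decreasing
#' transform of the entropy gives identical downstream direction
#' estimates; the negation is used here, the reciprocal is available via
#' `transform = "reciprocal"` (with a floor for zero entropy).
#'
#' @param pg a [posteriorgram()].
#' @param tol row-normalization tolerance.
#' @param transform `"negation"` (default) or `"reciprocal"`.
#' @return object of class `asqm_result` with `measure = "iEnt"`, scalar
#'   `value` and the per-frame entropies plus `mean_entropy_bits` in
#'   `diagnostics`.
#' @export
inverse_entropy <- function(pg, tol = 1e-4, transform = c("negation", "reciprocal")) {
  transform <- match.arg(transform)
  rs <- rowSums(pg$probs)
  if (any(abs(rs - 1) > tol)) stop("posteriorgram rows are not normalized")
  P <- pg$probs
  Hl <- -P * log2(P)
  Hl[P == 0] <- 0
  H <- rowSums(Hl)
  hbar <- mean(H)
  value <- if (transform == "negation") -hbar else 1 / max(hbar, 1e-12)
  structure(list(measure = "iEnt", value = value,
                 diagnostics = list(frame_entropy = H, mean_entropy_bits = hbar)),
            class = "asqm_result")
}

#' Direction-dependent ASQM profile
#'
#' Applies a posteriorgram provider to each beamformed sector signal and
#' scores it with the chosen measure, yielding one ASQM scalar per
#' steering sector.
#'
#' @param beamformed named list of single-channel signals (one per
#'   sector), e.g. from [beamform_all()].
#' @param azimuth_grid numeric sector azimuths (default: parsed from the
#'   list names).
#' @param provider function mapping a waveform to a [posteriorgram()],
#'   e.g. `function(x) posteriors(classifier, x)`.
#' @param measure `"mm"`, `"map"` or `"ient"`.
#' @param config an [mm_config()] (for `"mm"`).
#' @param filters a [learn_map_filters()] set (for `"map"`).
#' @return a [direction_profile()] with semantics `"ASQM"`.
#' @export
asqm_profile <- function(beamformed, provider, measure = c("mm", "map", "ient"),
                         azimuth_grid = as.numeric(names(beamformed)),
                         config = mm_config(), filters = NULL) {
  measure <- match.arg(measure)
  if (length(beamformed) < 2L) stop("need at least 2 sectors")
  vals <- vapply(seq_along(beamformed), function(i) {
    res <- tryCatch({
      pg <- provider(beamformed[[i]])
      switch(measure,
             mm = m_measure(pg, config),
             map = map_events(pg, filters),
             ient = inverse_entropy(pg))
    }, error = function(e) {
      stop(sprintf("sector %g deg: %s", azimuth_grid[i], conditionMessage(e)),
           call. = FALSE)
    })
    res$value
  }, numeric(1))
  direction_profile(vals, azimuth_grid, semantics = "ASQM")
}
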