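# Phoneme posteriorgrams: log-mel features with context stacking, a
# small trainable softmax classifier, a fully synthetic posteriorgram
# generator, and triphone-to-monophone grouping. The classifier path and
# the synthetic path emit the same `posteriorgram` object, so the speech
# quality measures are testable without any trained model.

#' Posteriorgram container
#'
#' A frames x classes matrix of per-frame class probabilities; every row
#' sums to 1.
#'
#' @param probs frames x classes matrix.
#' @param class_labels character vector of class names.
#' @param hop_s frame hop in seconds (default 0.010).
#' @param tol row-sum tolerance.
#' @return an object of class `posteriorgram`.
#' @export
posteriorgram <- function(probs, class_labels = colnames(probs), hop_s = 0.010,
                          tol = 1e-6) {
  probs <- as.matrix(probs)
  if (is.null(class_labels)) class_labels <- paste0("c", seq_len(ncol(probs)))
  if (any(probs < -tol) || any(probs > 1 + tol)) stop("probabilities outside [0, 1]")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > tol)) {
    stop(sprintf("rows must sum to 1 (worst deviation %.3g)", max(abs(rs - 1))))
  }
  colnames(probs) <- class_labels
  structure(list(probs = probs, class_labels = class_labels, hop_s = hop_s),
            class = "posteriorgram")
}

#' @export
print.posteriorgram <- function(x, ...) {
  cat(sprintf("posteriorgram: %d frames x %d classes (%.2f s at %g ms hop)\n",
              nrow(x$probs), ncol(x$probs), nrow(x$probs) * x$hop_s, x$hop_s * 1000))
  invisible(x)
}

# HTK mel scale.
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters equidistant on the HTK mel scale.
#'
#' @param n_mels number of filters (default 40).
#' @param n_fft FFT size (default 512).
#' @param sample_rate sampling rate in Hz.
#' @param fmin,fmax band edges in Hz.
#' @return `n_mels` x `(n_fft/2 + 1)` matrix.
#' @export
mel_filterbank <- function(n_mels = 40, n_fft = 512, sample_rate = 16000,
                           fmin = 64, fmax = sample_rate / 2) {
  nb <- n_fft %/% 2 + 1L
  freqs <- seq(0, sample_rate / 2, length.out = nb)
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2))
  fb <- matrix(0, n_mels, nb)
  for (i in seq_len(n_mels)) {
    lo <- edges[i]; ce <- edges[i + 1]; hi <- edges[i + 2]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, dn))
  }
  attr(fb, "center_hz") <- edges[2:(n_mels + 1)]
  fb
}

#' Log-mel filterbank features
#'
#' 25 ms Hamming windows with a 10 ms shift, 512-bin magnitude spectra,
#' 40 triangular mel filters, log of the filter outputs with a floor.
#'
#' @param x numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param n_mels,n_fft,win_s,hop_s feature parameters.
#' @param log_floor floor applied before the log.
#' @return frames x `n_mels` matrix of log filter outputs, with the frame
#'   hop attached as attribute `"hop_s"`.
#' @export
logmel <- function(x, sample_rate = 16000, n_mels = 40, n_fft = 512,
                   win_s = 0.025, hop_s = 0.010, log_floor = 1e-10) {
  win <- round(win_s * sample_rate)
  hop <- round(hop_s * sample_rate)
  if (length(x) < win) stop("input shorter than one analysis window")
  n_frames <- (length(x) - win) %/% hop + 1L
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1)) / (win - 1))  # Hamming
  fb <- mel_filterbank(n_mels, n_fft, sample_rate)
  nb <- n_fft %/% 2 + 1L
  out <- matrix(0, n_frames, n_mels)
  for (t in seq_len(n_frames)) {
    seg <- x[(t - 1L) * hop + seq_len(win)] * w
    mag <- Mod(stats::fft(c(seg, numeric(n_fft - win)))[seq_len(nb)])
    out[t, ] <- log(pmax(fb %*% mag, log_floor))
  }
  attr(out, "hop_s") <- hop_s
  out
}

#' Stack temporal context frames
#'
#' Concatenates each feature frame with its `left` preceding and `right`
#' following frames; edges are padded by replicating the first/last
#' frame. With the 40-dimensional default features and left = right = 5
#' this yields 440-dimensional vectors.
#'
#' @param features frames x dim matrix.
#' @param left,right context sizes (>= 0).
#' @return frames x `dim * (left + right + 1)` matrix.
#' @export
stack_context <- function(features, left = 5, right = 5) {
  if (left < 0 || right < 0) stop("context sizes must be >= 0")
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 1L) stop("no frames")
  idx <- lapply(-left:right, function(o) pmin(pmax(seq_len(n) + o, 1L), n))
  do.call(cbind, lapply(idx, function(i) features[i, , drop = FALSE]))
}

#' Synthetic phone inventory
#'
#' A silence class plus `n_classes` speech-like classes, each with a
#' distinct deterministic spectral template: voiced classes are rendered
#' as pulse trains through two formant-like resonances, unvoiced classes
#' as band-passed noise bursts.
#'
#' @param n_classes number of speech classes (default 40).
#' @return object of class `phone_inventory`: data.frame with `label`,
#'   `voiced`, `f0`, `f1`, `f2`.
#' @export
phone_inventory <- function(n_classes = 40) {
  i <- seq_len(n_classes)
  tbl <- data.frame(
    label = sprintf("p%02d", i),
    voiced = (i %% 3) != 0,
    f0 = 90 + (i * 13) %% 90,
    f1 = 280 + (i * 157) %% 700,
    f2 = 1000 + (i * 331) %% 2600)
  tbl <- rbind(data.frame(label = "sil", voiced = FALSE, f0 = 0, f1 = 0, f2 = 0), tbl)
  structure(tbl, class = c("phone_inventory", "data.frame"))
}

#' Synthetic phone stream with frame labels
#'
#' Draws a random phone sequence from the inventory (silence included)
#' with uniform 40-200 ms durations, renders each phone from its spectral
#' template and returns the waveform together with one class label per
#' 10 ms analysis frame (aligned with [logmel()] framing).
#'
#' @param inventory a [phone_inventory()].
#' @param duration_s total duration in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param seed integer RNG seed.
#' @param hop_s,win_s label/frame alignment parameters (match [logmel()]).
#' @return list with `waveform` and `frame_labels` (character).
#' @export
synth_phone_stream <- function(inventory, duration_s, sample_rate = 16000,
                               seed = 1, hop_s = 0.010, win_s = 0.025) {
  if (nrow(inventory) < 1L) stop("inventory is empty")
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  n <- round(duration_s * sample_rate)
  with_seed(seed, {
    x <- numeric(n)
    seg_label <- integer(n)
    pos <- 1L
    while (pos <= n) {
      ph <- sample.int(nrow(inventory), 1)
      len <- min(n - pos + 1L, round(stats::runif(1, 0.04, 0.2) * sample_rate))
      idx <- pos:(pos + len - 1L)
      row <- inventory[ph, ]
      if (row$label == "sil") {
        seg <- 1e-4 * stats::rnorm(len)
      } else if (row$voiced) {
        period <- round(sample_rate / row$f0)
        exc <- numeric(len)
        exc[seq(1, len, by = period)] <- 1
        seg <- resonator(resonator(exc, row$f1, 90, sample_rate), row$f2, 140, sample_rate)
        seg <- seg / max(1e-12, stats::sd(seg), na.rm = TRUE)
      } else {
        seg <- resonator(stats::rnorm(len), row$f2, 400, sample_rate)
        seg <- seg / max(1e-12, stats::sd(seg), na.rm = TRUE)
      }
      x[idx] <- seg
      seg_label[idx] <- ph
      pos <- pos + len
    }
    win <- round(win_s * sample_rate)
    hop <- round(hop_s * sample_rate)
    n_frames <- (n - win) %/% hop + 1L
    centers <- (seq_len(n_frames) - 1L) * hop + win %/% 2
    list(waveform = x, frame_labels = inventory$label[seg_label[centers]])
  })
}

#' Train the phoneme classifier
#'
#' A single-hidden-layer feed-forward network with softmax outputs,
#' fitted by cross-entropy (via `nnet`), mapping context-stacked log-mel
#' features to per-frame phone posteriors. Deterministic under `seed`.
#'
#' @param stacked frames x dim matrix from [stack_context()].
#' @param labels character/factor frame labels aligned with rows.
#' @param hidden hidden-layer size (default 16).
#' @param seed integer RNG seed.
#' @param maxit optimizer iterations.
#' @param decay weight decay.
#' @return object of class `phoneme_classifier`.
#' @export
train_phoneme_classifier <- function(stacked, labels, hidden = 16, seed = 1,
                                     maxit = 120, decay = 1e-4) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (nrow(stacked) != length(labels)) stop("labels must align with frames")
  empty <- levels(labels)[table(labels) == 0]
  if (length(empty)) stop("class(es) absent from training data: ",
                          paste(empty, collapse = ", "))
  mu <- colMeans(stacked)
  sdv <- pmax(apply(stacked, 2, stats::sd), 1e-6)
  xs <- sweep(sweep(stacked, 2, mu), 2, sdv, "/")
  fit <- with_seed(seed, nnet::nnet(
    xs, nnet::class.ind(labels), size = hidden, softmax = TRUE,
    maxit = maxit, decay = decay, MaxNWts = 1e6, trace = FALSE))
  structure(list(net = fit, class_labels = levels(labels), mu = mu, sd = sdv,
                 hidden = hidden),
            class = "phoneme_classifier")
}

#' @export
print.phoneme_classifier <- function(x, ...) {
  cat(sprintf("phoneme_classifier: %d classes, %d-dim input, %d hidden units\n",
              length(x$class_labels), length(x$mu), x$hidden))
  invisible(x)
}

#' Posteriorgram from a waveform via the trained classifier
#'
#' Runs [logmel()], [stack_context()] and the classifier's softmax
#' forward pass.
#'
#' @param classifier a [train_phoneme_classifier()] fit.
#' @param x numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param left,right context sizes used at training time.
#' @return a [posteriorgram()].
#' @export
posteriors <- function(classifier, x, sample_rate = 16000, left = 5, right = 5) {
  feats <- stack_context(logmel(x, sample_rate), left, right)
  if (ncol(feats) != length(classifier$mu)) {
    stop("feature dimensionality does not match the classifier")
  }
  xs <- sweep(sweep(feats, 2, classifier$mu), 2, classifier$sd, "/")
  p <- stats::predict(classifier$net, xs)
  p <- pmax(p, 0)
  p <- p / rowSums(p)
  posteriorgram(p, classifier$class_labels)
}

#' Train the default classifier on synthetic phone streams
#'
#' Generates a clean [synth_phone_stream()] of the requested length,
#' plus a block of pure stationary noise (speech-shaped and white, at
#' several levels) labeled as the silence class, and fits
#' [train_phoneme_classifier()] on the stacked log-mel features of
#' both.
#'
#' The noise-as-silence exemplars matter for the downstream quality
#' measures: the in-stream silence segments are near-digital-zero, so a
#' net that never saw louder non-speech can emit unstable, flickering
#' posteriors on noise-dominated input — which would read as high
#' temporal divergence where a degraded signal should read low. With
#' realistic silence exemplars, non-speech input maps stably to the
#' silence class. The phone classes themselves stay clean-trained: the
#' measures need the net to remain *sensitive* to degradation of
#' speech, so no noisy-speech (multi-condition) material is used.
#'
#' @param inventory a [phone_inventory()].
#' @param train_s clean-stream duration in seconds; noise exemplars add
#'   `train_s / 3`.
#' @param sample_rate sampling rate in Hz.
#' @param hidden,maxit classifier settings.
#' @param seed integer RNG seed.
#' @return a `phoneme_classifier`.
#' @export
train_default_phoneme_classifier <- function(inventory = phone_inventory(),
                                             train_s = 60, sample_rate = 16000,
                                             hidden = 16, maxit = 120, seed = 1) {
  stream <- synth_phone_stream(inventory, train_s, sample_rate,
                               seed = sub_seed(seed, 1))
  noise_s <- train_s / 6
  ssn <- speech_shaped_noise(noise_s, sample_rate, seed = sub_seed(seed, 3))
  white <- with_seed(sub_seed(seed, 4), stats::rnorm(round(noise_s * sample_rate)))
  white <- white / sqrt(mean(white^2))
  # phone segments have unit RMS; present each noise at three levels
  nz <- unlist(lapply(c(1, 0.3, 0.1), function(g) c(g * ssn, g * white)))
  nz_frames <- stack_context(logmel(nz, sample_rate))
  feats <- rbind(stack_context(logmel(stream$waveform, sample_rate)), nz_frames)
  labels <- c(stream$frame_labels, rep("sil", nrow(nz_frames)))
  train_phoneme_classifier(feats, labels, hidden = hidden,
                           seed = sub_seed(seed, 2), maxit = maxit)
}

#' Synthetic posteriorgram with controlled degradation
#'
#' Builds the ideal one-hot posteriorgram from a frame-label sequence,
#' mixes it with the uniform distribution (`(1 - delta) P + delta U`) and
#' smears it over time with a normalized Hann kernel of width `smear_ms`,
#' renormalizing rows. Emulates the temporal smearing and loss of
#' sparsity seen in posteriorgrams of degraded speech.
#'
#' @param frame_labels character/factor sequence of frame labels.
#' @param class_labels full class set (default: levels of `frame_labels`).
#' @param delta degradation in [0, 1].
#' @param smear_ms temporal smear width in ms (>= 0).
#' @param hop_s frame hop in seconds.
#' @return a [posteriorgram()].
#' @export
synth_posteriorgram <- function(frame_labels, class_labels = NULL, delta = 0,
                                smear_ms = 0, hop_s = 0.010) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  if (smear_ms < 0) stop("smear_ms must be >= 0")
  f <- factor(frame_labels, levels = class_labels %||% sort(unique(frame_labels)))
  n <- length(f); k <- nlevels(f)
  P <- matrix(0, n, k, dimnames = list(NULL, levels(f)))
  P[cbind(seq_len(n), as.integer(f))] <- 1
  P <- (1 - delta) * P + delta / k
  klen <- round(smear_ms / (hop_s * 1000))
  if (klen >= 2) {
    kern <- hann_periodic(klen + 2)[-1][seq_len(klen)]
    kern <- kern / sum(kern)
    P <- apply(P, 2, function(col) stats::filter(c(rep(col[1], klen), col,
                                                   rep(col[n], klen)),
                                                 kern, sides = 2)[klen + seq_len(n)])
  }
  P <- P / rowSums(P)
  posteriorgram(P, levels(f), hop_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group triphone posteriors into monophones
#'
#' Sums the probabilities of all triphones mapped to the same monophone;
#' row sums are preserved.
#'
#' @param pg a [posteriorgram()] over triphone classes.
#' @param mapping named character vector: `mapping[triphone] = monophone`.
#'   Must cover every class of `pg`.
#' @return a [posteriorgram()] over the monophone classes.
#' @export
group_triphones <- function(pg, mapping) {
  unmapped <- setdiff(pg$class_labels, names(mapping))
  if (length(unmapped)) {
    stop("unmapped class(es): ", paste(utils::head(unmapped, 5), collapse = ", "))
  }
  mono <- mapping[pg$class_labels]
  groups <- sort(unique(mono))
  out <- vapply(groups, function(g)
    rowSums(pg$probs[, mono == g, drop = FALSE]), numeric(nrow(pg$probs)))
  posteriorgram(matrix(out, nrow = nrow(pg$probs), dimnames = list(NULL, groups)),
                groups, pg$hop_s)
}

#' Posteriorgram CSV export / import
#'
#' Plain CSV with class labels as the header and one row per frame; the
#' hop is recorded in a leading comment line.
#'
#' @param pg a [posteriorgram()].
#' @param path file path.
#' @return `read_posteriorgram_csv` returns a [posteriorgram()].
#' @export
write_posteriorgram_csv <- function(pg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hop_s: %g", pg$hop_s), con)
  utils::write.csv(as.data.frame(pg$probs), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posteriorgram_csv
#' @export
read_posteriorgram_csv <- function(path) {
  first <- readLines(path, n = 1)
  hop <- as.numeric(sub("# hop_s:\\s*", "", first))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  posteriorgram(as.matrix(df), colnames(df), hop)
}

#' Save / load the phoneme classifier
#'
#' Plain-text container holding the class labels, normalization
#' statistics, architecture and flattened network weights.
#'
#' @param classifier a `phoneme_classifier`.
#' @param path file path.
#' @return `load_phoneme_classifier` returns a `phoneme_classifier`.
#' @export
save_phoneme_classifier <- function(classifier, path) {
  lines <- c(
    sprintf("classes: %s", paste(classifier$class_labels, collapse = " ")),
    sprintf("hidden: %d", classifier$hidden),
    sprintf("n_inputs: %d", length(classifier$mu)),
    sprintf("n_nnet_n: %s", paste(classifier$net$n, collapse = " ")),
    sprintf("mu: %s", paste(format(classifier$mu, digits = 17), collapse = " ")),
    sprintf("sd: %s", paste(format(classifier$sd, digits = 17), collapse = " ")),
    sprintf("wts: %s", paste(format(classifier$net$wts, digits = 17), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_phoneme_classifier
#' @export
load_phoneme_classifier <- function(path) {
  lines <- readLines(path)
  val <- function(key) strsplit(trimws(sub("^[^:]+:", "",
                                           grep(paste0("^", key, ":"), lines,
                                                value = TRUE)[1])), "\\s+")[[1]]
  classes <- val("classes")
  nn <- as.integer(val("n_nnet_n"))
  mu <- as.numeric(val("mu"))
  sdv <- as.numeric(val("sd"))
  wts <- as.numeric(val("wts"))
  # rebuild a minimal nnet object that predict.nnet accepts
  k <- nn[3]
  skel <- with_seed(1, nnet::nnet(matrix(stats::rnorm(2 * k * nn[1]), 2 * k),
                                  rbind(diag(k), diag(k)),
                                  size = nn[2], softmax = TRUE, maxit = 0,
                                  MaxNWts = 1e6, trace = FALSE))
  skel$wts <- wts
  skel$n <- nn
  structure(list(net = skel, class_labels = classes, mu = mu, sd = sdv,
                 hidden = nn[2]),
            class = "phoneme_classifier")
}
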