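test_that("GCC-PHAT self-correlation concentrates at lag zero", {
  set.seed(1)
  f <- rnorm(400) * spatialspeech:::hann_periodic(400)
  r <- gcc_phat_pair(f, f, 8)
  expect_equal(r[9], 1, tolerance = 1e-6)
  expect_lt(max(abs(r[-9])), 1e-6)
})

test_that("GCC-PHAT locates a circular delay like direct cross-correlation", {
  set.seed(2)
  f <- rnorm(512)
  for (d in c(2, 3, 5)) {
    g <- c(utils::tail(f, d), utils::head(f, -d))
    r <- gcc_phat_pair(f, g, 8, nfft = 512)
    lags <- -8:8
    # oracle: argmax of the direct circular cross-correlation
    # sum_i f[i] g[i - L], matching the e^{i w tau} inverse-transform
    # convention of the GCC definition
    oracle <- sapply(lags, function(L) {
      n <- length(g)
      idx <- ((seq_len(n) - 1 - L) %% n) + 1
      sum(f * g[idx])
    })
    expect_identical(lags[which.max(r)], lags[which.max(oracle)])
  }
})

test_that("zero frames yield a flagged all-zero GCC vector", {
  r <- gcc_phat_pair(numeric(400), numeric(400), 8)
  expect_true(all(r == 0))
  expect_true(attr(r, "degenerate"))
})

test_that("feature layout follows the pair/lag arithmetic", {
  set.seed(3)
  g4 <- array_geometry(cbind(runif(4, -0.05, 0.05), runif(4, -0.09, 0.09), 0))
  sig <- mc_signal(matrix(rnorm(4 * 8000), 4), g4)
  fe <- extract_features(sig, tau_max = 16)
  expect_identical(ncol(fe$values), 6L * 33L)  # C(4,2) pairs x (2*16+1) lags
  g6 <- bte_geometry()
  sig6 <- spatialize(rnorm(8000), 10, g6)
  fe6 <- extract_features(sig6, channel_subset = 1:6)
  expect_identical(nrow(fe6$pair_layout), 15L)  # C(6, 2)
})

test_that("features are invariant to overall gain (PHAT normalization)", {
  g <- bte_geometry()
  set.seed(4)
  sig <- spatialize(rnorm(6000), -20, g)
  f1 <- extract_features(sig)
  sig2 <- mc_signal(sig$samples * 37.5, g)
  f2 <- extract_features(sig2)
  expect_equal(f1$values, f2$values, tolerance = 1e-9)
})

test_that("permuting the channel subset relabels pairs but keeps the values", {
  g <- bte_geometry()
  set.seed(5)
  sig <- spatialize(rnorm(6000), 30, g)
  fa <- extract_features(sig, channel_subset = c(1, 3, 4, 6))
  fb <- extract_features(sig, channel_subset = c(6, 4, 3, 1))
  expect_identical(fa$pair_layout, fb$pair_layout)  # canonical ordering
  expect_equal(fa$values, fb$values)
})

test_that("a two-sector model separates well-spaced sources almost perfectly", {
  g <- bte_geometry()
  # target-active frames only: silent-gap frames carry no directional cue
  mk <- function(az, seed) {
    src <- synth_speechlike(2, 16000, seed = seed)
    target <- spatialize(src, az, g)
    mixed <- mix_at_snr(target, diffuse_noise(2, g, seed = seed + 50), 15)
    feats <- extract_features(mixed)
    centers <- (seq_len(nrow(feats$values)) - 1L) * 160L + 200L
    mask <- spatialspeech:::active_sample_mask(target$samples[1, ], 16000)
    feats$values[mask[centers], , drop = FALSE]
  }
  tr_a <- rbind(mk(-60, 1), mk(-60, 11)); tr_b <- rbind(mk(60, 2), mk(60, 12))
  train <- rbind(tr_a, tr_b)
  labs <- c(rep(-60, nrow(tr_a)), rep(60, nrow(tr_b)))
  model <- train_doa_model(train, labs)
  ta <- mk(-60, 3); tb <- mk(60, 4)
  test_feats <- rbind(ta, tb)
  D <- test_feats %*% t(model$weights) + rep(model$biases, each = nrow(test_feats))
  pred <- model$azimuth_grid[max.col(D)]
  truth <- c(rep(-60, nrow(ta)), rep(60, nrow(tb)))
  expect_gte(mean(pred == truth), 0.95)
  # calibrated logistic: exactly 0.5 at D = -beta1/beta2, correct limits
  b <- model$calibration
  expect_equal(plogis(b[1] + b[2] * (-b[1] / b[2])), 0.5, ignore_attr = TRUE)
  expect_gt(b[2], 0)
  expect_error(train_doa_model(train, labs, azimuth_grid = c(-60, 0, 60)),
               "no training examples")
})

test_that("probability maps are proper probabilities and average correctly", {
  model <- fixture_doa_model()
  g <- bte_geometry()
  sc <- build_scene(scene_spec(snr_db = 10, duration_s = 1.5, seed = 31))
  pm <- probability_map(sc$signal, model)
  expect_true(all(pm$probs > 0 & pm$probs < 1))
  prof <- average_map(pm)
  # oracle: explicit loop-based time average
  oracle <- apply(pm$probs, 1, function(r) sum(r) / length(r))
  expect_equal(prof$values, unname(oracle), tolerance = 1e-12)
  # two-frame arithmetic-mean contract
  pm2 <- pm; pm2$probs <- matrix(c(0.2, 0.8), 1, 2)
  pm2$azimuth_grid <- 0
  expect_equal(average_map(pm2)$values, 0.5)
})

test_that("the localizer recovers a speech source in diffuse noise", {
  model <- fixture_doa_model()
  hits <- 0L
  snrs <- c(0, 5, 10, 15, 20, 0, 5, 10, 15, 20)
  for (i in seq_along(snrs)) {
    sc <- build_scene(scene_spec(snr_db = snrs[i], duration_s = 2, seed = 400 + i))
    est <- estimate_direction(average_map(probability_map(sc$signal, model)))
    hits <- hits + (est == -30)
  }
  expect_gte(hits, 9L)
})

test_that("pure diffuse noise produces no confident sector", {
  model <- fixture_doa_model()
  g <- bte_geometry()
  noise <- diffuse_noise(2, g, seed = 77)
  prof <- average_map(probability_map(noise, model))
  expect_lt(max(prof$values), 0.9)
})

test_that("DOA models survive a save/load round-trip", {
  model <- fixture_doa_model()
  path <- tempfile(fileext = ".txt")
  save_doa_model(model, path)
  m2 <- load_doa_model(path)
  expect_equal(m2$weights, model$weights, tolerance = 1e-12)
  expect_equal(m2$calibration, model$calibration, tolerance = 1e-12)
  sc <- build_scene(scene_spec(snr_db = 15, duration_s = 1, seed = 9))
  expect_equal(probability_map(sc$signal, m2)$probs,
               probability_map(sc$signal, model)$probs, tolerance = 1e-9)
})

test_that("feature-layout mismatches are rejected", {
  model <- fixture_doa_model()
  g3 <- array_geometry(cbind(runif(3, -0.05, 0.05), runif(3, -0.09, 0.09), 0))
  sig <- mc_signal(matrix(rnorm(3 * 8000), 3), g3)
  m2 <- model
  m2$feature_meta$channel_subset <- 1:3
  expect_error(probability_map(sig, m2), "layout")
})
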