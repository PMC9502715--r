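test_that("spatialize reproduces plane-wave delays (cross-correlation oracle)", {
  set.seed(1)
  two <- array_geometry(rbind(c(0, 0.09, 0), c(0, -0.09, 0)))
  src <- rnorm(16000)
  for (az in c(-30, 20, 60)) {
    s <- spatialize(src, az, two, head_shadow = FALSE)
    cc <- ccf(s$samples[1, ], s$samples[2, ], lag.max = 20, plot = FALSE)
    lag_meas <- cc$lag[which.max(cc$acf)]
    d <- plane_wave_delays(two, az) * 16000
    expect_lte(abs(lag_meas - (d[1] - d[2])), 1)
  }
})

test_that("frontal source arrives simultaneously at mirrored microphones", {
  set.seed(2)
  g <- bte_geometry()
  s <- spatialize(rnorm(8000), 0, g, head_shadow = FALSE)
  # left-front (1) and right-front (4) are mirror images
  cc <- ccf(s$samples[1, ], s$samples[4, ], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("pure fractional delay preserves energy and determinism", {
  g <- bte_geometry()
  imp <- numeric(1000); imp[500] <- 1  # mid-signal so sinc tails stay inside
  s <- spatialize(imp, -50, g, head_shadow = FALSE)
  # energy preserved up to the truncated sinc tails of the ideal
  # fractional delay (~1e-4 for a 500-sample half-window)
  for (ch in 1:6) expect_equal(sum(s$samples[ch, ]^2), 1, tolerance = 1e-3)
  expect_error(spatialize(numeric(0), 0, g), "empty")
})

test_that("diffuse field coherence falls with frequency", {
  g <- bte_geometry()
  d <- diffuse_noise(2, g, n_directions = 19, seed = 5)
  expect_identical(nrow(d$samples), 6L)
  # magnitude-squared coherence between the two front mics (0.18 m apart)
  sp <- stats::spec.pgram(cbind(d$samples[1, ], d$samples[4, ]), spans = c(25, 25),
                          taper = 0, plot = FALSE, detrend = FALSE)
  f_hz <- sp$freq * 16000
  low <- mean(sp$coh[f_hz > 150 & f_hz < 350])
  high <- mean(sp$coh[f_hz > 3000 & f_hz < 5000])
  expect_gt(low, high)
  expect_error(diffuse_noise(1, g, n_directions = 1), "n_directions")
})

test_that("mix_at_snr calibrates the reference-channel SNR exactly", {
  g <- bte_geometry()
  target <- spatialize(synth_speechlike(2, 16000, 1), -30, g)
  noise <- diffuse_noise(2, g, seed = 2)
  mixed <- mix_at_snr(target, noise, 0)
  g0 <- attr(mixed, "noise_gain")
  # re-measure achieved SNR over target-active samples on the ref channel
  mask <- spatialspeech:::active_sample_mask(target$samples[1, ], 16000)
  snr <- 10 * log10(mean(target$samples[1, mask]^2) /
                      mean((g0 * noise$samples[1, mask])^2))
  expect_equal(snr, 0, tolerance = 0.01)
  # gain ratio between +20 and -10 dB mixes is 10^(30/20)
  g20 <- attr(mix_at_snr(target, noise, 20), "noise_gain")
  gm10 <- attr(mix_at_snr(target, noise, -10), "noise_gain")
  expect_equal(gm10 / g20, 10^(30 / 20), tolerance = 1e-9)
  silent <- mc_signal(matrix(0, 6, ncol(target$samples)), g)
  expect_error(mix_at_snr(target, silent, 0), "silent")
})

test_that("synthetic reverb has the requested decay and an identity limit", {
  g <- bte_geometry()
  sig <- spatialize(synth_speechlike(0.5, 16000, 1), 0, g)
  expect_identical(apply_reverb(sig, 0)$samples, sig$samples)
  expect_error(apply_reverb(sig, -0.1), "t60")
  # Schroeder backward integration of the tail: -60 dB at t60 +/- 10%
  ir <- reverb_impulse_response(0.5, 16000, seed = 3)
  tail <- ir[-(1:81)]  # drop direct path + gap
  edc <- rev(cumsum(rev(tail^2)))
  edc_db <- 10 * log10(edc / edc[1])
  # fit decay slope between -5 and -35 dB and extrapolate to -60
  idx <- which(edc_db < -5 & edc_db > -35)
  slope <- unname(coef(lm(edc_db[idx] ~ idx))[2])
  t60_est <- (-60 / slope) / 16000
  expect_equal(t60_est, 0.5, tolerance = 0.1)
  expect_identical(reverb_impulse_response(0.5, 16000, seed = 3), ir)
})

test_that("build_scene records ground truth and the grid enumerates fully", {
  sc <- build_scene(scene_spec(snr_db = 20, duration_s = 1, seed = 1))
  expect_identical(sc$truth$target_azimuth_deg, -30)
  expect_true(is.na(sc$truth$interferer_azimuth_deg))
  scl <- build_scene(scene_spec(noise_kind = "localized", snr_db = 5,
                                duration_s = 1, seed = 1))
  expect_identical(scl$truth$interferer_azimuth_deg, 40)
  grid <- scene_grid(n_utterances = 3)
  expect_length(grid, 28 * 3)  # 2 rooms x 2 noise kinds x 7 SNRs
  expect_length(unique(vapply(grid, `[[`, 1L, "seed")), 84L)
})

test_that("scene_spec validates and round-trips through its text format", {
  expect_error(scene_spec(target_azimuth_deg = 120), "frontal")
  expect_error(scene_spec(room = "anechoic", t60_s = 0.3), "t60")
  sp <- scene_spec(noise_kind = "localized", snr_db = -5, room = "reverberant",
                   duration_s = 3, seed = 42)
  path <- tempfile(fileext = ".cfg")
  write_scene_spec(sp, path)
  sp2 <- read_scene_spec(path)
  expect_equal(sp2, sp)
})
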