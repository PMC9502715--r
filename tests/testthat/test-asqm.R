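test_that("M-Measure is zero for time-constant posteriorgrams", {
  P <- matrix(rep(c(0.7, 0.2, 0.1), each = 120), 120, 3)
  pg <- posteriorgram(P, c("a", "b", "c"))
  expect_equal(m_measure(pg)$value, 0, tolerance = 1e-9)
})

test_that("M-Measure matches a brute-force double-loop oracle", {
  kl2 <- function(p, q) sum(p * (log2(p) - log2(q)))
  mm_oracle <- function(P, lags, eps = 1e-10) {
    P <- pmax(P, eps); P <- P / rowSums(P)
    n <- nrow(P)
    curve <- sapply(lags, function(L) {
      acc <- 0
      for (t in (L + 1):n) {
        acc <- acc + 0.5 * (kl2(P[t - L, ], P[t, ]) + kl2(P[t, ], P[t - L, ]))
      }
      acc / (n - L)
    })
    mean(curve)
  }
  for (seed in 1:5) {
    pg <- random_posteriorgram(90, 8, seed)
    cfg <- mm_config(delta_grid_ms = c(50, 100, 250))
    expect_equal(m_measure(pg, cfg)$value, mm_oracle(pg$probs, c(5, 10, 25)),
                 tolerance = 1e-10)
  }
  # alternating two fixed distributions, odd lag -> exactly D(p, q)
  p <- c(0.8, 0.15, 0.05); q <- c(0.1, 0.3, 0.6)
  P <- do.call(rbind, rep(list(p, q), 40))
  pg <- posteriorgram(P, c("a", "b", "c"))
  kl_sym <- 0.5 * (kl2(p, q) + kl2(q, p))
  res <- m_measure(pg, mm_config(delta_grid_ms = c(50)))  # lag 5, odd
  expect_equal(res$value, kl_sym, tolerance = 1e-9)
})

test_that("M-Measure restricts its grid on short utterances and errors on tiny ones", {
  pg <- random_posteriorgram(30, 5, seed = 2)  # 300 ms < 800 ms max lag
  res <- m_measure(pg)
  expect_true(res$diagnostics$restricted_grid)
  tiny <- random_posteriorgram(4, 5, seed = 3)
  expect_error(m_measure(tiny), "shorter")
})

test_that("matched filters learn clean traces and normalize the self-match to 1", {
  # fixed 10-frame rectangular phones
  labs <- rep(rep(c("a", "b", "c"), times = 8), each = 10)
  pg <- synth_posteriorgram(labs)
  fl <- learn_map_filters(pg, labs, support_frames = 21)
  # filter of class "a": ~10-frame rectangle centered in the support
  h <- fl$filters[, "a"]
  expect_true(all(h[6:15] > 0.9 * max(h)))
  expect_lt(max(h[c(1:3, 19:21)]), 0.1 * max(h))
  # convolving with the average clean trace peaks at 1
  avg <- rep(0, 21); avg[6:15] <- 1
  expect_equal(max(spatialspeech:::fft_conv(h, avg)), 1, tolerance = 1e-6)
  expect_identical(fl$filters, learn_map_filters(pg, labs, support_frames = 21)$filters)
  expect_error(learn_map_filters(pg, rep("a", length(labs)), 21), "no occurrences")
})

test_that("event counting follows the threshold and scaling logic", {
  labs <- rep(rep(c("a", "b"), times = 6), each = 10)
  clean <- synth_posteriorgram(labs)
  fl <- learn_map_filters(clean, labs, support_frames = 21)
  # all-zero activations: no events
  zero <- clean; zero$probs[] <- 0; zero$probs[, "b"] <- 1
  one_a <- map_events(zero, fl)$diagnostics$per_class[["a"]]
  expect_identical(one_a, 0L)
  # a single clean rectangular activation of "a" -> exactly 1 event
  single <- matrix(0, 60, 2, dimnames = list(NULL, c("a", "b")))
  single[, "b"] <- 1
  single[26:35, "a"] <- 1; single[26:35, "b"] <- 0
  pg1 <- posteriorgram(single, c("a", "b"))
  expect_identical(map_events(pg1, fl)$diagnostics$per_class[["a"]], 1L)
  # the same activation scaled by 0.4 peaks below threshold -> 0 events
  scaled <- single; scaled[, "a"] <- scaled[, "a"] * 0.4
  scaled[, "b"] <- 1 - scaled[, "a"]
  pg2 <- posteriorgram(scaled, c("a", "b"))
  expect_identical(map_events(pg2, fl)$diagnostics$per_class[["a"]], 0L)
})

test_that("inverse entropy matches the closed forms and a brute-force oracle", {
  one_hot <- synth_posteriorgram(rep(c("a", "b"), 10))
  res <- inverse_entropy(one_hot)
  expect_equal(res$value, 0)
  expect_equal(res$diagnostics$mean_entropy_bits, 0)
  unif <- synth_posteriorgram(rep(c("a", "b", "c", "d"), 5), delta = 1)
  expect_equal(inverse_entropy(unif)$diagnostics$mean_entropy_bits, log2(4),
               tolerance = 1e-12)
  for (seed in 1:5) {
    pg <- random_posteriorgram(50, 7, seed)
    oracle <- 0
    for (t in 1:50) for (k in 1:7) {
      p <- unname(pg$probs[t, k])
      if (p > 0) oracle <- oracle - p * log2(p)
    }
    oracle <- oracle / 50
    expect_equal(inverse_entropy(pg)$diagnostics$mean_entropy_bits, oracle,
                 tolerance = 1e-12)
    expect_equal(inverse_entropy(pg)$value, -oracle, tolerance = 1e-12)
  }
  bad <- random_posteriorgram(10, 4, seed = 6)
  bad$probs <- bad$probs * 1.05
  expect_error(inverse_entropy(bad), "normalized")
  # reciprocal transform induces the same ranking
  a <- random_posteriorgram(40, 6, seed = 7)
  b <- synth_posteriorgram(rep(letters[1:6], length.out = 40), delta = 0.8)
  neg <- c(inverse_entropy(a)$value, inverse_entropy(b)$value)
  rec <- c(inverse_entropy(a, transform = "reciprocal")$value,
           inverse_entropy(b, transform = "reciprocal")$value)
  expect_identical(order(neg), order(rec))
})

test_that("all three measures are invariant to consistent class permutation", {
  set.seed(8)
  labs <- sample(letters[1:5], 80, replace = TRUE)
  pg <- synth_posteriorgram(labs, delta = 0.3, smear_ms = 50)
  fl <- learn_map_filters(synth_posteriorgram(labs), labs, support_frames = 15)
  perm <- sample(5)
  pgp <- posteriorgram(pg$probs[, perm], pg$class_labels[perm])
  flp <- fl
  flp$filters <- fl$filters[, perm]
  flp$class_labels <- fl$class_labels[perm]
  expect_equal(m_measure(pgp)$value, m_measure(pg)$value, tolerance = 1e-12)
  expect_equal(inverse_entropy(pgp)$value, inverse_entropy(pg)$value,
               tolerance = 1e-12)
  expect_identical(map_events(pgp, flp)$value, map_events(pg, fl)$value)
})

test_that("ASQM profiles have one value per sector and detect the speech side", {
  # identical input for every sector -> constant profile
  sigs <- setNames(rep(list(synth_phone_stream(phone_inventory(4), 1, seed = 9)$waveform),
                       5), c(-40, -20, 0, 20, 40))
  prov <- function(x) synth_posteriorgram(
    rep(letters[1:4], length.out = nrow(logmel(x))), delta = 0.2)
  prof <- asqm_profile(sigs, prov, "mm")
  expect_length(prof$values, 5L)
  expect_true(all(abs(prof$values - prof$values[1]) < 1e-12))
})
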