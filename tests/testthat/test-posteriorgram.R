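test_that("log-mel framing and band localization behave as specified", {
  x <- sin(2 * pi * 1000 * seq_len(16000) / 16000)
  fm <- logmel(x)
  expect_identical(nrow(fm), 98L)  # floor((16000 - 400) / 160) + 1
  expect_identical(ncol(fm), 40L)
  # the dominant band of a 1 kHz tone is the filter whose center is nearest
  centers <- attr(mel_filterbank(), "center_hz")
  expect_identical(unique(apply(fm, 1, which.max)), which.min(abs(centers - 1000)))
  expect_true(all(logmel(numeric(400)) == log(1e-10)))
  expect_error(logmel(numeric(100)), "shorter")
})

test_that("context stacking pads edges by replication and widens to 440", {
  set.seed(1)
  fm <- matrix(rnorm(200), 5, 40)
  st <- stack_context(fm)
  expect_identical(ncol(st), 440L)
  expect_identical(stack_context(fm, 0, 0), fm)
  # frame 1: all left context equals the replicated first frame
  expect_equal(st[1, 1:40], st[1, 41:80])
  expect_equal(st[1, 201:240], fm[1, ])
  expect_error(stack_context(fm, -1), "context")
})

test_that("synthetic phone streams align labels with feature frames", {
  inv <- phone_inventory()
  st <- synth_phone_stream(inv, 5, seed = 3)
  expect_identical(length(st$frame_labels), nrow(logmel(st$waveform)))
  expect_identical(st$waveform, synth_phone_stream(inv, 5, seed = 3)$waveform)
  long <- synth_phone_stream(inv, 60, seed = 4)
  expect_true(all(inv$label %in% unique(long$frame_labels)))
})

test_that("a small classifier learns well-separated phones and degrades with noise", {
  inv <- phone_inventory(6)
  train <- synth_phone_stream(inv, 25, seed = 5)
  clf <- train_phoneme_classifier(stack_context(logmel(train$waveform)),
                                  train$frame_labels, hidden = 12, seed = 6)
  test <- synth_phone_stream(inv, 8, seed = 7)
  acc_at <- function(x) {
    pg <- posteriors(clf, x)
    mean(clf$class_labels[max.col(pg$probs)] == test$frame_labels)
  }
  noise <- speech_shaped_noise(8, seed = 8)
  lvl <- function(snr) sqrt(mean(test$waveform^2) / (mean(noise^2) * 10^(snr / 10)))
  acc_clean <- acc_at(test$waveform)
  acc_10 <- acc_at(test$waveform + lvl(10) * noise)
  acc_0 <- acc_at(test$waveform + lvl(0) * noise)
  expect_gte(acc_clean, 0.9)
  expect_gt(acc_clean, acc_10)
  expect_gt(acc_10, acc_0)
  pg <- posteriors(clf, test$waveform)
  expect_equal(rowSums(pg$probs), rep(1, nrow(pg$probs)), tolerance = 1e-9)
})

test_that("classifiers survive a save/load round-trip", {
  inv <- phone_inventory(4)
  train <- synth_phone_stream(inv, 10, seed = 9)
  clf <- train_phoneme_classifier(stack_context(logmel(train$waveform)),
                                  train$frame_labels, hidden = 8, seed = 10)
  path <- tempfile(fileext = ".txt")
  save_phoneme_classifier(clf, path)
  clf2 <- load_phoneme_classifier(path)
  test <- synth_phone_stream(inv, 2, seed = 11)
  expect_equal(posteriors(clf2, test$waveform)$probs,
               posteriors(clf, test$waveform)$probs, tolerance = 1e-10)
})

test_that("synthetic posteriorgrams degrade as advertised", {
  labs <- rep(c("a", "b", "c"), each = 20)
  pg0 <- synth_posteriorgram(labs)
  expect_true(all(pg0$probs %in% c(0, 1)))
  pg1 <- synth_posteriorgram(labs, delta = 1)
  expect_equal(unname(pg1$probs), matrix(1 / 3, 60, 3), tolerance = 1e-12)
  expect_equal(inverse_entropy(pg1)$diagnostics$mean_entropy_bits, log2(3),
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:5) {
    pg <- synth_posteriorgram(labs, delta = runif(1), smear_ms = runif(1, 0, 200))
    expect_equal(rowSums(pg$probs), rep(1, 60), tolerance = 1e-9)
  }
  # sparseness (mean max row entry) strictly decreasing in delta and smear
  sparseness <- function(d, s) mean(apply(synth_posteriorgram(labs, delta = d,
                                                              smear_ms = s)$probs,
                                          1, max))
  sp_d <- vapply(c(0, 0.3, 0.6, 0.9), sparseness, numeric(1), s = 0)
  expect_true(all(diff(sp_d) < 0))
  sp_s <- vapply(c(0, 50, 100, 200), function(s) sparseness(0.2, s), numeric(1))
  expect_true(all(diff(sp_s) < 0))
  expect_error(synth_posteriorgram(labs, delta = 1.2), "delta")
})

test_that("triphone grouping preserves probability mass", {
  set.seed(13)
  n_tri <- 120
  tri <- sprintf("t%03d", seq_len(n_tri))
  mapping <- setNames(sprintf("m%02d", (seq_len(n_tri) - 1) %% 40 + 1), tri)
  P <- matrix(rexp(50 * n_tri), 50, n_tri)
  P <- P / rowSums(P)
  pg <- posteriorgram(P, tri)
  g <- group_triphones(pg, mapping)
  expect_identical(ncol(g$probs), 40L)
  expect_equal(rowSums(g$probs), rep(1, 50), tolerance = 1e-12)
  # identity mapping leaves the posteriorgram unchanged
  id <- setNames(tri, tri)
  expect_equal(group_triphones(pg, id)$probs[, tri], pg$probs, tolerance = 1e-15)
  expect_error(group_triphones(pg, mapping[-1]), "unmapped")
})

test_that("posteriorgram CSV round-trips", {
  pg <- random_posteriorgram(20, 5, seed = 14)
  path <- tempfile(fileext = ".csv")
  write_posteriorgram_csv(pg, path)
  pg2 <- read_posteriorgram_csv(path)
  expect_equal(pg2$probs, pg$probs, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(pg2$hop_s, pg$hop_s)
})
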