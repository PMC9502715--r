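# Shared fixtures, trained once per test run and memoized. Training the
# full 19-sector DOA model and the phoneme classifier takes a few
# minutes; every test that needs them shares the same instance.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

fixture_system <- function() {
  memo("system", function() train_localization_system(seed = 1))
}

fixture_doa_model <- function() fixture_system()$doa_model

fixture_classifier <- function() fixture_system()$classifier

fixture_bank <- function() fixture_system()$bank

fixture_provider <- function() {
  clf <- fixture_classifier()
  function(x) posteriors(clf, x)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

db_pow <- function(db) 10^(db / 10)

# A small random row-stochastic posteriorgram.
random_posteriorgram <- function(n_frames, n_classes, seed) {
  set.seed(seed)
  P <- matrix(stats::rexp(n_frames * n_classes), n_frames, n_classes)
  P <- P / rowSums(P)
  posteriorgram(P, paste0("c", seq_len(n_classes)))
}
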