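# spatialspeech

Spatial detection of a speech source with a binaural hearing-aid
microphone array, for researchers in audio signal processing and
computational audiology.

A classical direction-of-arrival (DOA) estimator has high spatial
resolution but no notion of speech: a loud, weakly modulated broadband
interferer (think vacuum cleaner) captures it even at favorable SNRs. A
speech quality measure computed on beamformed audio knows where the
speech is, but only coarsely. `spatialspeech` implements both streams
and their probabilistic fusion for a 6-microphone behind-the-ear array:

* **DOA stream** — GCC-PHAT features
  `ρ_kl(τ,t) = (1/Ω) Σ_ω Ψ(ω,t) X_k X_l* e^{iωτ}` with PHAT weighting
  `Ψ = 1/|X_k X_l*|`, one linear SVM per 10° sector α ∈ {−90°,…,+90°}
  giving decision values `D(α,t) = ⟨w(α), φ(t)⟩ + b(α)`, calibrated to
  probabilities `P(α,t) = 1/(1 + e^{−(β₁+β₂D)})` and time-averaged to
  `P_DOA(α)`.
* **ASQM stream** — MVDR beamforming
  `w(α,ω) = R⁻¹d / (dᴴR⁻¹d)` against an isotropic noise covariance
  `R(ω) = (1/K) Σ_α d dᴴ` over all 19 sectors; phoneme posteriorgrams
  from a log-mel + softmax classifier; single-ended ASR-based speech
  quality measures (ASQM) per steered sector: M-Measure
  `M(Δt) = 1/(T−Δt) Σ_t D_KL(P_ph(t−Δt), P_ph(t))` averaged over
  Δt = 50…800 ms, matched phoneme (MaP) event counts, or inverse
  entropy; min–max rescaled to `P_ASQM(α)`.
* **Fusion** — `P_s(α) = P_ASQM(α)·P_DOA(α)`, estimate
  `α̂ = argmax_α P_s(α)`, scored by the hit rate over 10° sectors
  (±5° tolerance, chance 1/19 ≈ 5.26%).

A synthetic scene simulator (speech-like modulated source, weakly
modulated broadband interferer, diffuse speech-shaped noise field,
fractional-delay spatialization with optional head shadow, synthetic
reverberation, exact SNR calibration) provides ground truth without any
external corpus, and an experiment pipeline reproduces the qualitative
study design: in diffuse noise the DOA stream alone is essentially
perfect; with a localized weakly modulated interferer the DOA stream
locks onto the interferer and only the fused estimator recovers the
talker.

## Worked example

```r
library(spatialspeech)

geometry <- bte_geometry()

# train everything from one seed: the phoneme classifier, the MVDR bank
# and the bagged 19-sector DOA model (a few minutes)
sys <- train_localization_system(geometry, seed = 1)

# a scene the DOA stream gets wrong: talker at -30 deg, strong weakly
# modulated broadband interferer at +40 deg, 5 dB SNR, anechoic
sc <- build_scene(scene_spec(noise_kind = "localized", snr_db = 5,
                             duration_s = 2.5, seed = 2002), geometry)

p_doa <- average_map(probability_map(sc$signal, sys$doa_model))
estimate_direction(p_doa)
#> [1] 40     # the DOA stream picks the interferer

bf <- beamform_all(sc$signal, sys$bank)            # 19 steered signals
mm <- asqm_profile(bf, function(x) posteriors(sys$classifier, x), "mm")
round(mm$values, 2)
#>  [1] 9.28 3.97 3.23 5.83 7.27 8.68 4.41 1.30 2.95 0.98 1.08 0.25 1.25
#> [14] 0.15 1.24 8.79 6.25 1.84 1.02
# high values sit in the left (speech) quadrant; the interferer-steered
# sector (+40, value 0.15) scores lowest — but the MM profile alone is
# too coarse to name the exact sector:
estimate_direction(mm)
#> [1] -90

p_s <- fuse_profiles(rescale_asqm(mm), p_doa)
estimate_direction(p_s)
#> [1] -30    # fusion recovers the talker exactly
```

The three printed estimates illustrate the division of labor: the DOA
profile is sharp but speech-blind (it reports the interferer at +40°),
the M-Measure profile is speech-sensitive but spatially coarse (it only
says "left quadrant"), and their product names the talker's sector.

`run_experiment(validate_config(list(seed = 1)))` runs the full grid
(utterances × {anechoic, reverberant} × {diffuse, localized} ×
SNR −10…+20 dB) and writes per-scene records plus a hit-rate table per
condition and method (`DOA`, `ASQM_mm`, `DOAxASQM_mm`, …).

A thin CLI wrapping these functions ships in
`inst/scripts/spatialspeech` (subcommands `scene`, `doa-train`,
`doa-map`, `beamform`, `posteriors`, `asqm`, `run-all`).

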