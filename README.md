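# betaSift

Single-trial extraction of post-movement beta oscillations from
multichannel EEG by empirical mode decomposition and spatial-template
matching.

## The problem

Voluntary movement suppresses the sensorimotor beta rhythm (~20 Hz) over
the contralateral motor cortex and is followed, about a second after
movement offset, by a sharp amplitude rebound — the post-movement beta
event-related synchronization (PM-bERS). The rebound is non-phase-locked:
its latency, frequency and amplitude vary across trials, so the
conventional estimate (band-pass in a fixed task band, rectify, average
envelopes over ~100 trials, read off the peak) smears the rebound and
underestimates it. betaSift recovers the **beta rebound (BR)** — the
envelope maximum in the post-movement window (0.5–1.5 s) minus the mean
envelope of the reference window (−3.5 to −2.5 s) — from **each single
trial**, for anyone studying trial-by-trial sensorimotor dynamics or
building BCI-grade features from few trials.

## The method

For one epoch **B** (M × N; M = 32 channels, N = 7000 samples at 1000 Hz,
t = 0 at movement onset):

1. **EMD.** The channel of interest x(t) (C3 for right-hand movement) is
   sifted into intrinsic mode functions c₁..c_J plus a monotonic residue:
   h_k = h_{k−1} − mean[spline envelopes], stopping when
   SD_k = ‖h_{k−1} − h_k‖²/‖h_{k−1}‖² < ε (default 0.2) and the IMF
   definition holds.
2. **Spatial maps.** V_j(i) = corr(b_i, c_j) over channels i — each IMF's
   scalp distribution.
3. **Selection.** ρ_j = corr(V_j, T) against a spatial template T
   (conventional-ERS rebounds per channel); exact 1-D 3-means splits
   ρ₁..ρ_J into high/middle/low groups and the high group s₁ is kept.
4. **Reconstruction.** Σ_{k∈s₁} c_k at the CI, or per channel with
   least-squares weights cov(b_i, c_k)/var(c_k).
5. **Trial-specific band.** The post-movement minus reference amplitude
   spectra; bins above 2·SD of the subtracted spectrum (robust scale) in
   13–30 Hz span the trial's beta band.
6. **Rebound.** Zero-phase Butterworth band-pass, AM rectification
   m(t) = √(x² + H(x)²) with H the Hilbert transform, and the BR at the
   most reactive channel, with its peak latency.

A ground-truth simulator (`simulateSession()`) generates event-locked
32-channel sessions — focal beta source with suppression and jittered
rebound, spatially mixed 1/f background, line noise, drifts, ocular
artifacts — so every stage is testable without any recordings. See the
methods vignette (`vignettes/single-trial-beta.Rmd`) for the model,
parameter meanings and limitations.

## Worked example

```r
library(betaSift)

## 1. simulate a template-generation group and build the spatial template
ers <- lapply(1:2, function(s) {
  cfg <- simConfig(seed = 100 + s, nTrials = 30)
  ses <- simulateSession(cfg)
  clean <- ses$epochs[!ses$truth$artifact]
  conventionalERS(clean, taskBand(clean, "C3"))
})
template <- buildTemplate(ers, "C3")

## 2. simulate a validation session and extract one trial
cfg <- simConfig(seed = 7, nTrials = 40)
session <- simulateSession(cfg)
extractSingleTrial(session$epochs[[1]], template)
#> TrialResult [ok]
#>   selected IMFs: {2} of 8
#>   band: [18, 23] Hz
#>   BR = 5.96 uV at C3, latency 1.28 s

## 3. run the whole session and compare with the conventional method
summary <- runSession(session$epochs, template, keepEnvelopes = TRUE)
#> SessionSummary: 40 trials, 85% usable
#>   single-trial BR: 4.1 +/- 1.78 uV, latency 1.09 +/- 0.285 s
#>   conventional BR: 1.99 uV
#>   Wilcoxon signed-rank: V = 565, p = 2.5e-06

## 4. latency jitter smears the averaged envelope
averagingAttenuation(summary@envelopes, 1000, -4, groupSizes = c(1, 10, 25))$table
#>    k     brUv nGroups
#> 1  1 4.096492      34
#> 2 10 2.247534       3
#> 3 25 2.260375       1
```

Reading the output: trial 1's sensorimotor activity lived in IMF 2 of 8;
its trial-specific band was 18–23 Hz and its rebound 5.96 µV at C3,
peaking 1.28 s after movement onset. Across the session the mean
single-trial rebound (4.1 µV) is about twice the conventional
averaged-ERS value (1.99 µV) — the paired Wilcoxon test confirms the
ordering — and averaging envelopes over 10 or 25 trials before measuring
shrinks the apparent rebound toward the conventional value, which is the
latency-jitter smearing the single-trial method avoids.

A thin command-line front end with `simulate`, `template`, `extract`,
`compare` and `attenuation` verbs lives at `inst/cli/betasift.R`
(`system.file("cli", "betasift.R", package = "betaSift")`).

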