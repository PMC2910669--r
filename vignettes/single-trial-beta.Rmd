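---
title: "Extracting single-trial post-movement beta rebounds with betaSift"
author: "betaSift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting single-trial post-movement beta rebounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Voluntary movements modulate the sensorimotor beta rhythm (~20 Hz) over the
contralateral motor cortex: its amplitude drops in the two seconds before
movement onset and rebounds sharply about a second after it — the
post-movement beta event-related synchronization (PM-bERS). The rebound is
non-phase-locked: its latency, frequency and amplitude vary from trial to
trial, so conventional analysis, which band-pass filters in a fixed band
and averages rectified envelopes across dozens of trials, smears the
rebound and underestimates its amplitude. Any study of trial-by-trial
dynamics — attention, arousal, clinical state — needs the rebound from each
individual trial.

betaSift implements a spatiotemporal single-trial estimator. The key idea
is that empirical mode decomposition (EMD) can split a single channel's
epoch into oscillatory modes without a fixed basis, and that each mode's
*spatial* signature across the other channels reveals whether it comes
from the sensorimotor cortex or from noise (line interference, drifts,
ocular activity), even when temporal waveforms alone are ambiguous.

## The pipeline

For one event-locked epoch `B` (M channels x N samples, time anchored at
movement onset) the pipeline runs:

1. **Artifact gate.** Epochs whose EOG channels reach 100 uV peak
   amplitude are dropped (`rejectArtifactEpoch()`).
2. **EMD of the channel of interest** (C3 for right-hand movements). The
   sifting loop subtracts the mean of the upper and lower natural
   cubic-spline envelopes through the local extrema until the stoppage
   statistic `SD_k = ||h_{k-1} - h_k||^2 / ||h_{k-1}||^2` falls below
   `eps` *and* the candidate satisfies the IMF definition (extrema and
   zero-crossing counts differ by at most one; mean envelope within 5% of
   the peak-to-peak range). IMFs are extracted until the residue is
   monotonic (`emdDecompose()`).
3. **Spatial maps.** Each IMF is correlated with every raw channel,
   giving a per-channel weight vector — its scalp map (`spatialMap()`).
4. **Template matching and selection.** Each map is correlated with a
   spatial template (conventional-ERS beta rebounds per channel, averaged
   over subjects); the correlations are partitioned into highly-,
   middling- and lowly-correlated groups by exact one-dimensional 3-means,
   and the high group is kept (`selectIMFs()`).
5. **Reconstruction.** Selected IMFs are summed (CI mode) or projected
   onto every channel by least squares (multichannel mode,
   `reconstructSignal()`).
6. **Trial-specific band.** The amplitude spectra of the post-movement
   (0.5–1.5 s) and reference (−3.5 to −2.5 s) windows of the
   reconstruction are subtracted; bins above twice the (robustly
   estimated) SD of the subtracted spectrum inside the 13–30 Hz search
   range define the trial's beta band (`trialBand()`).
7. **Envelope and rebound.** The reconstruction is band-pass filtered in
   that band with a zero-phase Butterworth filter, rectified by the AM
   method `m(t) = sqrt(x^2 + H(x)^2)` (Hilbert transform), and the beta
   rebound is the envelope maximum in the post-movement window minus the
   reference-window mean, reported at the channel with the largest
   rebound (`extractSingleTrial()`).

`runSession()` wraps the per-trial loop, computes the conventional
averaged-ERS baseline on the same trials, and tests the single-trial
rebounds against the conventional value with a one-sample Wilcoxon
signed-rank test (exact for n <= 25, normal approximation above).
`averagingAttenuation()` reproduces the latency-jitter smearing
experiment: averaging k single-trial envelopes before measuring the
rebound shrinks it as k grows.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `eps` | 0.2 | sifting stoppage criterion; the classic value. Smaller values oversift and flatten amplitude modulation; larger ones leave mixed modes. |
| `maxSiftIters`, `maxImfs` | 100, 16 | termination guarantees for pathological inputs; the result records whether a cap bit. |
| `search` | 13–30 Hz | band-detection search range: the beta range, excluding the mu rhythm near 10 Hz. |
| `rule` | `two_sd` | detection threshold: 2 SD of the subtracted spectrum; `zscore` (3.09 SD) is the stricter printed alternative. |
| `minBandHz` | 2 | narrower detections are widened symmetrically; with 1-s windows the spectral resolution is 1 Hz, so anything narrower is a single bin. |
| `filterOrder` | 4 | Butterworth band-pass order, applied forward-backward. |
| `post`, `ref` | 0.5–1.5 s, −3.5 to −2.5 s | analysis windows, half-open `[start, end)`. |
| `rhoFloor` | 0.5 | fallback threshold when fewer than three IMFs prevent clustering. |

## Numerical choices

**Time convention.** Sample k maps to `t0Offset + (k-1)/fs`; windows are
half-open, so a 1-s window at 1000 Hz always contains exactly 1000
samples and a 7-s epoch spanning [−4, 3) holds exactly 7000.

**Spline boundaries.** The paperless part of every EMD implementation is
the envelope boundary. betaSift mirror-extends two extrema about each end
of the signal before fitting natural cubic splines; this suppresses the
end swings that would otherwise corrupt the outer fraction of a 7-s
epoch. The compiled path is checked in the test suite against an
independent pure-R spline reference.

**Sifting termination.** The stoppage statistic alone does not guarantee
the extracted component satisfies the IMF definition, so sifting
continues past `SD_k < eps` until the definition check passes (still
capped at `maxSiftIters`). Once the meaningful components are gone, EMD
will happily decompose floating-point jitter riding on the residual trend
into thousands of spurious "extrema"; a component whose peak-to-peak
amplitude falls below 1e-12 of the input's is therefore discarded and the
decomposition stops. Completeness (IMFs + residue = input to relative L2
error 1e-8) is enforced by the `IMFSet` validity check.

**Exact 3-means.** With at most ~16 IMFs per epoch, the 1-D 3-means
partition is found by exhaustive search over contiguous partitions of the
sorted correlations (optimal 1-D clusters are contiguous). This is
globally optimal and deterministic — no random restarts, no seed
sensitivity.

**Detection threshold scale.** The threshold "2 x SD of the subtracted
spectrum" is ambiguous about how the SD is estimated. The sample SD is
inflated by the very rebound bins the threshold is meant to find: with a
5-Hz-wide reactive band inside an 18-bin search range the sample-SD
threshold converges on the signal level itself and detection collapses.
betaSift therefore estimates the scale robustly (1.4826 x median absolute
deviation) by default, which tracks the noise floor; `scaleEstimator =
"sd"` restores the plain estimator, and `sdScope` switches the estimation
range between the search band and the full spectrum. The `zscore` rule
reuses the same scale with the 3.09 multiplier, so it is strictly
stricter and its false-detection rate on rebound-free trials is lower by
construction.

**Band span rule.** Supra-threshold bins need not be contiguous; the band
runs from the lowest to the highest passing bin, and detections narrower
than 2 Hz are widened symmetrically (clamped to the search range).

**Filtering.** `signal::butter` + `signal::filtfilt`. An order-4
band-pass (two poles per edge) is numerically stable even for 2-Hz-wide
bands at fs = 1000 (largest pole modulus ~0.996) and, applied twice,
attenuates more than 30 dB one octave outside the band edges. Higher
orders are unstable for narrow bands in double precision.

**Envelopes.** The analytic signal is computed over the full epoch, not
just the analysis windows, so Hilbert edge transients stay in the outer
0.25 s, which the result marks as edge-unreliable. The rebound may be
negative; it is not clipped at zero, preserving the statistic's
distribution for the signed-rank comparison.

## The simulator: what it emulates, and what it does not

`simulateSession()` generates event-locked 32-channel epochs (10–20
montage plus VEOG/HEOG, 1000 Hz, [−4, 3) s) with full ground truth:

* **Source.** A C3-focal beta source with forward weights that fall off
  as a Gaussian of scalp distance (near zero contralaterally, zero at the
  EOG channels). Its amplitude modulator holds a 2 uV baseline, is
  suppressed by 50% over [−2, 0) s (movement preparation), and carries a
  Gaussian rebound bump (SD 0.3 s) peaking at twice the baseline — post
  amplitude three times baseline — at a latency jittered across trials
  (mean 1.2 s, SD 0.45 s, the jitter magnitude reported for real
  single-trial latencies). Center frequency (SD 1.5 Hz) and amplitude
  (10% lognormal) also jitter per trial.
* **Carrier.** Equal-amplitude random-phase tones spaced 2 Hz apart
  spanning the configured 4-Hz band, normalized to unit mean Hilbert
  envelope. The spacing is two spectral-resolution bins of the 1-s
  analysis windows, so the band's edge bins each carry exactly one tone
  and the injected band has deterministic spectral edges — a stylized
  stand-in for a broadband rhythm that keeps band-recovery experiments
  well-posed. With `bandHz = 0` the carrier is a pure sinusoid and the
  Hilbert envelope equals the modulator exactly, which is the
  configuration used for amplitude-recovery experiments.
* **Noise.** 1/f^1.7 Gaussian background band-limited to 0.5–100 Hz (the
  acquisition band-pass) at 5 uV RMS, 60% of its power spatially mixed
  through eight random scalp patterns (volume conduction makes real EEG
  noise spatially correlated; without this, every noise mode's spatial
  map would be focal at the recording channel and selection would face an
  unrealistically hard contrast), 40% channel-independent; 60 Hz line
  noise (2 uV, common phase, per-channel gain); sub-0.5 Hz drifts
  (10 uV); and, with probability 0.05, a 150 uV ocular transient coupled
  into the EOG and frontal channels. The background level is chosen so
  the sensorimotor rhythm dominates the beta band at C3, as it does over
  motor cortex in artifact-free recordings.

Ground truth records, per trial, the injected band, the drawn latency,
and the rebound amplitude *as the estimator defines it* (modulator
maximum over the post window minus its reference mean): with latency
jitter the bump can fall outside the post window, and an estimator scored
against the nominal bump height would be penalized for the window, not
for its error.

What the simulator does **not** emulate: realistic volume-conduction head
models, the mu rhythm and other rhythmic foci, non-Gaussian muscle
artifacts, electrode drift/popping, or inter-subject montage variation.
Passing the simulation experiments therefore shows the pipeline recovers
what it is designed to recover under the stated statistical structure —
it does not certify performance on any particular real recording.

## Validation experiments

The test suite and `scripts/acceptance.R` rerun, from scratch:

* the worked nine-IMF clustering example (high group = {0.62, 0.81});
* completeness and the IMF definition over random 7000-sample signals;
* two-tone separation (20 Hz + 2 Hz);
* exact-3-means against an independent exhaustive oracle;
* band recovery (injected 18–22 Hz rebound, three times baseline,
  detection within 1 Hz at both edges), with the rebound centered in the
  post-movement window — latency variability is studied separately;
* rebound-amplitude recovery at 1, 2 and 4 uV over baseline with a
  pure-tone carrier (median estimate within 15%);
* envelope fidelity for a Gaussian-modulated carrier (RMS error < 3%);
* the session-level contrast: across simulated sessions (100 trials,
  latency jitter SD 0.45 s) the mean single-trial rebound exceeds the
  conventional averaged-ERS rebound (Wilcoxon p < 0.01), and averaging
  envelopes over 1/10/25/40 trials shrinks the measured rebound
  monotonically;
* template recovery: a template built from four simulated subjects
  correlates r > 0.9 with the true forward weights and captures the
  source-carrying IMF on validation trials.

The acceptance script scales some experiment sizes (sessions of 60
trials, 8 sessions, 20 completeness signals) so a full run stays within a
few minutes on one core; the test suite runs the session experiment at 20
sessions of 100 trials.

## Known limitations

* EMD mode mixing: when the rhythm's envelope passes through nulls, a
  single IMF can splice between the rhythm and co-band noise; the spatial
  selection inherits whatever mixture the IMF carries. Ensemble EMD would
  reduce this and is deliberately out of scope.
* The 2-SD rule's false-detection rate on rebound-free trials is
  substantial at single-trial SNR (reported by the acceptance script);
  no-band flags and the stricter `zscore` rule are the available
  mitigations.
* Trials whose rebound latency falls outside the fixed post-movement
  window under-read by construction; the window is part of the method's
  definition, not an estimation error.
* The template transfers across subjects only insofar as montages match
  label-for-label; re-referencing and montage editing are out of scope.
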