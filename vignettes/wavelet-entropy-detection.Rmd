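---
title: "Wavelet-entropy detection of shadowed breathing targets: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-entropy detection of shadowed breathing targets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioradar)
```

This vignette is the package's account of its science: the signal model,
the statistic, the tunable parameters and why their defaults are what
they are, what the scene simulator does and does not emulate, and the
numerical choices a maintainer would want written down.

## Signal model

A bistatic impulse UWB radar records, per probe pulse, a fast-time
waveform of `nFast = 2048` samples over `fastWindowNs = 60` ns. Sample m
corresponds to a two-way delay τ = m·dt and hence a range
r = c·τ/2, so the record spans 0–9 m. Pulses arrive at
`slowFsHz = 64` samples/s; stacking `durationS = 32` s of them gives the
2048 × 2048 echo matrix (a power of two along slow time, convenient for
the full dyadic DWT).

A stationary breathing person at range r₀ contributes, to rows within the
torso footprint around r₀, a slow-time modulation
a·sin(2π·f·t + φ) with f the respiration rate. The model assumes:

* respiration is narrow-band and quasi-sinusoidal over the record
  (harmonics are negligible at the SNRs of interest);
* targets are stationary: the modulation stays at a fixed range;
* echo amplitude decays as 1/r² and is further multiplied by an
  attenuation factor when the target sits in the shadow cone of a nearer
  body;
* static structure (walls) is constant along slow time;
* receiver noise is zero-mean white Gaussian.

## The pipeline and its parameters

### Preprocessing (`preprocessEcho`)

* **Distance accumulation** (`nRangeBins = 200`): the 2048 fast-time rows
  are partitioned into 200 contiguous blocks (152 of 10 rows, 48 of 11,
  evenly interleaved) and each block is *summed*. Summing, not
  averaging, is deliberate: a torso spans many native fast-time cells,
  so its respiration signature adds coherently within a block while
  noise adds in quadrature — a ~√10 amplitude SNR gain for weak targets.
  The total sample sum is conserved exactly.
* **Clutter removal** (`clutterWindow = 100` slow-time samples): each
  range bin's slow-time signal has its centred moving average
  subtracted; the window shrinks symmetrically at the record edges
  rather than padding, so no data are fabricated. A slow-time-constant
  row maps to zero exactly. Note the filter is not transparent to
  respiration: the Dirichlet gain of a 101-sample window at 0.25 Hz /
  64 Hz is 0.763, so subtraction leaves 0.24 of the breathing amplitude.
  Every later stage sees that attenuation, which is why the simulator's
  amplitude budget (below) is stated *after* this filter.
* **FIR low-pass** (`lpCutoffHz = 16`, `lpOrder = 64`): a Hamming-window
  linear-phase FIR along slow time, applied once forward with its
  order/2 group delay compensated so windowed statistics stay aligned
  with the record. Respiration (≤ 0.5 Hz) sits deep in the passband
  (gain within 1%). The cutoff default matters for the entropy floor:
  the statistic needs the *noise* to stay broadband relative to the
  wavelet subbands. At a 4 Hz cutoff the surviving noise occupies only
  the lowest ~4 of 7 subbands and noise-bin entropy drops to ~0.7·ln 7,
  shrinking the detection margin; at 16 Hz (half the Nyquist rate) the
  noise floor sits at ~0.92·ln 7, fluctuating just under the ceiling,
  which is the regime the detector is designed for. The cutoff is
  configurable; values below ~8 Hz trade entropy contrast for extra
  noise suppression.

### Auto-correlation (`autocorrelateMatrix`)

R(k) = (1/N)·Σₜ x(t)x(t−k), the **biased** time-average estimator, on
each range bin. The expectation in R_x(t) = E[x(t)x(t−Δt)] is realised
as a time average because a single realisation is available. The biased
normalisation (divide by N, not N−k) is the default because it
guarantees |R(k)| ≤ R(0) and a nonnegative spectrum, which stabilises
the downstream energy distribution; the unbiased variant is available.
Lag 0 — where the noise energy piles up — is *retained*: it is one
coefficient among 2048 and the subband energies dilute it, so no
special-case excision is applied.

### Wavelet entropy (`entropySpectrum`)

Each lag-domain vector is decomposed by a periodized orthogonal
Daubechies filter bank (`waveletName = "db4"`, four vanishing moments,
8 taps) to depth `nLevels = 6`, giving subbands D₁…D₆ plus A₆ — seven
bands, entropy ceiling ln 7 ≈ 1.946.

* **Why periodized (circular) boundaries:** with an orthonormal CQF pair
  the circular analysis operator is *exactly* orthogonal at every even
  length, so the subband energies are an exact partition of the signal
  energy (Parseval) and reconstruction is exact to machine precision.
  Symmetric padding was considered and rejected: the extra boundary
  coefficients inflate the energy total, so the "energies sum to the
  signal energy" identity the statistic leans on would hold only
  approximately.
* **Why include A_J as a (J+1)-th band:** the respiration line lives at
  0.25–0.4 Hz, inside A₆ (0–0.5 Hz at 64 Hz sampling). A detail-only
  energy distribution would discard precisely the ordered component the
  statistic is supposed to reward, so the approximation band is a full
  member of the distribution.
* **Energy normalisation** (`energyMode`): the default
  `"mean_per_coeff"` divides each band's energy by its coefficient
  count. For white noise this equalises all J+1 bands (the per-
  coefficient variance is flat), pushing noise bins to the entropy
  ceiling and maximising the contrast to a narrow-band signature.
  `"raw_sum"` keeps plain sums; its white-noise distribution follows
  the halving dyadic bandwidths, P_j ∝ 2^−j, and the entropy approaches
  2·ln 2 ≈ 1.386 as J grows — a closed form the tests check. Both modes
  are exposed because either normalisation is defensible; the default
  was chosen for the larger noise-vs-signal separation.
* **Windows** (`windowLen`): the record can be split into non-overlapping
  temporal windows with per-window entropies combined by
  `windowCombine` (`"mean"` default, `"max"` available). The default is
  a single window spanning the record: the targets are stationary, so
  temporal resolution buys nothing here, and one window uses all 2048
  lags for the energy estimates. The window length must be a multiple
  of 2^J so every subband splits evenly.
* **Degenerate bins:** a zero-energy bin has no structure at all; its
  entropy is reported as the ceiling ln(J+1) and flagged, so it can
  never masquerade as a target.

### Detection (`findEntropyPits`, `classifyPits`)

The entropy profile is thresholded at median(H) − k·MAD(H)
(`pitK = 3`), computed over bins beyond `blindRangeM = 1` m (the wall's
reflection dominates 0–1 m). The threshold is relative, so detection is
invariant to adding a constant to the whole spectrum. A candidate pit is
a maximal sub-threshold run; its interval extends half a bin beyond the
outermost sub-threshold bin centres, so an n-bin pit is n bin-widths
wide. Within a run, the minimum's tie-break is toward the nearer bin
(deterministic output); the reported `center_m` (interval midpoint) is
the preferred location estimate because strong targets produce pits
with flat bottoms across the torso.

Pits are accepted when their width lies in
[`minPitWidthM` = 0.2, `maxPitWidthM` = 0.8] m — the bracket of
plausible torso footprints. A width-failing pit whose interval starts
within `ghostWindowM = 1` m behind an already-accepted pit is labelled
`rejected_ghost`: trailing multipath (ground bounce) re-radiates the
accepted target's respiration over a band too wide to be a torso.
Everything else that fails the gate is `rejected_width`.

The **energy baseline** (`powerSpectrumProfile` + `findPowerPeaks`)
integrates each bin's periodogram over 0.1–1 Hz and calls peaks that
exceed both a robust floor (median + k·MAD) and 5% of the strongest
peak. The relative term operationalises reading a linear-scale power
plot: a peak three orders of magnitude below the dominant response is
not visible on it regardless of the noise floor. The 5% operating point
reproduces the classical detector's qualitative behaviour — it sees an
unshadowed far target (~7.5% of the near peak under this geometry's
1/r⁴ power budget) but not a shadowed one (~0.1%).

## The scene simulator

`simulateScene` builds echo matrices with exactly the structure the
pipeline assumes: a static wall profile in 0–1 m, per-target respiration
signatures, 1/r² amplitude loss, a hard shadow cone, trailing
multipath, and white Gaussian noise. Everything is deterministic given
`seed`; target components are seed-independent so scenes superpose
exactly (the RNG feeds only the wall profile and the noise).

Choices that matter:

* **Torso footprint:** a raised-cosine (Hann) envelope of compact
  support `bodyThicknessM` + c/(2B) = 0.4 + 0.3 m, the pulse extent at
  the 500 MHz bandwidth. A Gaussian of the same −3 dB width was
  considered and rejected: its unbounded skirts keep a *strong* near
  target's entropy pit growing logarithmically with SNR (the skirt
  stays detectable for >0.6 m), defeating the torso-width gate. The
  finite support caps the pit at the physical footprint, which is also
  what the width-gating logic presumes about real torsos.
* **Shadow cone:** binary in/out with a single amplitude factor
  `shadowAtten`, boundary-inclusive (a bearing separation exactly equal
  to `shadowHalfAngleDeg = 20°` counts as shadowed). The attenuation is
  a free parameter — no physical value is asserted — with default 0.1,
  chosen so that a shadowed target's respiration-band *power* (∝
  atten²) lands ~3 orders of magnitude below the near target's: below
  the baseline's visibility threshold but, after range accumulation and
  auto-correlation, still far above the entropy statistic's detection
  floor. That separation — baseline blind, entropy not — is the regime
  the method exists for.
* **Amplitude budget** behind the defaults (`respAmp = 1`,
  `noiseSigma = 0.005`): a shadowed target at 6 m has native amplitude
  1/36 × 0.1 ≈ 2.8×10⁻³, ~2.8×10⁻² per accumulated bin, and ~6.6×10⁻³
  after the clutter filter's 0.24 passband gain. The biased
  auto-correlation noise floor is σ_f²/√N with σ_f the filtered noise
  scale; at `noiseSigma = 0.005` the shadowed target's lag-domain line
  sits comfortably (≳30×) above that floor while remaining invisible to
  the power baseline. Doubling the noise roughly quarters that margin.
* **Trailing multipath:** a uniform band starting `trailGapM = 0.15` m
  behind the torso's rear face, spanning `trailLengthM = 1` m at
  `trailAmpFrac` (default 0 — trailing is a scenario feature, not
  always-on) of the target amplitude, same frequency, shifted phase.
  With `trailAmpFrac = 0.3` the band carves a ~1 m entropy depression:
  wide enough to fail the torso gate, separated from the target's own
  pit by the gap, and therefore classified as a ghost.

What the simulator does **not** emulate: antenna patterns and wall
dielectrics (no full electromagnetic propagation), target micro-motion
and respiration harmonics, non-Gaussian or correlated receiver noise,
range sidelobes of the real pulse shape, and moving clutter. Passing
tests therefore show that the *statistic and its decision logic* behave
as designed under the assumed signal structure — not that the method is
robust to every artefact of real hardware data; the entropy values of
real records (absolute pit depths, floor levels) will differ.

## Problem sizes and determinism

The test suite and the acceptance script run the full chain at the
radar's native geometry (2048 × 2048 scenes, 200 range bins) for the
simulation studies — 20 seeded shadowed scenes, a five-angle sweep, 20
trailing scenes — and use shorter records (512-sample rows, depths 3–5)
for unit-level properties, which exercise the same code paths at a
fraction of the cost. All randomness flows through explicit seeds:
scenes are bit-reproducible, and the Monte-Carlo checks (200 white-noise
replicates for the entropy floor, 40 for the raw-sum closed form) state
their replicate counts.

## Known limitations

* The entropy floor depends on the low-pass cutoff (see above); users
  who narrow the band below ~8 Hz should expect a lower noise floor
  and re-examine `pitK`.
* Two targets closer than one torso footprint merge into a single pit
  wider than the gate and would both be rejected; the detector has no
  sub-footprint resolution.
* A ghost is only recognised *behind an accepted* target: if the true
  target's pit is itself rejected, its trailing depression is labelled
  `rejected_width` rather than `rejected_ghost`.
* The bistatic single-channel geometry provides no bearing estimate;
  `angleDeg` exists in the simulator to drive the shadow geometry, not
  as something the detector recovers.
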