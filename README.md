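# bioradar

Wavelet-entropy detection of multiple stationary breathing humans in
impulse ultra-wideband (IR-UWB) bio-radar echoes — including targets
hidden in the radar *shadow* of a nearer person, which classical
energy-spectrum detection misses.

## The problem

A bistatic IR-UWB radar probes a scene with short pulses and records, for
every pulse, a fast-time waveform of 2048 samples spanning 60 ns (9 m of
range via r = c·τ/2). Stacking successive pulses gives an M × N echo
matrix: rows are fast time (range), columns are slow time. A breathing
person modulates the echo at their range sinusoidally at the respiration
rate (~0.25 Hz) over the few range cells covered by the torso.

The person nearest the antennas reflects part of the illumination, so a
*shadowing region* forms behind them: a farther person inside it returns
so little energy that their respiration-band power is buried orders of
magnitude below the near target's peak — an energy detector sees one
person where there are two.

## The statistic

The echo of a breathing target is *ordered* (narrow-band, periodic), while
noise in the shadowing region is *disordered* (broadband) — a difference in
spectral structure, not in energy. The pipeline quantifies it per range
bin τ:

1. **Preprocess** — distance accumulation (2048 → 200 range bins),
   sliding-window subtraction of static clutter, FIR low-pass along slow
   time.
2. **Auto-correlate** each bin's slow-time signal,
   R_x(Δt) = E[x(t)·x(t−Δt)]: the periodic respiration component survives
   at all lags while uncorrelated noise collapses onto Δt = 0.
3. **Dyadic DWT** of the lag-domain signal into detail subbands D_1…D_J
   plus the approximation A_J (Daubechies db4, J = 6 ⇒ 7 subbands).
4. **Relative subband energies** P_{τ,j} = E_{τ,j} / Σ_j E_{τ,j}, with
   E_{τ,j} the (per-coefficient) energy of subband j, and the
   **wavelet entropy**

   H_τ = − Σ_j P_{τ,j} · ln P_{τ,j} ∈ [0, ln(J+1)].

   Noise bins sit near the ceiling ln 7 ≈ 1.946; breathing targets carve
   deep *entropy pits* whose width matches the torso thickness.
5. **Detect** — pits below the robust threshold median(H) − k·MAD(H) are
   gated by physical width (0.2–0.8 m); width-failing pits immediately
   behind an accepted target are classified as trailing-multipath ghosts.

A seeded scene simulator (wall clutter, 1/r² attenuation, shadow cone,
trailing multipath, receiver noise) makes the whole chain testable
without radar hardware.

## Worked example

Two breathing targets, at 3 m and — inside the 3 m target's shadow cone —
at 6 m:

```r
library(bioradar)

scene <- sceneConfig(targets = list(targetSpec(3, respFreqHz = 0.3),
                                    targetSpec(6, respFreqHz = 0.25)),
                     seed = 42L)
res <- runPipeline(runConfig(scene = scene))
res$report
#> DetectionReport: 2 accepted, 0 ghost, 0 width-rejected (threshold 1.638)
#>   range_m center_m  lo_m  hi_m width_m  h_min n_bins   status
#> 1   2.817    2.997 2.661 3.333  0.6592 0.2331     15 accepted
#> 2   6.012    6.012 5.810 6.214  0.3955 0.2797      9 accepted

res$baselinePeaks
#>   range_m    power
#> 1 2.99707 79.67977
```

Both targets are accepted: their entropy minima (0.23 and 0.28 nats) sit
far below the noise bins near ln 7, the pit centres (`center_m`) land on
3.0 m and 6.0 m, and the pit widths (0.66 m and 0.40 m) are torso-sized.
The energy baseline (`baselinePeaks`) reports *only* the 3 m target — the
shadowed person at 6 m is invisible to it.

The same chain is scriptable from a shell via `inst/scripts/bioradar`
(subcommands `simulate`, `preprocess`, `autocorr`, `entropy`, `detect`,
`pipeline`), driven by a YAML configuration.

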