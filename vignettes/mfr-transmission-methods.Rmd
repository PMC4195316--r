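---
title: "Quantifying modulated firing-rate transmission with Wiener-filter ideal observers"
author: "mfrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying modulated firing-rate transmission with Wiener-filter ideal observers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfrsim)
```

## The problem

Many sensorimotor pathways encode a continuous signal as temporal modulation
of a tonic spike rate (modulated firing-rate, MFR, coding). Vestibular mossy
fibers, for example, fire tonically at roughly 40 spikes/s and modulate that
rate with head velocity, whose natural power lies below about 20 Hz. The
cells reading this code — cerebellar granule cells in that pathway — are
leaky, resonant spiking neurons, and a spike train is a harsh medium: it
samples its input only when spikes occur. `mfrsim` simulates this
transmission chain in open loop and asks, quantitatively, how much of the
modulation an ideal linear observer could get back out.

Two complementary measurements are produced for every run:

* a **direct transfer-function estimate** `T(f) = Pxy/Pxx` from the stimulus
  to the spiking output passed through a *sampling-rate filter* (a binary
  0/1 train at the simulation step) — no binning, smoothing, or prior
  assumption about the decoder; and
* the **variance-accounted-for (VAF) spectrum**,
  `VAF(f) = |Pxy|^2 / (Pxx Pyy)` in percent — the magnitude-squared
  coherence, which equals the fraction of stimulus variance at `f` that the
  non-causal Wiener filter `K(f) = Pyx/Pyy` recovers. `VAF = 100%` means
  perfect linear reconstruction at that frequency; 90% is used as the
  threshold of "faithful" transmission.

The transfer function alone is misleading for spike codes: a sinusoid fitted
at a *known* input frequency returns a finite gain far above the Nyquist
frequency of the spike code (half the carrier rate), where no observer
without that prior knowledge could reconstruct anything. The VAF spectrum is
what separates genuine transmission from that artifact, which is why the two
are always reported together here.

## Models

**Membrane models.** The resonant integrate-and-fire (rIF) neuron is

C dV/dt = −(V − E_R)/R − I_B + I_E,  with I_B = g_b · b · (V − E_R),
db/dt = −b/τ_b between spikes,

with reset to `E_R` at threshold `V_th`, `b` incremented by 1 at each spike,
and recorded spike times shifted by a pure output delay Δ_s that does not
feed back on the dynamics. Defaults are the published granule-cell fit:
`C` = 3 pF, `R` = 5227 MΩ (τ = RC = 15.7 ms), `E_R` = −71.5 mV,
`V_th` = −41.8 mV (rheobase (V_th − E_R)/R = 5.68 pA), `g_b` = 55.6 pS,
`τ_b` = 19.6 ms, Δ_s = 4.85 ms. The passive LIF is the special case
`g_b = 0`, Δ_s = 0. On the resonant-state convention: the increment-by-one
reading of the spike-triggered conductance (`I_B = g_b·b·(V−E_R)` with `b`
jumping by 1) is used because the alternative jump of 1/τ_b makes the
resonant current numerically negligible (≈ 0.04 pA at 40 spikes/s) and
could not reproduce any ~10-Hz resonance; with the jump-1 convention the
resonant current is ≈ 0.9 pA, the right scale.

**Ideal encoder (iIF).** A leak-free integrator (rest/reset 0, threshold 1)
that accumulates `rate(t)·dt` and spikes whenever the accumulator reaches 1.
Negative instantaneous rates are clipped to zero — this clipping *is* the
rectification phenomenon that push-pull coding counteracts. Each encoder
starts at a uniformly random accumulator phase (per-cell derived seed):
physical populations are not spike-synchronized at time zero, and without
phase randomization identical deterministic encoders would be artificially
locked.

**Integration.** Exponential-Euler membrane update and exact exponential
decay of `b`, at `dt = 0.025` ms; threshold is tested at end-of-step and the
reset applied immediately. Constant-current LIF inter-spike intervals match
the closed form `τ ln(IR/(IR − (V_th − E_R)))` to within one step, and the
rIF with `g_b = 0`, Δ_s = 0 reproduces the LIF bit-for-bit. The kernel is
compiled (Rcpp); state can be carried across drive segments, and splitting a
drive is exact.

## Stimuli and calibration

Stimuli follow the `2σ = 1` convention — every modulation or noise waveform
is normalized to sample standard deviation 0.5, so an amplitude factor
carries all magnitude information and `±amplitude` covers ~95% of
excursions.

* `gen_bandlimited_gaussian()` builds band-limited Gaussian noise in the
  frequency domain (independent Gaussian Fourier coefficients up to the
  cutoff, exactly zero above), giving a brick-wall spectrum that a
  time-domain filter could not.
* `gen_ou_noise()` uses the exact Ornstein–Uhlenbeck discretization
  `x[k+1] = x[k]·e^(−dt/τ) + sqrt(1 − e^(−2dt/τ))·ξ`, so its statistics are
  independent of the step size. "Fast" noise is τ_n = 1 ms, "slow" τ_n =
  100 ms.
* Normalization is applied empirically per realization (divide by the
  measured sd), so the convention holds exactly for every draw.

**Current calibration.** The tonic current `I0` is bisected on simulated
constant-current rates until the carrier rate `F0` is matched to 0.5%
(rates measured from mean inter-spike interval after a 1-s warm-up, which
avoids count quantization). The modulation amplitude follows the relative
convention: `A_I` is the extra tonic current that would raise the rate to
`(1+a)·F0`. Noise amplitudes `A_IN` use the same rule with `a_n` in place of
`a` (the alternative literal reading "A_IN = a_n·F0", a current numerically
equal to a rate, has no consistent units; the calibration convention is used
throughout and is a package decision).

**Low-rate populations.** When the population is held at effective rates far
below the input bandwidth (mean 4, sd 2 spikes/s), per-cell F_eff targets
are drawn from a normal distribution rescaled to those exact sample moments
(the condition specifies the realized population moments) and truncated at
zero; each cell's tonic (subthreshold) current is then bisected with the
modulation — fixed at `A_I` = 2 pA — and any noise current active, until its
measured F_eff matches its target to 3% on a 60-s calibration window. For
the slow-noise variant the noise amplitude is `A_IN` = 2 pA, equal to the
modulation amplitude; the source condition states only that the amplitude
was "adjusted", and equal signal and noise amplitudes is the package's
choice, fixed before any benchmarking.

**Encoder populations.** Heterogeneous carrier rates are drawn
`Normal(mean, v·mean/2)` truncated at zero with relative variance `v = 0.5`
(mean 40 → sd 10 spikes/s). Population summaries of the benchmark
populations report realized `F_eff` with sd ≈ `v·mean/2`, which is why the
benchmark encoder populations are heterogeneous: identical deterministic
encoders sharing one stimulus would collapse a population to a single cell.

**Push-pull coding.** `floor(N/2)` cells (deterministically the second half)
receive the inverted signal `−x`; the analyzed output is
`y = y_plus − y_minus`.

## Spectral estimation choices

* Welch averaged periodograms: 2-s Hann-windowed segments, 50% overlap,
  per-segment mean removal — 0.5-Hz resolution, matching the lowest
  evaluated frequency; analysis band 0.5–200 Hz.
* The spiking output enters the analysis as spike counts in 0.1-ms bins.
  Coarser analysis grids are *not* safe: at 1-ms bins the aliased sidebands
  of the carrier harmonics (multiples of 40 Hz reach far beyond 500 Hz)
  fold into the 0–20 Hz band and depress the baseline mean VAF by ~11
  percentage points. At 0.1-ms bins the result is within 0.1 pp of the
  full-rate analysis at a quarter of the cost; this was validated against
  full-rate analysis before freezing the default.
* Gain is normalized to unity at the lowest analysis frequency and reported
  in dB (`20·log10`); phase is unwrapped and reported in degrees with lags
  negative. The transfer convention is `T = Pxy/Pxx` with
  `Pxy = conj(X)·Y`, i.e. output over input (a printed formula with the
  ratio inverted appears in the source literature; every plot there is
  consistent with output-over-input, which is what is implemented).
* The mean VAF is the unweighted average over the bins from 0.5 Hz to the
  input cutoff (inclusive); bins with input power below 1e-12 of the peak
  are excluded from both the Wiener filter and the mean. Uniform (rather
  than input-power) weighting is recorded in the result metadata.
* VAF is computed from the cross-spectra directly; the identity between
  `1 − VAF` and the realized reconstruction-error variance is verified in
  the tests, not used as the definition.

Two estimator artifacts are worth knowing about. First, magnitude-squared
coherence estimated from `K` segments is biased upward by ~`1/K` and has a
sampling tail; statements like "VAF < 10% everywhere above the carrier rate"
need enough segments (240-s runs in the tests) before the estimator tail
sits below the bound. Second, coherence is invariant under linear filtering
of the output only insofar as the filter's group delay is negligible
relative to the Welch segment: the τ_α = 100 ms alpha filter delays its
output by ~200 ms, which at 2-s segments costs ~9 pp of apparent VAF at low
frequencies; at 16-s segments the invariance holds to < 1 pp.

## Benchmark conditions

`benchmark_condition()` packages the figure-style conditions the test suite
and the acceptance script recompute: single LIF/rIF cells at carrier 40
(and 20) spikes/s with `a` = 0.1 or 1 under 20-Hz band-limited noise;
single and 40-cell ideal-encoder populations at carrier 40, `a` = 1;
100-encoder populations at carrier 20 under 30-Hz noise with `a` = 1 and
with `a` = 10 plus push-pull; and 100-LIF low-rate populations (F_eff
4 ± 2 spikes/s, `A_I` = 2 pA) plain and with push-pull plus slow noise.
Each runs 120 s per seed and results are averaged over ≥ 3 seeds; per-seed
values are retained. The run length is a package choice (the source
conditions do not state one): at 0.5-Hz resolution it gives ~119 averaged
segments, enough that per-seed mean-VAF spread is a few tenths of a
percentage point in the high-fidelity conditions.

A note on one ambiguity: for the 100-encoder population at `a` = 10 the
realized effective rate rises to ~45–50 spikes/s because rectification
clips negative rates while positive excursions grow unboundedly; the
benchmark reproduces the condition without any compensating inhibition and
reports the realized `F_eff`.

## The transmission frontier

`sweep_max_cutoff()` bisects, for each target effective rate, the input
cutoff frequency at which the seed-mean VAF crosses 90% (1-Hz tolerance).
For the heterogeneous ideal-encoder population at `a` = 1 the frontier
follows `cutoff ≈ 2·F_eff` — twice the naive single-channel Nyquist limit —
because `N` desynchronized encoders sample the signal in an interleaved
fashion. A target rate whose threshold is not reached anywhere in the
search range is reported as censored (`NA`), not an error.

## What the generators do and do not emulate

The synthetic stimuli reproduce the study conditions: stationary Gaussian
band-limited modulation, OU noise currents, heterogeneous carrier rates,
push-pull splits. They do not emulate synaptic dynamics (facilitation,
depression, receptor kinetics), conductance noise, bursting, or closed-loop
inhibitory feedback — transmission through those stages is outside this
package's scope, so passing benchmarks here demonstrates fidelity of the
*spike-sampling and membrane* stages only. The plug-in `simulate_neuron()`
contract (drive in, spike train out, optional carried state) is the
intended seam for attaching more detailed neuron models.

## Worked example

```{r, eval = FALSE}
library(mfrsim)

cfg <- benchmark_condition("lif_baseline")   # 1 LIF, F0 = 40, a = 0.1, 20 Hz
agg <- run_experiment_seeds(cfg, seeds = 1:3)
agg$mean_vaf        # ~96, printed reference 97.8
plot(agg$results[[1]]$vaf)
plot(agg$results[[1]]$transfer)
```

## Known limitations

* Open-loop only; no spike-driven synapse models, no inhibitory feedback.
* The Wiener observer is linear and non-causal: VAF is an upper bound on
  linearly recoverable information, not a statement about any causal
  biological decoder (though the reconstruction kernels have finite support,
  so a delayed causal variant exists).
* Mean VAF weights band bins uniformly; conditions are compared at the
  0.5-Hz Welch resolution, and values within roughly a percentage point of
  each other should not be over-interpreted.
* The baseline single-cell mean VAF runs ~1.5 pp below the printed
  references across all current-stimulation conditions, consistent with a
  slightly different treatment of the band-edge bin (the bin at exactly the
  cutoff loses coherence through window leakage); the package includes that
  bin because input power is present there.
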