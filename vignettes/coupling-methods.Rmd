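---
title: "Quantifying LC–TCC coupling: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LC-TCC coupling: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duosync)
```

`duosync` quantifies the coupling between two simultaneously recorded
brainstem structures — the locus coeruleus (LC) and the
trigeminocervical complex (TCC) — from spike trains, stimulus onsets
and local field potentials (LFP). This vignette is the package's
account of its methods: the models and conventions each estimator
assumes, the parameters that matter and their defaults, what the
synthetic-session generator does and does not emulate, and the design
decisions taken where the underlying procedures left the choice open.

## Conventions

Time is in seconds, double precision, zero at session start; every
interval (PSTH bins, analysis windows) is half-open `[t, t + Δ)`. Phase
is wrapped to `(−π, π]` (the unique representative; `+π` maps to
itself) with the cosine convention: phase 0 at the oscillation peak.
The region names are `LC` and `TCC`; the alias `Sp5C` is accepted on
input. By recording convention, TCC analyses use single units and LC
analyses multi-unit activity, but nothing in the code enforces this.
Positive lags and positive coupling delays always mean *LC leads TCC*.

## Evoked-response analysis

PSTHs accumulate post-stimulus spike offsets into 1 ms bins (default)
over a window of one inter-stimulus interval. Two protocols are built
in: cutaneous stimulation (0.8 ms pulses every 1.5 s) and meningeal
stimulation (5 ms pulses every 2 s). Two reference statistics are
attached to each PSTH:

* `tail_mean` — the mean bin rate over the final 500 ms of the window,
  the reference epoch for the evoked-bin criterion;
* `pre_train_rate` — the mean rate over the 30 s immediately preceding
  the first stimulus. The pre-train epoch length is a design choice
  (the procedure only requires "before the train"); 30 s averages over
  several intermediate-rhythm cycles without reaching into earlier
  protocol phases.

A bin is *evoked* when its rate strictly exceeds `tail_mean`. The
criterion is deliberately implemented literally, including its two
awkward corners: bins inside the tail epoch can themselves be flagged,
and at millisecond resolution roughly half of all baseline bins are
flagged by chance (any bin holding one spike exceeds a sub-20 Hz tail
mean). The first is inherent to a self-referential criterion; the
second is why component extraction cannot simply merge runs of flagged
bins. `extract_components()` therefore screens each run for
significance — the run's excess spike count over the tail-rate
expectation must reach a Poisson z-score of `min_z` (default 4, chosen
so the family-wise false-run rate across the ~2000 candidate runs of a
2 s PSTH is negligible) — before merging surviving runs separated by at
most `merge_gap` (default 5) unflagged bins. The default bin width
(1 ms) and window (one ISI) are design choices; the criterion itself is
invariant to uniform rate rescaling, which the tests exercise.

TCC components are classified by peak latency — A-fiber below 30 ms,
C-fiber in `[30, 200)` ms, with a run straddling 30 ms split there.
LC components are the *two dominant* surviving runs (largest excess
spike count), labelled early and late in temporal order; dominance
rather than pure temporal order is used because a single spurious run
surviving the screen would otherwise shift both labels. A component's
`magnitude` is its mean excess rate over `tail_mean` normalised by
`pre_train_rate`; when the baseline is zero the magnitude is flagged
`NA` rather than infinite. `time_to_peak` is the excess-weighted
centroid of the smoothed rate above half its maximum (FWHM centroid),
whose standard error scales as component width over the square root of
the excess spike count — single-bin Poisson jitter would otherwise
dominate a raw argmax.

## Rhythm analysis

`mean_frequency()` converts a spike train to a rate signal: the count
in a centred window of length `width` around each spike, divided by
`width`, linearly interpolated onto a uniform grid and zeroed farther
than `width/2` from any spike. Defaults pair `width` with the analysis
band: 100 s at 2 Hz output for the slow rhythm, 10 s at 2 Hz for the
intermediate rhythm, 0.5 s at 50 Hz for delta-band power.

Band edges are design choices bracketing the observed rhythms with
margin: slow `[1/1200, 1/120]` Hz, intermediate `[1/40, 1/12]` Hz,
delta `[0.3, 2]` Hz. All filtering is zero-phase (forward–backward FIR
with reflection padding), so phases and lags carry no group delay; the
first and last filter-length samples of a phase signal are flagged
edge-contaminated and spikes falling there are excluded from phase
histograms.

`estimate_period()` decimates the rate so the band occupies a sensible
fraction of the Nyquist range, band-passes, and returns the lag of the
highest positive-lag autocorrelation peak within `[1/high, 1/low]`,
parabolically refined. How the original analysis computed "period" is
not specified; the autocorrelation route was chosen and is validated by
recovery of injected periods (within 0.2–1 % at the study's session
lengths). Two guards matter: the signal must span at least three of the
band's longest periods, and confidence is gated by Fisher's g-test on
the *unfiltered* in-band periodogram — the autocorrelation of a
band-filtered signal oscillates even for white-noise input, so a
genuine spectral peak must be established before filtering. A
low-confidence estimate returns `NA` with a warning rather than a
number.

Spike-phase histograms allocate each spike to the phase (75 or 150
bins per cycle; 150 by default — both appear in practice and no rule
selects between them) of the reference signal at the nearest sample,
then z-score the counts so that histograms from different sessions
average as pure temporal-dynamics profiles. The preferred phase is the
circular mean of the spike phases, not the argmax bin — robust to bin
noise, at the cost of assuming a unimodal preference. `precession()`
is the wrapped circular difference `TCC − LC` of two preferred phases
measured against the *same* reference signal. Sign semantics deserve a
note: "the TCC peak shifts earlier in the cycle" is circularly
ambiguous, so the package fixes the convention operationally — the
generator's `tcc_phase_advance` is defined as exactly the value
`precession()` recovers (a positive advance places the TCC rate peak at
positive reference phase). The sensitized preset uses a positive
advance on the slow rhythm.

## Synchronization and LFP analysis

The MUA delta-power ratio is periodogram power in 0.3–2 Hz divided by
total power above DC. The normalisation bandwidth for "total power" is
unstated in the source procedure; the DC-excluded full Nyquist band is
used, since rate signals carry a large mean offset that would otherwise
swamp the ratio. The synchronization index averages this ratio over two
10-minute windows centred in the two longest inter-train gaps — the
before/after comparison epochs of a microinjection protocol; sessions
without two qualifying gaps raise an error listing the gaps available.

Raw LFP is decimated to 50 Hz (zero-phase FIR, 20 Hz cutoff — below
the 25 Hz output Nyquist; unit DC gain enforced exactly). Spectrograms
use the stated STFT parameters: Hamming window of 1024 samples,
overlap 1014 (10-sample hop, 0.2 s frames at 50 Hz), FFT length 8096.
The delta time course integrates the *log* PSD over 0.3–2 Hz per
frame — implemented literally as stated, with `linear = TRUE` as a
sensitivity switch. Sliding R² smooths both series with a
Savitzky-Golay filter (order 3, frame 51) and computes the squared
Pearson correlation on 400 s windows with a 10 s hop (the hop is a
design choice; the estimator per window was taken to be Pearson on the
smoothed series). The cross-correlogram lag scans `±max_lag`
(default 0.2 s) and refines the global peak by a local quadratic fit
whose neighbourhood adapts to the peak's sharpness (the contiguous
region above 90 % of the peak, capped at 30 ms): band-limited LFP pairs
have smooth correlation peaks for which the wide fit averages noise,
while a broadband shift still resolves to its exact sample. Swapping
the inputs flips the sign exactly.

## Statistics

`compare_groups()` reproduces the normality-gated test choice: a
Lilliefors test on each sample (and on the paired differences), then
Student's t if all pass at `alpha_normality` (default 0.05, unstated in
the source), otherwise Wilcoxon signed-rank (paired) or Mann-Whitney U
(unpaired). The Lilliefors null distribution is built by Monte-Carlo
(10⁴ standard-normal samples per sample size, internally seeded and
cached) rather than an analytic approximation; the type-I error of the
whole gated procedure is verified ≤ 7 % at nominal 5 % under Gaussian
nulls. Zero-variance samples force the nonparametric branch with a
`degenerate` flag. No multiple-testing correction is applied (none is
applied in the source analyses); contrasts are reported per comparison,
and pairing is an explicit input rather than inferred.

## The synthetic-session generator

The generator exists so that every estimator can be validated by
parameter recovery; its defaults *are* the study conditions wherever
those are stated, and documented choices where they are not.

Firing rates are multiplicatively modulated baselines:
`rate(t) = base × Π_r (1 + depth_r · m_r(t))`, clipped at zero.
Multiplicative (not additive) mixing keeps rates interpretable as
modulated baselines. Each rhythm's modulation `m_r` mixes a component
shared between regions (the TCC copy delayed by `coupling_lag`) and a
region-specific component with an independent seeded phase, weighted
`shared_fraction : 1 − shared_fraction`. Spikes are drawn by thinning
an inhomogeneous Poisson process; the LC multi-unit cluster is the
union of four independently thinned trains carrying equal shares of the
population rate, mirroring multi-unit extraction. Evoked responses are
Gaussian rate bumps (peak latency, width, multiplicative gain) —
PSTH shapes are never specified in the source, and a Gaussian gives a
controllable peak latency and width. The LFP is shared delta-band
(0.3–2 Hz brick-wall) Gaussian noise, amplitude-modulated by the
shared slow-rhythm envelope (so LFP delta power co-varies with the slow
rate oscillation), delayed for the TCC by an exact FFT fractional
delay, plus white measurement noise.

Preset parameters, in three groups:

* **Stated values, injected as-is** — naive slow/intermediate periods
  400.4 s / 21.3 s; sensitized 675.0 s / 20.5 s; coupling lag
  10.1 ms; LC evoked latencies 62.8 / 129.6 ms; stimulation protocols
  0.8 ms @ 1.5 s and 5 ms @ 2 s with 50-pulse trains.
* **Qualitative condition differences, encoded as preset scalars** —
  sensitization raises the TCC baseline three-fold, applies a +0.5 rad
  TCC phase advance on the slow rhythm and scales the LC late-component
  gain to 0.3; propranolol scales the LC delta-rhythm depth to 0.3 and
  LC evoked gains to 0.4 of naive. These are config values, not code.
* **Unstated magnitudes, chosen once** — modulation depths 0.6 / 0.5 /
  0.4 (slow / intermediate / delta), baselines 15 Hz (LC MUA) and 2 Hz
  (TCC, low in naive animals), `shared_fraction` 0.8, LFP noise sd 0.3
  relative to the unit-variance delta drive, LFP sampling 1000 Hz
  (well above the 50 Hz decimation target), rate-process sampling
  50 Hz. The delta period is 0.87 s rather than a round 1 s so that it
  is incommensurate with both inter-stimulus intervals — a 1 s delta
  rhythm phase-locks to 2 s stimulus trains and masquerades as evoked
  structure, which real (non-entrained) delta activity does not.

What the generator does *not* emulate: refractory periods and bursting,
spike-sorting contamination, non-stationary baselines beyond the
configured rhythms, conduction-delay jitter, volume conduction between
the electrodes, and any biophysical (gap-junction) mechanism behind LC
synchrony. Passing recovery tests therefore demonstrates that the
estimators are correct for data satisfying their generative
assumptions — not that real recordings satisfy them.

## Validation scale and determinism

Everything stochastic flows from one master seed per config through
derived per-stream seeds, so identical configs give bit-identical
sessions and the whole cohort → analysis → contrast chain is
reproducible. The test suite validates at the sizes the estimators are
meant for: 5400 s (naive) and 10800 s (sensitized) sessions for period
recovery, 600 s LFP pairs at 1 kHz over ten seeds for lag recovery
(mean error well under 1 ms), 600 s two-region sessions over twenty
seeds per injected offset for the phase pipeline (constructed shifts,
`shared_fraction = 1`, advance on the intermediate rhythm — slow-rhythm
injection would need multi-hour sessions per seed while exercising the
identical code path), and 2000 s three-train sessions for the
synchronization contrast, where the propranolol preset yields a
strictly lower index than naive in at least 18 of 20 seed pairs.

## Known limitations

* Session I/O uses the CSV-directory + JSON dialect only; HDF5
  containers would need an HDF5-capable R stack.
* The evoked-bin criterion is noise-hungry at 1 ms bins by
  construction; the significance screen in `extract_components()` is a
  package addition (documented above) without which the literal
  criterion yields no usable components.
* `estimate_period()` reports a single dominant period per band; it
  does not separate two rhythms inside one band.
* The sliding-R² estimator assumes both signals are well sampled on a
  common grid; it linearly interpolates rather than resampling with an
  anti-alias filter, which is adequate for the smooth band-power and
  slow-rate signals it is applied to.
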