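---
title: "Quantifying SSVEP responses: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying SSVEP responses: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepr)
```

## The measurement problem

A steady-state visual evoked potential (SSVEP) is a narrow-band oscillation
entrained in visual cortex by a flickering stimulus. Experiments that compare
stimulus renderings (colour, size, shape, ...) need a per-condition scalar
that answers: *how much did power at the flicker frequency rise during
stimulation, relative to rest?* The difficulty is that the raw effect is
buried in a background whose power falls roughly as 1/f, varies across
subjects, and is spread unevenly across the scalp.

`ssvepr` addresses each nuisance with a dedicated stage:

* the 1/f background and inter-frequency comparability — by the **relative**
  measure ERSP = (P_stim − P_base)/P_base at the stimulation frequency;
* scalp topography variability — by **Common Spatial Patterns (CSP)**, which
  learns, per frequency, the channel combination whose variance discriminates
  stimulation from baseline best;
* off-frequency interference (including the three simultaneously flickering
  distractor frequencies of a realistic BCI display) — by a per-frequency
  **elliptic band-pass** before CSP.

## Epoch classes

From each trial the pipeline takes a 4 s stimulation epoch `[onset,
onset + 4 s)` and a 4 s baseline epoch `[onset − 4 s, onset)`. Intervals are
half-open over 0-based sample indices and durations are converted with
`round()`. The baseline is the final 4 s of the 6 s rest preceding the onset,
which maximizes separation from the previous trial's stimulation; trials
without a full margin on either side are dropped (not padded — padding would
bias spectra) with a logged warning. Whether re-referencing precedes or
follows decimation is immaterial (both are linear); the pipeline fixes the
order select → re-reference → downsample → epoch and logs each stage.

## The narrow-band filter: nominal order versus measured response

The filter contract is stated in measured terms: 2 Hz passband centred on
*f*, peak-to-peak passband ripple at most 0.04 dB, and at least 40 dB
attenuation beyond the stopband edges. The stopband edges are set at
*f* ± 2 Hz (1 Hz transitions): the closest pair of stimulation frequencies
(14 and 17 Hz) is 3 Hz apart, so full attenuation must be reached before the
neighbouring frequency — the per-frequency CSP stage is only meaningful if a
sinusoid at one stimulation frequency is invisible to another frequency's
filter. `design_bandpass()` asserts this cross-frequency selectivity.

These constraints fix the minimum elliptic prototype order. An order-3
prototype with 0.04 dB ripple and 40 dB stopband reaches only ~9 dB at
*f* ± 2 Hz and ~27 dB at the 3 Hz-distant neighbour: no order-3 design can
meet the measured contract, whatever its nominal description. The design
therefore selects the minimal feasible order via `signal::ellipord` (order 5,
a band-pass transfer function of order 10) and records the achieved ripple,
attenuation and measured passband width in the returned object and in run
reports, so the escalation is visible in provenance rather than silent.

Two numerical points:

* **Zero-phase application.** Epochs are filtered forward-backward
  (`zero_phase = TRUE`, the default; a causal single pass is available),
  which preserves epoch timing and squares the magnitude response — the
  40 dB single-pass stopband becomes 80 dB in application. Edges are handled
  by odd (point-symmetric) reflection padding sized to the filter's
  ring-down length, capped by the epoch length.
* **Ringing.** A 2 Hz-wide band at 128 Hz forces poles of modulus ≈ 0.994,
  an impulse ring-down of tens of seconds — longer than the 4 s epoch. This
  is physics, not a defect: any filter this selective rings this long.
  Consequences: band-limited noise in adjacent bins leaks slightly across
  epoch edges, and a stopband sinusoid is attenuated in a finite epoch by
  somewhat less than the asymptotic transfer-function value. The tests
  assert the transfer function exactly and the epoch-level attenuation at a
  correspondingly looser bound.

## Decimation

Recordings are decimated to 128 Hz with an order-8 Chebyshev type I low-pass
(cutoff 0.8 × target Nyquist) applied zero-phase, then every k-th sample is
kept. The passband ripple is set to 0.02 dB and the coefficients are
normalized to exact unit DC gain: an even-order Chebyshev I dips by its full
ripple at DC, and a double pass doubles the ripple in dB, so a larger ripple
(e.g. the conventional 0.05 dB) cannot simultaneously keep DC exact and hold
all in-band gains within 1% — at 0.02 dB the worst-case double-pass gain
error is below 0.5%.

## CSP estimation

Per stimulation frequency, class covariances are averages of per-epoch
channel covariances, each normalized by its trace. Trace normalization
removes inter-trial global amplitude nuisance (standard CSP practice) and
makes the fit invariant to class-wide rescaling; note it also rescales the
achieved eigenvalue, which is then a ratio of *normalized* variances
(`normalize = FALSE` recovers the raw variance ratio). A relative ridge of
1e-9 guards near-singular covariances after narrow-band filtering, and a
genuinely rank-deficient baseline is an error rather than a silent
pseudo-inverse. The generalized eigenproblem is solved by whitening the
baseline covariance; only the top eigenvector is used (one "most responsive"
component), the weights have unit norm and a fixed sign convention (first
nonzero weight positive) for reproducible serialization.

CSP is fitted on the band-pass **filtered** epochs and applied to the same:
since the ERSP is read at *f*, filtering first is the only interpretation
under which training and application see the same signal subspace. The
filter is fitted **pooling all conditions** of a frequency
(`csp_scope = "pooled"`, per-condition fitting available): pooling gives
every condition the same projection, which matters for inference (below).

One bias is worth naming: CSP maximizes the stimulation/baseline variance
ratio *in sample*, so even with no injected signal the projected stimulation
power slightly exceeds baseline power, and null ERSPs are slightly positive.
Because the pooled filter is shared by all conditions of a frequency, this
bias is common to all conditions and cancels from between-condition
contrasts, which is what the statistics test. Null calibration of the
estimator itself is therefore checked on a single channel (where CSP is a
no-op).

## Welch spectra and the ERSP

Spectra use 1 s Hann windows with 3/4 s overlap (13 segments per 4 s epoch at
128 Hz, 1 Hz resolution), per-segment mean removal (avoiding DC leakage into
low bins), and density normalization (the PSD integrates to the signal
variance). The ERSP is computed average-then-ratio: class PSDs are averaged
over trials first, then `(P_stim − P_base)/P_base` is formed in the single
1 Hz bin nearest *f* — the passband already confines signal power, so wider
integration would only add noise, and averaging before the ratio keeps the
denominator stable. A log-ratio variant, 10·log10(P_stim/P_base), is
available via `variant = "logratio"`. Values of order 5–10 are typical for
strong responses: ERSP = 9 is a ten-fold power increase.

## Statistics

The omnibus test across conditions is a Friedman rank test with mid-ranks
and the standard tie correction; blocks are (subject × frequency) pairs, so
a single-subject, four-frequency experiment has n = 4 blocks. A fully tied
table yields statistic 0 and p = 1. The p-value comes from the chi-square
approximation (df = k − 1) or, for small tables, from exact enumeration of
all (k!)^n within-block permutations (`method = "exact"`) — at n = 4 the
chi-square approximation can be off by ~0.1 in the mid-range, so the exact
route exists and is tested against an independent enumeration oracle.

Post-hoc comparisons are two-sided Wilcoxon signed-rank tests at the
Bonferroni level α/m, m = k(k−1)/2, run only when the omnibus test is
significant at α = 0.05. Zero differences are dropped (Wilcoxon's rule;
Pratt's method behind `zero_method = "pratt"`), tied magnitudes get
mid-ranks, and the p-value is exact (full 2^n sign-assignment distribution
via the rank generating function) for n ≤ 15, with a tie- and
continuity-corrected normal approximation beyond. At least 5 nonzero pairs
are required — with fewer, even the most extreme assignment cannot reach
conventional levels — so the pipeline skips (and reports) rather than runs
post-hoc tests on single-subject block structures. The multiplicity count is
pairwise-conditions only; frequencies do not multiply m.

## The synthetic session generator

The generator emulates the study design the pipeline expects: trials of 6 s
rest + 4 s stimulation in which all four flicker frequencies are active
simultaneously, the attended one at the condition's amplitude and the others
at 25% of it (`distractor_ratio`; realistic interference, though the
attended/unattended ratio is a modelling choice, not a measured quantity);
30 repetitions per (condition, frequency); randomized trial order; markers
at each onset. Signals are sinusoids at *f* with a second harmonic at 25% of
the fundamental, random phase per trial (the analysis is power-based, and a
fixed phase would understate variance), projected through an
occipital-dominant topography (gain 1.0 on O1/O2, 0.6 on Pz/P3/P4, 0.4 on
P7/P8, 0 elsewhere — mastoids included, so re-referencing never removes
signal). The background is 1/f^β-shaped Gaussian noise (exact
frequency-domain shaping, β = 1, PSD 2 µV²/Hz at 10 Hz) plus a 10 Hz alpha
sinusoid (4 µV, random phase per channel). The default fundamental amplitude
of 3 µV yields pipeline ERSPs of roughly 2–6 — the order of magnitude
reported in stimulus-comparison studies. Identical configurations (including
the seed) generate bit-identical sessions.

`calibrate_amplitude()` inverts the generator's noise model: it returns the
amplitude for which the expected stimulation/baseline Welch-bin power ratio
on a given analysis channel equals a target r, using two analytic constants —
a bin-centred sinusoid of amplitude a contributes a²/3 to the peak bin of
the Hann-windowed density, and linked-mastoid re-referencing of independent
equal-power channel noise inflates background power by 3/2. This makes
r − 1 a known ground truth for the ERSP estimator. The calibration holds for
the *unfiltered single-channel* readout: narrow-band filtering biases the
Welch bin value of the (now sharply peaked) filtered noise but not of the
bin-centred sinusoid, and CSP mixes channels with data-dependent weights, so
the calibrated ratio is asserted without those two stages, whose effect is
covered instead by monotonicity and ordering tests.

What the generator does **not** model: volume conduction/forward-model
channel correlations (beyond the shared mastoid reference), eye or muscle
artifacts, non-stationary alpha, attention or fatigue dynamics, and any
harmonic structure beyond 2f. Passing tests therefore demonstrate
correctness of the computation under the stated statistical structure, not
robustness to artifacts in real recordings.

## Validation sizes

The checks that accompany the package run at these sizes, chosen to keep the
full suite at desk scale while preserving the study's design constants where
they matter: filter constants on 100,000-point grids for all four
frequencies; a full default session (1024 Hz, 20 channels, 30 repetitions)
for the preprocessing constants; 100 random 2–7-channel instances against a
100,000-vector Rayleigh-quotient search for CSP; ERSP calibration at target
ratios {2, 5, 10} with 30 trials per frequency cell; 2000 Monte-Carlo
replicates for the Friedman type-I error and the family-wise error of the
full procedure; effect recovery (2:1 amplitude, 30 repetitions, 1024 Hz)
over 5 seeds; and 200 replicate null experiments of 10 simulated subjects
each (at 128 Hz with 3 trials per cell) for end-to-end null calibration.

## Known limitations

* The ERSP's raw form is unbounded above and bounded below by −1; strongly
  skewed for weak responses. The statistics are rank-based, so inference is
  unaffected, but means of small samples can mislead — the ordering summary
  (`qualitative_replication()`) reports standard errors for this reason.
* CSP uses a single component; montages in which two spatially distinct
  sources respond at the same frequency would need the multi-component
  extension, which is out of scope.
* EDF input is not implemented; recordings enter via the in-memory
  constructor (`raw_recording()`) or the plain-text fixture format
  (`read_recording()`).
* Narrow-band ring-down exceeding the epoch length (see above) slightly
  couples adjacent epochs' noise; at the 6 s trial spacing this is
  negligible, but much shorter rest periods would need attention.
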