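---
title: "Skewness-based functional connectivity: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skewness-based functional connectivity: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfconn)
```

## The problem

Interictal high-frequency activity (80–500 Hz) is a promising marker of
epileptic tissue, but it resists conventional functional-connectivity
analysis: ripples and fast ripples last only tens of milliseconds, so most
of any recording is baseline, and their rates and amplitudes vary widely
across channels. Amplitude- or phase-correlation networks computed directly
on the band-passed signal therefore carry little information in this band.

`sfconn` implements the alternative this package is built around: summarize
each channel-second by how strongly transient events distort the amplitude
distribution — the **sample skewness of the upper envelope** — and build the
network from the co-variation of those summaries over time.

## The model

For each bipolar channel $i$ and one-second epoch $t$, with envelope
samples $x_1,\dots,x_n$ and mean $\bar x$,

$$ Y_{it} \;=\; \frac{\tfrac1n\sum_k (x_k-\bar x)^3}
                     {\bigl(\tfrac1n\sum_k (x_k-\bar x)^2\bigr)^{3/2}} $$

i.e. the biased (divisor-$n$) sample skewness. Epochs containing events
have heavy right tails and high $Y_{it}$; baseline epochs sit near the
skewness of the background envelope. The network edge between channels $i$
and $j$ is the absolute Spearman rank correlation of their skewness series
$Y_{i\cdot}, Y_{j\cdot}$ (tie-corrected average-rank form; on tie-free data
this equals $1 - 6\sum d^2 / (T(T^2-1))$). The diagonal is forced to zero,
and node strength $s_i = \sum_j Z_{ij}$, bounded by $N-1$, is the per-channel
summary used for localization. Rank correlation is deliberate: it captures
monotone co-variation of event intensity without assuming linearity, and it
is invariant to any strictly increasing transform of a channel's skewness
series.

## Preprocessing choices

The stage order is fixed: bad-channel removal → bipolar montage →
(optional) resampling → band filter → power-line notch → upper envelope →
1-s epoching.

* **Bipolar montage.** Adjacent contacts of one shaft are subtracted
  (`A1-A2` = A1 − A2); pairs never span shafts. After bad-channel removal,
  a missing contact breaks the chain by default — we do not form
  long-distance "bipolar" pairs across a gap; `bridgeGaps = TRUE` relaxes
  this for sensitivity analyses.
* **Band filter.** Hamming-window FIR, transition bandwidth 0.1× the lower
  band edge (floored at 2 Hz), applied forward–backward, so the effective
  stopband attenuation is twice the ~53 dB single-pass design. The
  high-frequency band is 80–500 Hz when 500 Hz fits below Nyquist and a
  high-pass above 80 Hz otherwise (the natural form at a 1000 Hz common
  rate); both are available explicitly, plus delta/theta/alpha/beta/gamma
  comparison bands.
* **Notch.** "Order-2 Butterworth with 5 Hz cutoff" is interpreted as an
  order-2 band-stop of 5 Hz *total* width (±2.5 Hz) at the mains frequency
  and every harmonic below Nyquist; the width is configurable.
* **Envelope.** Strict local maxima (plateaus count once, at their first
  sample; endpoints excluded), natural cubic spline through the maxima,
  evaluated at every sample; beyond the first/last maximum the boundary
  value is held rather than extrapolated. At each detected maximum the
  envelope equals the signal exactly. A channel with fewer than two maxima
  is flagged and given a constant envelope.
* **Resampling.** Fourier method (spectrum truncation = ideal low-pass
  anti-aliasing); downsampling only. The package keeps native rates unless
  a common rate is requested.
* **Epochs.** Non-overlapping 1-s epochs of the *continuous* envelope
  (the envelope is computed once on the whole segment and then cut, so
  epoch boundaries introduce no envelope discontinuities); the trailing
  partial epoch is dropped.

### Zero-phase filtering, spectrally

Forward–backward filtering with a filter $H$ is a zero-phase pass with
response $|H(\omega)|^2$. The package evaluates $|H|^2$ (FIR band filter,
and the product of Butterworth notch biquads) on the DFT grid of the
mirror-padded signal and multiplies in the frequency domain. This is exact
zero phase, gives the doubled attenuation of two passes, costs
$O(n\log n)$ regardless of filter length, and lets the band and notch
responses be fused into a single pass inside the pipeline (their spectral
responses simply multiply; the public `filterBand()`/`notchPowerline()`
stages remain available separately and agree with the fused path away from
the padded edges). Edge effects are absorbed by odd-mirror padding of one
filter length (FIR) or one second (notch ringing).

## What "skewness across epochs" means here

The feature matrix is built per channel, per epoch: $Y$ is $N\times T$ and
row $i$ is channel $i$'s envelope-skewness time series. This is the reading
consistent with an $N\times T$ matrix whose rows are correlated across
time; computing skewness *across channels* within an epoch would yield a
single series and no network. Anyone comparing numerical results against
other implementations should check which reading was used.

## The synthetic cohort generator

Real interictal iEEG with surgical ground truth cannot ship with a
package, so every claim the test suite makes is established on synthetic
cohorts with known labels. Each channel is unit-RMS Gaussian $1/f$
background (exponent configurable) plus Hann-windowed sinusoidal bursts:

* carrier frequency uniform in `eventFreqRange` (default 80–400 Hz),
  duration uniform in 30–100 ms, peak amplitude `eventAmplitude`× the
  background RMS with mild log-normal jitter;
* burst times follow an inhomogeneous Poisson process whose per-second
  intensity is `rate × ((1 − coupling) + coupling × latent(t))`, where
  `latent` is a shared log-Gaussian AR(1) process (lag-1 correlation 0.9,
  log-scale SD 0.8, normalized to unit mean) common to all
  epileptic-behaving channels of a patient; their event *amplitudes* are
  also modulated by `latent^(coupling/2)`. Normal channels draw
  independent homogeneous Poisson bursts at `eventRateNormal`;
* contacts are named in 5-contact depth-shaft notation (`A1..A5`,
  `B1..B5`, …) so bipolar pairing is exercised. With the default 20
  contacts and 25% epileptic fraction the epileptic block is exactly one
  shaft, which keeps labeled and unlabeled bipolar channels structurally
  exchangeable when coupling is zero and rates are equal (bipolar chains
  share contacts, so chain position alone affects strength; tiling whole
  shafts removes that confound from the null);
* one master seed expands into per-patient substreams, so any patient can
  be regenerated alone, bit-identically.

Defaults (`simConfig()`): 10 patients × 20 contacts, 300 s at 1000 Hz —
the common resampling rate used for heterogeneous multi-centre recordings,
where the high-frequency band becomes a high-pass above 80 Hz — rates 2
vs 0.2 events/s, amplitude 4× RMS, coupling 0.9. These are the study
conditions under which the package validates itself: strong co-modulated
high-frequency activity on one electrode against sparse independent
activity elsewhere.

For surgical outcome emulation, `effectOutcome > 0` gives each
poor-outcome patient (even patient indices; ILAE 4 / Engel 3)
`max(1, round(effectOutcome × nEpileptic))` *residual* contacts directly
after the labeled block that behave epileptically (same shared latent) but
are labeled non-epileptic — the situation where treatment missed part of
the epileptic network. Seizure-free patients (ILAE 1 / Engel 1) have none.

**What the generator does not emulate:** realistic neural-mass dynamics,
spikes and sharp transients, muscle/movement artifacts, electrode drift,
heterogeneous channel counts or sampling rates within a cohort, spatially
decaying field spread, or clinically realistic outcome base rates. Passing
tests therefore demonstrate that the estimator recovers the statistical
structure it targets — temporally co-modulated transient high-frequency
events — not that it attains any particular performance on clinical data.

## Evaluation choices

* **Normalization.** Per patient, strengths are mean-subtracted then
  min–max mapped to [0, 1] before pooling, removing channel-count and
  baseline-connectivity differences; the map is affine-invariant.
* **ROC.** Thresholds sweep the unique scores with strict ">" ("exceeding"
  a threshold labels a channel epileptic; ties fall to non-epileptic), and
  ±∞ endpoints pin the curve at (0,0) and (1,1). Trapezoidal AUC equals
  the normalized Mann–Whitney statistic with ties credited one half.
* **Bootstrap CIs** resample the pooled unit: channels for localization,
  patients for outcome classification (1000 iterations, percentile 2.5/
  97.5, seeded). Patient-specific AUCs get a t-based 95% CI instead.
* **Truth labels.** A bipolar pair counts as epileptic when *either*
  contact lies in the labeled tissue: a resection that includes a contact
  removes every derivation it takes part in. Cohorts mixing resection and
  seizure-onset labels should supply whichever zone determined treatment
  per patient.
* **Outcome score.** Minus the mean normalized strength over channels
  outside the labeled tissue; residual epileptic network raises the
  outside mean, so higher scores predict seizure freedom. Group membership
  follows ILAE 1–2 or Engel 1 ⇒ seizure-free (either scale suffices, so
  ILAE 1 with Engel 2 is seizure-free), ILAE 3–6 or Engel 2–4 ⇒ poor.
* **Effect size.** Cohen's d between paired per-patient AUC sets uses the
  paired-difference SD (sample, divisor k−1) by default; the pooled-SD
  two-sample form is available via `method = "pooled"`. Zero spread is
  reported as an infinite-effect flag rather than NaN.

## Degenerate inputs and numerical conventions

Zero-variance epochs get skewness 0 and a degeneracy flag (shape is
preserved; flagged cells are reported). A channel whose whole skewness
series is constant gets zero edges with a warning, rather than NaNs
propagating into strengths. Constant inputs to the Spearman correlation
return 0 with a warning. Normalization and ANOVA refuse constant input
with informative errors. All RNG-dependent routines (simulation,
bootstrap) take explicit seeds and restore the caller's RNG state.

## Problem sizes used in the package's own validation

The test suite establishes parameter recovery at the default cohort size
(10 patients × 20 contacts × 5 min, ten seeds) for the strong-effect and
null-calibration checks, and verifies coupling monotonicity on reduced
cohorts (5 patients × 2 min, ten seeds per coupling level, identical
across levels) where the effect gradient, not absolute power, is under
test. Outcome classification is checked on a 30-patient cohort of
5-minute segments with `effectOutcome = 0.6`. `scripts/acceptance.R`
recomputes the same quantities from scratch with three seeds per
condition.

## Known limitations

* The envelope spline can overshoot between widely spaced maxima on very
  flat stretches; with ≥80 Hz content this is rare, and the skewness rank
  correlation is insensitive to it.
* EDF/BrainVision readers are not included; cohorts enter either through
  the package's plain-text container (`writeCohort()`/`readCohort()`,
  which also carries BIDS-style channel status) or as in-memory
  `RecordingSegment` objects built from any reader the user has.
* Direct-mode connectivity on very short epochs (< ~50 samples) is noisy;
  the default 1-s epochs at ≥500 Hz are well away from that regime.
* The pooled bootstrap resamples channels, which treats channels within a
  patient as exchangeable after normalization; patient-level resampling is
  available for the outcome analysis, where patients are the unit.
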