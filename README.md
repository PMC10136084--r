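# sfconn — skewness-based functional connectivity for high-frequency iEEG

`sfconn` localizes epileptic tissue from interictal intracranial EEG using
functional networks built in the high-frequency band (80–500 Hz), where
transient events — high-frequency oscillations (HFOs) and high-frequency
activity (HFA) — are informative but too brief and too variable for
conventional amplitude- or phase-correlation connectivity. It is aimed at
epilepsy researchers working with SEEG/ECoG recordings who want a
detection-free network analysis of the high-frequency band, and it ships a
synthetic iEEG cohort generator with known channel-level ground truth so
the entire pipeline can be exercised and validated offline.

## The method

For each bipolar channel *i* and non-overlapping 1-s epoch *t*, the
package computes the biased sample skewness of the channel's upper
envelope within the epoch,

```
Y[i,t] = m3 / m2^(3/2),   mk = (1/n) Σ (x - x̄)^k
```

giving an N×T feature matrix **Y**. Epochs containing transient
high-frequency events have heavy right tails (high skewness); baseline
epochs do not. The network adjacency is

```
Z[i,j] = | spearman(Y[i,·], Y[j,·]) |,   Z[i,i] = 0
```

and each channel's connectivity strength `s[i] = Σ_j Z[i,j]` is the
localization score: channels whose event intensity co-varies with many
others over time sit centrally in the epileptic network. Strengths are
mean-subtracted and min–max normalized per patient, pooled across
patients, and evaluated against resected-zone / seizure-onset-zone labels
by ROC/AUC with bootstrap confidence intervals; per-patient AUCs get
t-based intervals. Minus the mean normalized strength *outside* the
labeled tissue serves as a surgical-outcome score (residual epileptic
network predicts poor outcome).

Preprocessing follows the fixed order: bad-channel removal → bipolar
montage → optional Fourier resampling → zero-phase FIR band filter
(80–500 Hz band-pass, or high-pass above 80 Hz when 500 Hz exceeds
Nyquist) → order-2 Butterworth notch (5 Hz wide) at the mains frequency
and harmonics → upper envelope via natural cubic spline over local maxima
→ 1-s epoching. Conventional band networks (delta…gamma, and the direct
extension of per-epoch Spearman correlation to the high-frequency band)
are available as comparison paths.

See `vignettes/sfc-methods.Rmd` for the full account of the model,
parameter choices and limitations.

## Worked example

Simulate a 10-patient cohort at the default study conditions (20 contacts
on 5-contact depth shafts, 5 minutes at 1000 Hz, one epileptic shaft per
patient with coupled 80–400 Hz bursts at 2/s against 0.2/s elsewhere) and
run the full pipeline:

```r
library(sfconn)

cfg    <- simConfig(seed = 1)        # defaults: 10 patients, coupling 0.9
cohort <- simulateCohort(cfg)
run    <- runPipeline(cohort, runConfig(bootstrapB = 1000), quiet = TRUE)
print(run)
#> SfcRun: 10 patients, mode 'sfc', band 'hfo'
#>   pooled AUC 0.975 (95% CI 0.948-0.996); individual mean AUC 0.981
#>   outcome AUC 0.680 (group p = 0.611)
```

Pooled localization is near-ceiling: epileptic bipolar channels (the
coupled shaft) have much higher connectivity strength than the rest. The
outcome AUC is statistically at chance (p = 0.61, 5 patients per group)
because this cohort was simulated with `effectOutcome = 0` — both outcome
groups have fully labeled epileptic tissue, so there is nothing for the
outcome score to find. Adding
residual epileptic tissue outside the labeled zone for the poor-outcome
half turns it informative:

```r
runOut <- runPipeline(simulateCohort(simConfig(nPatients = 30,
                                               effectOutcome = 0.6,
                                               seed = 5)),
                      runConfig(bootstrapB = 1000), quiet = TRUE)
print(runOut$evaluation$outcome$roc)
#> RocResult: AUC 0.849 (95% CI 0.674-0.973) over 15 positives / 15 negatives
```

Per-patient objects are plain S4 containers with accessors:

```r
p <- run$patients[[1]]
p$Z
#> AdjacencyMatrix: 16 nodes, mean |rho| 0.084, max 0.641
head(strengths(p$s), 4)
#>    A1-A2    A2-A3    A3-A4    A4-A5
#> 1.897528 2.250650 2.254948 2.078179
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/sfc.R` (`simulate`, `preprocess`, `connect`, `evaluate`,
`run` subcommands).

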