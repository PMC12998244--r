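# roarbout

Call-type classification and individual identification from the roaring
bouts of African lions (*Panthera leo*).

## The problem

A lion's roaring bout is a structured sequence of four call types: low
**moans** open the bout, loud arched **full-throated roars** (FTRs) follow,
then shorter, lower **intermediary roars** (IRs), and a train of brief
**grunts** closes it. The FTR carries an individually identifiable vocal
signature, which makes it the unit of interest for passive acoustic
monitoring and acoustic capture–recapture of lion populations — but picking
FTRs by eye from spectrograms injects observer bias. `roarbout` implements a
data-driven alternative for bioacousticians:

* **F0 contours.** Each annotated call is bandpass-filtered (30–375 Hz,
  zero-phase Butterworth, or windowed-FFT masking) and its
  fundamental-frequency contour extracted by normalized autocorrelation in
  128-sample windows: F0 = rate/ℓ\*, with ℓ\* the shortest
  near-maximal-correlation lag (octave guard) inside the band.
* **Call-type HMMs.** Each call type is modelled by a two-state Gaussian
  hidden Markov model over its F0 contour (states ≈ rise/peak vs.
  fall/terminal). Calls are classified leave-one-out by maximum forward
  log-likelihood across per-type HMMs, fitted by Baum–Welch with randomized
  restarts.
* **K-means on two features.** Call types are also clustered on the
  standardized (duration, maximum frequency) plane with Lloyd's K-means —
  k = 4 with moans, k = 3 with moans removed — with exact optimal
  cluster-to-label mapping for evaluation and a duration-rank heuristic
  (longest cluster = FTR) for label-free application.
* **Individual identification.** Per-lion HMMs are fitted on FTR contours
  and whole bouts are assigned leave-one-bout-out (so within-bout temporal
  autocorrelation cannot leak into training), with the FTR set chosen either
  from manual labels or by the K-means predictor.
* **Metrics.** Confusion matrices are reduced one-vs-rest and scored with
  accuracy (TP+TN)/(TP+TN+FP+FN), recall TP/(TP+FN), precision TP/(TP+FP)
  and F1 = 2PR/(P+R), under micro and macro averaging (plus the plain
  fraction-correct, reported as `traceAccuracy`, since the TN-inclusive
  accuracy exceeds it for more than two classes).
* **Synthetic bouts.** A generator produces labeled corpora with the bout
  grammar, per-type feature distributions, parametric contour templates and
  per-lion signatures, so every stage is testable without field recordings.

I/O covers RIFF WAV (PCM16/32, float32, multi-channel) and Raven-style
tab-separated selection tables with a column map for dialect drift.

## A worked example

```r
library(roarbout)

## 3 lions, 5 bouts each, distinct contour signatures (±25% peak spread)
ds <- genDataset(nIndividuals = 3, boutsPerIndividual = 5,
                 signatureSpread = 0.25, seed = 29)
nrow(ds$annotations)   # 221 calls across 15 bouts
table(ds$annotations$call_type)
#> full_throated_roar  grunt  intermediary_roar  moan
#>                 44    117                 33    27

## call types by K-means (moans removed, k = 3)
runCalltypeKmeans(ds$annotations, k = 3, dropMoans = TRUE, seed = 1)
#> ClassificationReport
#>   micro: accuracy 0.986 (trace 0.979) precision 0.979 recall 0.979 f1 0.979
#>   macro: accuracy 0.986 precision 0.964 recall 0.970 f1 0.965

## identify lions from K-means-predicted FTRs, leave-one-bout-out
rep <- runIndividualId(ds$annotations, ds$contours, ftrSource = "kmeans",
                       cfg = fitConfig(nRestarts = 2, seed = 7), nRepeats = 1)
macroMetrics(rep)["f1"]   # 1.0: every bout assigned to its lion
attr(rep, "perLion")
#>   lion_id n_bouts n_roars
#> 1     L01       5      14
#> 2     L02       5      15
#> 3     L03       5      11
```

The clustering report reads: 98.6% micro accuracy under the TN-inclusive
formula, 97.9% of calls in the correct cluster, with the few errors being
FTRs falling into the IR cluster. The identification report assigns all 15
held-out bouts to the correct lion from 40 data-driven FTR selections.

A thin command-line wrapper over the same functions ships in
`inst/scripts/roarbout.R` (`synth`, `f0`, `cluster`, `classify-calls`,
`identify` subcommands).

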