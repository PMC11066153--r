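# tiltBMI

Simulation and analysis of tilt brain–machine interface (BMI) learning
experiments in R.

In the tilt-BMI paradigm, a rat stands on a motorised platform that is
tilted in one of four ways (fast/slow × left/right). Cortical spike
trains from one hemisphere (*direct* neurons) drive a decoder that
classifies the tilt type on every trial; a correct classification rights
the platform (reward), an incorrect one lets the tilt continue
(punishment). Neurons in the opposite hemisphere (*indirect*) are
recorded but never used for control. Over weeks of daily sessions some
animals learn to improve decoding performance and some do not, which
makes the paradigm a natural testbed for asking *which* neurons change
their firing patterns during BMI learning, and how.

tiltBMI packages the complete analysis chain for this kind of
experiment, driven by a synthetic spike-train generator with known
ground truth, for methodologists who want to validate or extend the
analyses without access to raw electrophysiology:

- **Simulator** — per-neuron inhomogeneous-Poisson spike trains
  (constant background + Gaussian-profile response bump with per-trial
  latency jitter), with day-by-day tuning trajectories for learner,
  nonlearner and control cohorts and a ground-truth parameter ledger.
- **PSTH template decoder** — single trials are assigned to the tilt
  type whose peri-stimulus time histogram (PSTH) template (20 ms bins,
  −200…+200 ms) is nearest in Euclidean distance; *online* decoding uses
  the previous day's templates, *offline* decoding uses leave-one-out
  cross-validation within a day.
- **Information metrics** — confusion-matrix mutual information
  `I(r;s) = Σ P(r,s) log₂ P(r,s)/(P(r)P(s))` with shuffle-based bias
  correction (50 label permutations), spike-timing (ten 20 ms bins) vs
  spike-count (one 200 ms bin) information over the 0–200 ms post-tilt
  window, and ensemble redundancy `−P` with
  `P = I_ensemble − Σ I_neuron`.
- **Response metrics** — responsiveness (≥ 5 consecutive supra-threshold
  2 ms PSTH bins plus a paired one-sided t-test), peak response (PR),
  peak latency (PL), and a Fano-factor-style normalized variance of
  pre-tilt spike counts, all z-scored to the day-0 baseline.
- **Learning analysis** — performance normalisation, the
  5-consecutive-days learner rule, early/late phases, naive-vs-expert
  grouped-PSTH distances, and intertrial cumulative-sum linearity fits.

Sessions, templates and all result tables read/write plain CSV and JSON,
and `runPipeline()` ties the stages into one seeded, reproducible run.

## Worked example

Simulate a learner's baseline (day 0) and a late training day, then
decode and characterise them:

```r
library(tiltBMI)

neurons <- defaultNeurons(nPerHemisphere = 5, seed = 11)
traj    <- trajectorySpec("learner", nDays = 25)
day0    <- simulateSession(neurons, day = 0,  nTrials = 400,
                           trajectory = traj, seed = 7)
day20   <- simulateSession(neurons, day = 20, nTrials = 400,
                           trajectory = traj, seed = 8)
day0
#> SessionRecording: animal sim day 0
#>    400 trials, 10810 spikes, 10 neurons ( 5 direct / 5 indirect )

decodeOffline(day0,  hemisphere = "direct", firstN = 300)$accuracy  # 0.447
off20 <- decodeOffline(day20, hemisphere = "direct", firstN = 300)
off20$confusion
#> ConfusionMatrix (rows actual, cols predicted), 300 trials, accuracy 0.717
#>       predicted
#> actual  1  2  3  4
#>      1 40  3 27  1
#>      2  2 52 21  0
#>      3  7  3 59  2
#>      4  4  3 12 64
mutualInformation(off20$confusion)
#> [1] 0.8563  # bits, out of log2(4) = 2
```

Offline accuracy rises from 0.447 (baseline tuning) to 0.717 on day 20
because the learner trajectory pulls the four per-tilt response
amplitudes apart; the confusion matrix shows which tilt pairs remain
hard, and its mutual information (0.86 of a possible 2 bits) summarises
decoding quality in one number.

```r
tc <- timingAndCountInformation(day20, neuronRoster(day20)$neuron_id[1],
                                nShuffles = 50, seed = 1)
tc$timing
#> InfoEstimate (timing): raw 0.2147 - bias 0.0335 = 0.1812 bits (50 shuffles)

ensembleRedundancy(day20, "direct", nShuffles = 50, seed = 1)
#> RedundancyResult: I_ensemble 0.8455, sum I_neuron 0.9534 (n=5 included),
#>   P -0.1079, redundancy 0.1079 bits

on20 <- decodeOnline(day20, day0)       # previous-day templates
fit  <- intertrialCumsum(trialTable(on20$session)$outcome)
c(slope = fit$slope, r2 = fit$r_squared)
#>  slope 0.650, r2 0.9993
```

The bias-corrected single-neuron information separates genuine tuning
from finite-sampling inflation; positive redundancy (0.108 bits) means
the five direct neurons carry overlapping information about the tilt;
and the near-perfect linearity of the cumulative-sum fit (r² = 0.999,
slope = online accuracy) shows correct trials are spread uniformly
through the session rather than clustered early or late.

A whole cohort — baseline plus training days for every animal, online
and offline decoding, learner classification, response metrics and tidy
CSV outputs — runs with:

```r
res <- runPipeline(pipelineConfig(seed = 1, outDir = "run1"))
```

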