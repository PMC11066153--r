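---
title: "Models and methods behind tiltBMI"
author: "tiltBMI maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tiltBMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltBMI)
```

## The experiment the package models

A rat stands on a platform that is tilted in one of four ways — fast or
slow, clockwise (right) or counter-clockwise (left), coded here as tilt
types 1–4 (1 = fast right, 2 = slow right, 3 = fast left, 4 = slow
left). Spike trains recorded from the hindlimb sensorimotor cortex of
one hemisphere (*direct* neurons) drive a classifier that decodes the
tilt type within the first 200 ms of the perturbation; a correct
decision rights the platform (a natural reward), a wrong one lets the
tilt continue (a natural punishment). The opposite hemisphere's
*indirect* neurons are recorded but not used for control, and control
animals are tilted with rewards yoked to a BMI animal rather than to
their own neural activity. Each animal contributes a day-0 baseline
session of 400 tilts (100 per type, randomised order, no BMI coupling)
followed by daily BMI training sessions across 25 training days.
Analyses use only the first 300 trials of a session to limit fatigue
effects, and learning is quantified per day both *online* (the decoder
that actually ran, built from the previous day's recording) and
*offline* (leave-one-out cross-validation within the day).

Because raw recordings from such experiments are not generally
available, the package is built around a synthetic spike-train generator
whose statistical structure matches what the analyses assume, with
ground-truth parameters recorded for every simulated day. All empirical
statements below are the ones the package's tests and acceptance script
compute; nothing is quoted from measured rat data.

## The spike-train model

Each neuron fires as an inhomogeneous Poisson process on every trial,
with rate (spikes/s, time $t$ in ms relative to tilt onset, window
$[-200, 200]$):

$$\lambda(t) = b + a_k \exp\!\left(-\frac{(t - c)^2}{2 w^2}\right),
\qquad c = \ell_k + \varepsilon, \quad \varepsilon \sim N(0, \sigma_j^2)$$

where $b$ is the background rate, $a_k \ge 0$ and $\ell_k \in [0, 200]$
are the amplitude and latency for the trial's tilt type $k$, $w$ is the
bump width and $\sigma_j$ the trial-to-trial latency jitter, applied to
the bump *centre* rather than to individual spikes so that tightening
$\sigma_j$ increases spike-timing information without changing spike
counts. The rate is truncated at the window edges.

Sampling uses the exact superposition property of Poisson processes
rather than thinning: the background contributes a homogeneous process
(`rpois` count, uniform times), and the bump contributes a Poisson
number of spikes with mean equal to the truncated-Gaussian integral
$\frac{a_k}{1000} w \sqrt{2\pi}\,[\Phi(\frac{200-c}{w}) -
\Phi(\frac{-200-c}{w})]$, with spike times drawn from the corresponding
truncated normal. This is distributionally identical to thinning the
same rate function, runs orders of magnitude faster in vectorised R, and
is validated in the tests against the closed-form bump integral, the
Fano factor of background counts, and linear scaling of total counts
with $b$.

Trial sequences are balanced random permutations (equal counts of the
four tilt types), and the intertrial interval is not modelled because no
analysis uses it.

### Learning trajectories

`trajectorySpec()` turns a group label into per-day multipliers applied
to the neuron table before each simulated day (day 0 is always
identity):

- **Learners.** Direct-neuron amplitude separation grows monotonically
  and saturates, $s(d) = 1 + 2(1 - e^{-d/6})$ — a fast early phase and a
  flattening late phase. Direct-neuron jitter shrinks late
  ($\times\,1 - 0.5 (d/25)^2$), so late information gains come through
  spike timing. Indirect-neuron latencies show a transient early
  increase (peaking near day 3, relaxing afterwards), mimicking an
  early, global engagement that fades.
- **Nonlearners.** No improvement; amplitude separation drifts gently
  down and saturates, $1 - 0.15(1 - e^{-(d-1)/4})$. An exactly flat
  trajectory is *not* used, deliberately: the learner rule ("5
  consecutive days above day-1 performance") has a ~40% false-positive
  probability on any flat-but-noisy accuracy series, because the day-1
  reference is itself one noisy draw. Animals called nonlearners are
  precisely those whose performance never sustainably exceeds its
  starting point, and the experimental nonlearner curves sit slightly
  below zero on the normalised scale; the gentle early-saturating
  decline (≈ 4 accuracy points by day 25 at the default tuning)
  reproduces that behaviour and makes the generative labels recoverable
  by the rule itself. Setting `nonlearnerDecline = 0` restores the
  exactly flat variant.
- **Controls.** Identity on all days; their group label is assigned by
  design, not by the performance rule.

`defaultNeurons()` draws per-neuron parameters a physiologist would call
typical for this preparation: background 2–10 spikes/s, one preferred
tilt with a 15–30 spikes/s bump against 0–8 spikes/s for the others,
latencies 30–120 ms, jitter 5–15 ms, widths 10–25 ms. With few neurons a
draw may leave some tilt type without a dedicated preferring neuron;
decoding then relies on the weaker amplitude and latency differences,
which is realistic for small ensembles.

## The decoder

Templates are per-tilt-type PSTHs: mean spikes per trial in 20 ms bins
spanning −200 … +200 ms, concatenated across the neuron roster
(neuron-major). Bins are half-open $[l, r)$, so a spike at exactly
+200 ms is excluded — the convention is bit-stable and tested. A single
trial is binned the same way and assigned to the tilt type with the
smallest Euclidean distance between trial vector and template vector, on
raw counts with no normalisation; exact ties break to the lowest tilt
index so results are deterministic.

Offline decoding rebuilds the four templates from all other retained
trials for every held-out trial (leave-one-out). The implementation
updates class sums rather than recomputing means, and a brute-force
loop-based classifier in the test suite must agree with it exactly on
1000 random instances.

Online decoding freezes templates from the previous day's session (day 1
uses the day-0 baseline, which exists precisely to establish the initial
response state) and writes correct/incorrect outcomes back into the
day's trial table. Rosters are reconciled across the two days: a neuron
is used only if it fired at least one spike on both days, so units that
disappear are dropped and newly appearing units wait one day — "stopped
firing" is read as zero spikes in the session, the simplest testable
criterion.

## Information measures

Mutual information between actual and predicted tilt is the plug-in
estimate on the confusion matrix, in bits, with $0 \log 0 = 0$ and no
smoothing — finite-sampling inflation is handled by the shuffle
correction instead, which matches how the estimate is defined rather
than layering a second estimator on top. For four balanced classes the
value lies in $[0, 2]$ bits.

The bias of a neuron's (or ensemble's) information is estimated by
permuting the tilt-label vector, re-running the leave-one-out
classification against the permuted labels, and averaging the resulting
information over 50 permutations; the corrected value is raw − bias, and
only estimates strictly above 0 bits enter population summaries. Fifty
permutations stabilise the bias estimate to well under 0.01 bits, and on
untuned neurons the mean corrected information is within ±0.01 bits of
zero (checked over 20 seeded simulations).

Timing versus count information both use the 0–200 ms post-tilt window:
timing with ten 20 ms bins, count with a single 200 ms bin, and their
difference is the temporal information contributed by within-window
spike placement. Latency-coded simulated neurons show count ≈ 0 with
timing clearly positive; rate-coded neurons show timing ≈ count.

Redundancy is reported as $-P$ with
$P = I_\mathrm{ensemble} - \sum_n I_n$, where the ensemble estimate runs
the same leave-one-out classifier on the concatenated 20 ms responses of
all recorded neurons of a hemisphere and the sum runs over included
(> 0 bit) single neurons. One numerical subtlety is deliberate: the
ensemble and every single-neuron bias estimate reuse the *same* label
permutations, so a one-neuron hemisphere yields $P = 0$ exactly rather
than a small shuffle-noise residual. Per-animal Pearson correlations
between mean single-neuron information and the redundancy z-score
(z-scored across that animal's training days) are provided, returning
`NA` on zero-variance series.

## Response metrics

Responsiveness uses a 2 ms PSTH. The pre-tilt window ($[-200, 0)$ ms) of
the same trials provides the background: a neuron is responsive to a
tilt type when at least 5 consecutive post-tilt bins exceed background
mean + 2 SD of the 2 ms background-bin values *and* the per-trial
activity in the detected run exceeds the per-trial background activity
in a one-sided paired t-test at p < 0.001. The 2 SD multiplier is a
conventional PSTH detection threshold and is exposed as an argument, as
is the significance level; the significance criterion is an upper bound
on p (a lower bound would accept noise and reject signal). The
false-positive rate on flat Poisson neurons stays below 5% in testing.

PR is the maximum post-tilt 2 ms bin count divided by trials, minus the
background count per bin per trial; PL is that bin's centre. When a
neuron is responsive to several tilt types, only the most responsive
case (largest PR) is kept, so each neuron contributes one observation
per day.

Normalized variance is the Fano-factor form on the single 200 ms
pre-tilt count per trial: $\mathrm{NV} = \mathrm{var}(n) /
(\bar n + 0.01)$, with the 0.01 offset guarding near-silent neurons and
the 200 ms constant converting counts to the reported firing rates. The
ratio is taken on counts, not on rates: a Poisson train then calibrates
to NV ≈ 1 (rates would multiply the ratio by 5 and break that
calibration), constant counts give exactly 0, and rate mixtures scale as
the mixture-variance formula predicts. Per-tilt NVs are averaged across
a hemisphere's neurons, z-scored against the day-0 baseline, and the
four per-tilt z-scores averaged to one value per hemisphere per day.
Whether to smooth the counts first is a known fork in this methodology;
the package does not smooth, matching the binning convention above.

## Learning analysis

Performance series are normalised as differences: online accuracy
relative to day 0 (taken as the day-0 offline estimate, since no online
decoding exists before training), offline accuracy relative to training
day 1. An animal is a learner when some run of ≥ 5 consecutive training
days each *strictly* exceeds its day-1 value; the comparator is an
argument, and the rule is applied to the offline series by default
(the offline estimate is the cleaner of the two, being cross-validated
within day). Early and late phases are the first and last 5 training
days and require at least 10 days.

For naive-vs-expert comparisons the expert day is the training day with
the highest offline accuracy (latest on ties). Trials are pooled into
grouped tilt classes — RFS (right, fast+slow), LFS (left, fast+slow),
FRL (fast, right+left), SRL (slow, right+left) — before PSTH
construction, and the population distance between two grouped PSTHs is
the per-neuron Euclidean distance over 20 ms bins averaged across
neurons. The package reports the two orthogonal contrasts, side
(RFS vs LFS) and speed (FRL vs SRL), for the naive day and the expert
day; which pooled pairs to contrast is genuinely open in this analysis
family, and `tiltPairDistance()` accepts any two pooled PSTHs so other
pairings are one call away. Simulated learners sit above the identity
line (expert > naive) for direct neurons.

The intertrial analysis cumulates outcomes (+1 correct, +0 incorrect)
over the session and fits an ordinary least-squares line against trial
index. Exchangeable outcomes make this near-perfectly linear — slope
equal to session accuracy and r² above 0.99 — so departures from
linearity would indicate within-session learning or fatigue. The r² of
an all-incorrect (constant) series is defined as 0 to avoid a 0/0.

## Numerical and design choices

- Half-open bins everywhere; edge spikes clamp inward only against
  floating-point spill from the truncated-normal draw.
- Distance ties break to the lowest tilt index; argmax ties (PR/PL) to
  the earliest bin; expert-day ties to the latest day.
- Probabilities are plug-in counts; no smoothing anywhere.
- Seeds: every stochastic entry point takes a `seed` argument and
  restores the caller's RNG state; experiment-level seeds derive child
  seeds below 2³¹ for each animal-day.
- Degenerate inputs error early with specific messages: unbalanced
  trial counts, < 2 trials per class for leave-one-out, empty reconciled
  rosters, < 10 trials for NV, zero-variance baselines (NA with
  warning).

## Problem sizes used in validation

The packaged checks run at sizes chosen to keep the full suite fast
while leaving comfortable statistical margins: 400-trial sessions for
single-session claims (the baseline session size), 20 seeds for
null-information averages, 10 cohort seeds × 8 animals × 25 days at 6
neurons per hemisphere for end-to-end learner recovery, and 1000
replicates for the intertrial-linearity and classifier-equivalence
properties. The cohort default of 10 neurons per hemisphere reflects a
typical single-unit yield from a 16-microwire array; validation cohorts
use 6 to keep runtimes short without changing any conclusion.

## What passing tests do and do not show

The generator reproduces the statistical structure the analyses assume —
Poisson spiking, Gaussian response bumps, stable tuning within a day,
balanced randomised trials. Real recordings add effects the generator
deliberately omits: spike-sorting noise and unit turnover within days,
correlated (non-Poisson) variability, bursting, slow drifts in
excitability, behaviour-locked confounds, and genuinely shaped (rather
than parameterised) learning dynamics. Passing tests therefore certify
that the *analysis chain* is correct and recovers known ground truth
under its own assumptions, not that those assumptions hold for any
particular dataset. The exported tidy tables are the intended interface
for group-level inferential statistics, which are out of scope here.
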