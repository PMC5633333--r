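---
title: "Patient-adaptive seizure detection: models, adaptation and evaluation"
author: "seizAdapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-adaptive seizure detection: models, adaptation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neonatal seizures are rare, short events embedded in many hours of
continuous multichannel EEG. A detector trained on a population of other
newborns (a *patient-independent*, PI, system) faces a well-known obstacle:
each newborn's EEG has its own character, so the class-conditional feature
distributions of a new patient are shifted relative to the population the
detector was trained on. Clinician-labelled data from the new patient are
normally unavailable — EEG recording starts within hours of birth — so the
personalisation has to happen *on the fly*, from automatically generated
labels.

`seizAdapt` implements a semi-supervised personalisation scheme built from
two classifiers with complementary strengths:

* a **fixed discriminative branch** — a calibrated kernel margin
  classifier scoring every epoch with a seizure probability
  $P_{\mathrm{SVM},i} \in [0,1]$. It discriminates well but cannot be
  retrained in real time;
* an **adaptive generative branch** — one diagonal-covariance Gaussian
  mixture model (GMM) per class,
  $\theta_C = \{\mu_{C,m}, w_{C,m}, \Sigma_{C,m}\}$,
  $C \in \{S, \mathit{NS}\}$, whose posterior
  $P(S \mid x) = \frac{\pi\,p(x\mid\theta_S)}
  {\pi\,p(x\mid\theta_S) + (1-\pi)\,p(x\mid\theta_{NS})}$
  is cheap to update with the well-established MAP machinery of speaker
  adaptation.

The two probability streams are fused per epoch by the geometric mean,
$P_{\mathrm{FUSION}} = \sqrt{P_{\mathrm{GMM}}\,P_{\mathrm{SVM}}}$, which
suits classifiers whose outputs follow different distributions: one small
factor vetoes, agreement reinforces.

## MAP adaptation of the mixture means

Given $N$ new feature vectors $X = \{x_1,\dots,x_N\}$, conventional MAP
adaptation of a class model repeats three steps
(`conventionalMapUpdate()`, 3 passes by default):

1. *occupancy*: $P_{C,m}(x_i) = \dfrac{w_{C,m}\, g(x_i \mid \mu_{C,m},
   \Sigma_{C,m})}{\sum_j w_{C,j}\, g(x_i \mid \mu_{C,j}, \Sigma_{C,j})}$;
2. *occupancy-weighted data mean*:
   $E_{C,m}(X) = \dfrac{\sum_i P_{C,m}(x_i)\, x_i}{\sum_i P_{C,m}(x_i)}$;
3. *interpolation*:
   $\mu_{C,m} \leftarrow \alpha\,\mu_{C,m} + (1-\alpha)\,E_{C,m}(X)$.

Only the means move; weights and covariances stay frozen. This is
deliberate: the patient effect being modelled is a distributional shift,
and mean-only updates cannot collapse a component's variance on
mislabelled data.

Conventional MAP needs a hard label per vector to decide *which* class
model each vector adapts. Thresholding the discriminative probability
would waste most of the data (seizures are rare, so the seizure model
would barely adapt) and make the result threshold-sensitive. The package's
core update, `confidenceWeightedMapUpdate()`, instead uses **all** data to
adapt **both** models simultaneously, weighting by label confidence:

* $[0,1]$ is partitioned into $K$ equal-width bins
  (`partitionProbabilitySpace()`); epoch $i$ joins the seizure model's
  cluster $k$ if $\underline{P}_k \le P_{\mathrm{SVM},i} < \bar P_k$, and
  the non-seizure model's cluster by the complementary rule on
  $1 - P_{\mathrm{SVM},i}$ (`assignClusters()`);
* a monotone weight function $f$ is sampled at the bin centres,
  $h_k = f(c_k)$, and normalised together with the original-model mass
  $\bar h$ into a partition of unity:
  $\beta_k = h_k / (\bar h + \sum_j h_j)$,
  $\alpha = 1 - \sum_k \beta_k$ (`sampleWeightSchedule()`);
* each mean is updated as a weighted combination of the per-cluster
  statistics:
  $\mu_{C,m} \leftarrow \alpha\,\mu_{C,m} + \sum_k \beta_k\,
  E_{C,m}(X_{I_{C,k}})$.

Four weight shapes are provided, all increasing with confidence: `linear`
($f(c)=c$), `sigmoid` ($1/(1+e^{-s(c-0.5)})$, $s = 10$),
`exp1` ($e^{-3(1-c)}$) and `exp2` ($e^{-8(1-c)}$, the default). The
exponential shapes are the conservative ones — they essentially ignore
low-confidence clusters; the faster decay of `exp2` makes it the most
selective, and it is the configuration the experiments use with $K = 10$.
The shape parameters are free parameters of this implementation: only the
qualitative shapes are prescribed by the design, so the decay rates (3, 8)
and sigmoid steepness (10) were fixed once as round values reproducing
those shapes and are configurable.

### Numerical and edge-case choices

* All densities, likelihoods and occupancies are computed in log space
  with log-sum-exp; posteriors use `plogis` on log-likelihood ratios. An
  epoch whose densities underflow in *every* component (not reachable with
  finite variances, but guarded) gets uniform responsibilities and a
  warning.
* $\bar h$ defaults to $\sum_k h_k$, giving $\alpha = 0.5$; `hbar = Inf`
  expresses the $\alpha = 1$ (adaptation off) limit exactly. Construction
  fails if $\alpha \le \max_k \beta_k$: the original model must keep the
  largest single weight, since its training labels are the only certain
  ones.
* An empty cluster — or one whose occupancy mass for a component is zero —
  contributes nothing; its $\beta_k$ is folded back into $\alpha$ for that
  update. Folding (rather than renormalising over non-empty clusters) is
  the conservative choice: missing evidence defaults to the prior model,
  and the effective weights still sum to one.
* The three passes recompute occupancies from the updated means but keep
  the cluster assignment and $\beta$ fixed — they depend only on the
  discriminative probabilities, which do not change.
* Probabilities entering the fusion are clamped to
  $[10^{-6}, 1-10^{-6}]$ so one branch can never permanently zero the
  geometric mean.

## The streaming protocol

`runLoo()` evaluates a cohort leave-one-patient-out. For each held-out
patient, `trainPIModels()` fits the PI system on the remaining patients:
the margin classifier on standardized pooled epochs (class-balanced
subsample, Platt sigmoid fitted on out-of-fold decision scores), and one
GMM per class by EM (`fitGMM()`: k-means-seeded, diagonal covariance,
variance floor $10^{-6}\times$ the feature variance, monotone
log-likelihood). Three variants run on the held-out record:

* **PI** — score directly; no adaptation.
* **PA** — `hourlyAdaptationRun()`: the GMMs are re-initialised to the PI
  models, then adapted after every hour of record using that hour's pooled
  channel features and their raw per-channel discriminative probabilities;
  after each hour the fused system re-scores the *entire* record
  retrospectively (the system runs in real time but may revise earlier
  decisions). Point 0 of the resulting curve is exactly the PI-FUSION
  performance; partial final hours are used as-is.
* **ORACLE** — the patient-dependent reference: the system is retrained
  from scratch with a short true-labelled prefix of the test record (10
  minutes by default) mixed into the training pool, then evaluated on the
  remainder. A zero-length prefix reduces exactly to PI.

Scoring is per channel (each channel is processed independently), followed
by temporal smoothing (centred moving average, 3 epochs) and cross-channel
aggregation by the element-wise maximum — seizure activity on any single
channel flags the epoch. Maximum was chosen over averaging as the
clinically conservative rule consistent with per-channel independence.

## Evaluation

* `aucScore()` — rank-based (Mann–Whitney) AUC, ties counted half;
  identical to the trapezoidal area under the empirical
  sensitivity/specificity curve.
* `auc90()` — the partial area restricted to specificity $\ge 90\%$,
  linearly interpolated at the boundary and normalised by its maximum
  (0.1), so perfect discrimination scores 1 and a chance-level continuous
  classifier $\int_{0.9}^{1}(1-s)\,ds / 0.1 = 0.05$. The plain $/0.1$
  normalisation (rather than McClish standardisation) is used because
  reported values like "82.6%" are only reachable on that scale.
* `compareAucCorrelated()` — a z-test for the difference of two AUCs
  measured on the same epochs. The variance of each AUC and their
  covariance are estimated from per-observation placement values (the
  DeLong construction), which keeps the test calibrated at small
  prevalence; the test statistic is the classical correlated-ROC form
  $z = (A_1 - A_2)/\mathrm{SE}_{\mathrm{diff}}$. Default significance
  level: 1%.
* `eventMetrics()` — event-based scoring: an annotated seizure is detected
  if some detection overlaps it by $\ge 1$ s (no double counting); a
  detection overlapping no annotated event is one false detection,
  reported per hour (FD/h). Detections come from `thresholdToEvents()`
  (default threshold 0.5, minimum duration 8 s = one epoch).
* `relativeImprovement()` —
  $(\mathrm{AUC90}_{\mathrm{new}} - \mathrm{AUC90}_{\mathrm{base}}) /
  (1 - \mathrm{AUC90}_{\mathrm{base}})$: the fraction of the remaining
  headroom gained; negative when adaptation hurts.

## The synthetic cohort

No public corpus of neonatal EEG feature streams with per-epoch
annotations exists at the scale needed here, so `generateCohort()` builds
one with the statistical structure the method targets:

* **background structure**: a population non-seizure mixture (3 diagonal
  components, means scattered with sd 0.75, variances uniform on
  $[0.6, 1.4]$) in $D = 16$ dimensions;
* **class separation**: the seizure mixture reuses the background
  component layout shifted by 0.7 on the first 8 dimensions plus a small
  per-component jitter (sd 0.2). Tying the layouts is essential: placing
  the two classes' components independently in 16 dimensions makes them
  separable almost surely, regardless of the intended shift;
* **patient effect**: one additive Gaussian shift per class (sd 0.4 per
  dimension), shared across the patient's whole record and all channels —
  exactly the mechanism mean-only MAP adaptation is designed to capture;
* **events**: a Poisson process at 1.7 events/h (the rate of a large
  clinical corpus: roughly 1389 seizures in 817 h), uniform durations
  60–240 s, placed without overlap; epochs are labelled by their centre;
* **geometry**: 8 s epochs with 4 s hop, 2 independent channels, 6
  patients of 4 h by default. The epoch geometry is a package choice (the
  upstream feature definitions are not part of this artifact); every
  epoch is one ROC sample.

The defaults put the patient-independent fusion baseline at roughly
AUC $\approx 0.99$ / AUC90 $\approx 0.95$ — deliberately below ceiling so
adaptation has headroom, and near the operating regime of clinical
detectors. What the generator does *not* emulate: temporal autocorrelation
of the features within a seizure, artifacts and state changes
(sleep/wake), channel-specific seizure topography, and non-Gaussian
feature marginals. Tests passing on this cohort therefore demonstrate the
adaptation machinery under its own model assumptions, not clinical
performance.

## Experiment sizes and what they show

The bundled experiments run at desk scale: 6 patients x 4 h, 10 cohort
replicates for the ordering checks, 20 replicates for parameter-recovery
properties, 5000 null simulations for the significance-test calibration.
These sizes were chosen so the full suite completes on one CPU while the
Monte-Carlo margins stay interpretable.

Two qualitative results are stable across replicates: the patient-adaptive
fusion beats the patient-independent baseline (and its own adaptation
curve rises over the first hours), and oracle-confident adaptation pulls
the class means strictly closer to the shifted truth. One clinically
expected ordering does **not** transfer to this synthetic scale: the
Oracle variant — retrained with only a 10-minute true-labelled prefix —
sits *between* PI and PA here, rather than above both. With hours of
record available, confidence-weighted adaptation simply uses far more of
the patient's data than the Oracle's prefix contains; the Oracle's
upper-bound status at clinical scale rests on much longer records and a
far harder feature space. Corrupting 10% of the oracle labels degrades
parameter recovery without reversing it in aggregate, though the seizure
model alone can lose ground: with ~5% seizure prevalence, flipped
background epochs outnumber true seizure epochs in the top-confidence
cluster — a genuine failure mode of confidence weighting under heavy label
noise at low prevalence, not an implementation artifact.

## Known limitations

* Diagonal covariances throughout. Mean-only adaptation never touches
  covariances, and the generator is diagonal; correlated features would
  need a full-covariance extension of `ClassGMM`.
* The discriminative branch is a generic calibrated RBF-SVM with a
  class-balanced training cap, standing in for whatever margin classifier
  a deployment would use; it is pluggable behind the score-then-calibrate
  contract.
* Event scoring uses a single fixed threshold; collar rules and adaptive
  thresholds of deployed post-processing are out of scope.
* The weight schedule is fixed a priori; learning it from data is an open
  extension.
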