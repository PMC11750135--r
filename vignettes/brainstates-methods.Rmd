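---
title: "Latent brain-state dynamics: models, parameters and validation"
author: "brainstates package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent brain-state dynamics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainstates)
```

## The model

During naturalistic listening, whole-brain activity summarized at the
level of a few networks (here nine: auditory, visual, somatomotor,
language, medial temporal, frontoparietal, ventral attention, subcortical,
default mode) tends to move through a small number of recurring
configurations. We model one subject's T x N matrix of z-scored network
time courses as a hidden Markov chain with multivariate Gaussian
emissions: at each TR (2 s) the brain occupies one of K latent states,
state j emitting an observation with mean vector mu_j (the state's
network activity loadings, in z-units) and full covariance Sigma_j (whose
correlation form is the state-specific functional connectivity). States
persist and switch according to a K x K row-stochastic transition matrix.

Fitting uses Baum-Welch EM on the concatenation of all subjects, with the
forward recursion restarting from the initial distribution at every
subject boundary, so no transition is ever counted across subjects. The
paper-family of analyses this package implements typically relies on a
variational Bayesian HMM; we use maximum-likelihood EM and the training
log-likelihood as the model evidence for restart selection. This keeps
the contract — Gaussian states, random restarts, evidence-based selection
— fully specifiable while avoiding a dependence on a particular
variational implementation.

Numerical choices: covariances are re-estimated as full matrices with
1e-6 added to the diagonal each M-step; convergence is declared at a
relative log-likelihood change below 1e-6, with an iteration cap of 100
(the cap binds only for overparameterized fits at large K, where the
selected K is unaffected; raising it is a one-argument change);
initialization is k-means (Lloyd, seeded per restart, computed on a
row-sorted copy of the data so that results do not depend on subject
order) with per-cluster covariance starts; Viterbi ties break toward the
lower state index; forward-backward is computed in the scaled domain and
is exact to enumeration at small sizes (see the validation studies).

## Choosing the number of states

K is chosen by a dual criterion under leave-one-subject-out
cross-validation. For each candidate K the model is trained on all
subjects but one and used to decode the left-out subject. Two quantities
are computed per subject and averaged: the Calinski-Harabasz score of the
decoded Viterbi labelling of that subject's own data (clustering
quality), and a K-nearest-neighbour classification of which narrative the
subject heard, using the decoded expression probabilities as features
(cognitive sensibility). Both criteria are z-scored across the K grid
(default 2..10) and summed; the argmax wins, ties going to the smaller K.

Free choices the criterion leaves open, and what we chose: KNN uses k = 5
neighbours with majority vote and ties resolved by the single nearest
neighbour; features are the flattened T x K gamma matrix (probabilities
carry more information than the hard path); each fold's state labels are
aligned to a full-cohort reference model before feature construction,
since labels are otherwise arbitrary per fold; the CH score is capped at
1e12 when within-cluster dispersion vanishes. Note that with small
cohorts the chance level of leave-one-subject-out KNN sits *below* 1/C
for C balanced classes, because a subject's own class is depleted by one
in the training pool; the test suite computes this chance level by
simulation rather than assuming 1/C.

## State dynamics and surrogate nulls

From each subject's Viterbi path we compute fractional occupancy (time
share per state) and mean dwell time (mean contiguous run length x TR;
states never visited are NA, not zero). The transitional-hub statistic
asks whether some state receives a higher transition probability from
both other states than they exchange directly; its value is the mean of
the two differences, and zero when no state qualifies.

Significance is judged against circular-shift surrogates: every network
column of every subject is rotated by an independent uniform offset,
which preserves each column's marginal distribution and autocorrelation
while destroying cross-network covariance; the HMM is refitted on each
surrogate cohort and the hub statistic recorded. Empirical p-values use
the add-one convention (1 + #{null >= observed}) / (1 + n_perm) — never
exactly zero — with the raw exceedance proportion also reported.

A structural caveat the validation studies exposed, and which shaped the
power study's design: when individual networks carry strong state-related
mean shifts (loadings above ~1 z-unit), a single shifted column remains
strongly bimodal, surrogate fits simply track individual columns, and the
surrogate null inherits the chain's stationary asymmetry — it floors near
the true effect regardless of cohort size. The hub power study therefore
uses cohorts with loadings at half the default amplitude (where columns
are near-unimodal and the surrogate genuinely destroys latent structure)
and a pronounced hub (mean asymmetry 0.11), see `hubStudyGroundTruth()`.
The calibration study uses structureless white-noise cohorts. Because the
hub statistic is exactly zero whenever no state qualifies as a hub, the
null distribution carries ties at zero and the add-one p-value is
conservative rather than discrete-uniform; calibration is therefore
judged as type-I error not exceeding the nominal level.

## Per-state network topology

For each subject and state, the time points assigned to the state yield a
Pearson correlation graph over the nine networks. Negative weights are
set to zero (the common convention for weighted efficiency and
modularity; results are stated under it), edge lengths are reciprocal
weights, and we report weighted global efficiency (mean inverse shortest
path over ordered pairs; disconnected pairs contribute zero) and Louvain
modularity at resolution 1 (best of n runs). States are contrasted with
paired two-tailed t-tests, excluding subjects with insufficient occupancy
(fewer than N + 2 time points in a state). A model-derived variant
converts each state's fitted covariance to correlation and computes the
same metrics.

The resolution sweep for parcellation-style analyses runs Louvain at each
gamma (default 1.2 to 2.5 in steps of 0.01, 1000 runs each), scores
partition stability by the mean pairwise z-Rand score
(Traud-Kelsic-Mucha-Porter formulation, validated against a permutation
simulation), picks the medoid run as representative, and weights its
modularity by the mean z-Rand.

## Metastates

A finer HMM's transition matrix is reduced to metastates by agglomerative
clustering (average linkage). The similarity between two states combines
(i) the correlation of their transition profiles — outgoing row plus
incoming column, self-transitions zeroed, computed over positions
referring to neither state of the pair — and (ii) their direct mutual
mass, normalized by the matrix's largest mutual mass. Pure profile
correlation (an earlier design) fails on two-state blocks: each state
peaks exactly where the other is zeroed, so sibling states anti-correlate
and the direct-mass term is required; conversely direct mass alone cannot
isolate a hub state that exchanges mass with everyone, which the profile
term handles. Merged metastate patterns are unweighted averages of member
means, and decoded paths are relabelled by cluster.

Cross-run and cross-condition state matching follows a greedy confusion
rule: each candidate state's best-correlated predefined state is
computed; assignments are made in descending order of correlation with
already-taken states excluded, and a candidate that does not receive its
own top choice is marked "primed". Temporal correspondence between two
labelled sequences is summarized by per-state Jaccard indices and the
overall agreement fraction.

The nested generator used to validate this machinery splits each of the
three macro-states into sub-states (4/3/3 by default). Two properties are
required for the reduction to be identifiable at all, and are the
defaults: sub-states must switch quickly within their block (self 0.6,
within-block mass 0.94 — sticky sub-states leave the block structure
invisible in the transition matrix), and sub-state means must be
spatially distinct (perturbation sd 1.4 around macro patterns scaled to
2.5x — spatially indistinguishable sub-states let EM re-purpose duplicate
states arbitrarily). The reconstruction is scored against the generator's
macro truth; a comparison against a fitted K = 3 target is reported
descriptively, since that target fit carries its own noise at these
cohort sizes.

## Stimulus modulation

Three feature regressors are supported natively: the speech envelope
(magnitude of the FFT-based analytic signal, smoothed with a 50 ms moving
average), and word- and clause-level semantic coherence (cosine
similarity between consecutive item embeddings, optionally after
projecting the embeddings onto their first 50 principal components;
clause vectors average their words' vectors). Item or continuous signals
are convolved with a canonical double-gamma HRF (gamma shapes 7 and 17,
unit rate: response peak exactly 6 s, undershoot peak 16 s, 6:1 ratio,
32 s support, unit peak) and averaged within TR bins down to the 0.5 Hz
grid.

The modulation test correlates each subject's expression probability of a
state with the subject's own narrative's regressor, reports the group
mean, a two-tailed one-sample t-test, and an empirical p from circularly
shifting each subject's gamma column by independent offsets (default 5000
permutations); Benjamini-Hochberg correction runs across the
feature-by-state family.

## Behaviour

Comprehension is predicted from inter-subject alignment of state
expression: correlation with the best performer(s) of the subject's
narrative group (ties averaged, best performers excluded from the
correlation sample) and leave-one-out correlation with the group mean.
Head-motion similarity (framewise displacement by the Power convention,
50 mm head radius) serves as a covariate in a partial correlation
computed by the residual method, which is exactly the correlation of OLS
residuals — an identity the tests verify to 1e-12. Alignment samples are
pooled across narratives before correlating with scores. As the
comparison analysis, fractional occupancy and dwell time are correlated
with scores the same way.

## The synthetic cohort generator

`defaultGroundTruth()` encodes the study conditions: 64 subjects x 300
time points x 9 networks at TR 2 s (desk-scale studies reduce the subject
count, stated with each study), a 3-state Gaussian HMM whose mean vectors
load on sensory-motor, language + frontoparietal, and DMN +
frontoparietal groups, exchangeable within-state correlations (0.15,
0.35, 0.15 — the hub state is the most globally coupled), and a base
transition matrix with hub asymmetries of 0.06. Narrative drives (smooth
low-passed Gaussian random walks shared within a narrative) and stimulus
regressors tilt the transition kernel's log-odds, so inter-subject
correlation and feature coupling are emergent properties of the sampled
paths rather than being painted onto emissions. Feature regressors are
orthogonalized against the drives and each other within each narrative:
smooth signals of this length carry chance correlations around 0.2 that
would otherwise leak one feature's coupling into other states and make
selective modulation unidentifiable in principle.

The drive and coupling strengths (0.25 and 0.5 log-odds units) were
calibrated once, at design time, so that the cohort reproduces the
qualitative regime reported for this kind of data: narrative decoding
accuracy that rises with K without saturating at K = 2, clustering
quality that declines with K, modest within-narrative ISC, and selective
feature-state modulation. At stronger settings decoding saturates at
every K and the dual selection criterion degenerates; at weaker ones
nothing is detectable at desk scale.

Comprehension scores are `100 * logistic(3 * alignment + noise)` — the
logistic link keeps scores on the 0-100 percentage scale — where
alignment is the correlation between the subject's true hub-state
indicator and the narrative-group mean. FD traces are baseline plus noise
minus a small engagement term correlated with the same alignment.

What the generator does *not* emulate: spatially autocorrelated
measurement noise, scanner drift and physiological confounds, non-Markov
state durations, subject-level heterogeneity in state patterns, and any
relation between the embedding fixtures and real language. Passing
validation studies therefore demonstrates that the pipeline recovers what
it is designed to recover under its own assumptions — not that those
assumptions hold for any particular real dataset.

## Validation studies and their scales

The studies in `R/studies.R` (run by `scripts/acceptance.R` and asserted
by the test suite) use these problem sizes, chosen as the smallest at
which each property is stably identifiable: exact inference, 100 random
instances at K <= 3, T <= 8 against exhaustive enumeration; parameter
recovery, 10 homogeneous cohorts of 20 x 300 (drive and coupling at zero,
because the tilted chain's time-averaged kernel is not the base matrix —
comparing against it would measure the generator's Jensen bias, not EM);
K-selection, 10 cohorts of 12 x 300 over K = 2..6 with 5 restarts; hub
calibration, 100 white-noise cohorts of 4 x 100 with 50 permutations; hub
power, hub-identifiable cohorts of 32 x 300 with 100 permutations (10
cohorts in the test suite, 6 in the standalone script);
modulation calibration, 100 zero-coupling cohorts of 12 x 200 with 200
permutations; modulation power, 10 cohorts of 30 x 300 with 500
permutations; metastate reconstruction at 24 x 300; behaviour, 10
coupled cohorts of 30 x 300 with score noise at 0.25 so the planted
effect is detectable at this n.

## Known limitations

EM with likelihood selection can in principle prefer different local
optima than a variational fit; restarts mitigate but do not eliminate
this. The circular-shift surrogate carries structural hub signal whenever
single networks are strongly bimodal (see above), a property of the
surrogate itself that users should check on their own data by inspecting
the null distribution, not only its p-value. Hierarchical metastate
reduction is unreliable when sub-states are spatially indistinguishable
or sticky — mirroring the published observation that some finer models
fail to reduce cleanly. All behavioural analyses are correlational.
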