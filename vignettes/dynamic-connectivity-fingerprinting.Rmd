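---
title: "Dynamic and static connectivity fingerprinting: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic and static connectivity fingerprinting: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dynfc` implements a whole-brain functional-connectivity fingerprinting
pipeline for two-group classification: regional BOLD time series are turned
into edge features — either *static* connectivity (full-series Pearson
correlation, Fisher z-transformed) or *dynamic* connectivity (the standard
deviation of a tapered sliding-window correlation series) — and a linear
max-margin classifier with nested univariate feature selection is evaluated
by leave-one-out cross-validation (LOOCV), with inference by whole-pipeline
label permutation and anatomy read-outs from the signed classifier weights.
This vignette explains the models and the choices behind every tunable
parameter, what the synthetic cohort generator does and does not emulate,
and the statistical pathologies a user of this protocol should know about.

## Connectivity estimators

**Static connectivity.** For a T×N matrix of node signals, entry (i, j) is
`atanh(r_ij)` with the Pearson correlation clipped at |r| = 1 − 1e-7 so the
transform stays finite under perfect collinearity. The diagonal is defined
as 0 and excluded from features. A node with zero variance would produce
undefined correlations; its edges are set to 0 with a warning, keeping the
feature dimension fixed across subjects.

**Sliding windows.** A window specification (length w, step s, taper) yields
`floor((T − w)/s) + 1` windows; with the default w = 50 samples, s = 1 a
175-sample series gives 126 windows. Window accounting is in samples
(1-based, inclusive); seconds are samples × TR. The Hamming taper enters as
*weighted-moment* correlation — weighted means, variances and covariances
with weights normalized to sum 1 — which is the dominant convention in
tapered dynamic-connectivity work; the plausible alternative
(pre-multiplying the signal by the taper) changes window means and is not
used. A rectangular taper is retained as an option, mainly because it makes
the single-window case collapse exactly onto the static estimator, a useful
oracle in the test suite.

**Dynamic connectivity.** Entry (i, j) is the sample standard deviation
(denominator K − 1 over K windows; recorded in output metadata, as the
convention is not universal) of the windowed Fisher-z series. It needs at
least 2 windows. Values are non-negative; a large value means the pair's
coupling swings in and out of synchrony across the scan.

**Global-signal regression (GSR).** The regressor is the unweighted mean of
the N node signals (voxel-level global signals are upstream of this
package's contract); each node is replaced by its least-squares residual
after regressing out that mean plus an intercept.

## Classification protocol

Features are the N(N−1)/2 strictly-upper-triangle entries in row-major
order, so weights map back to node pairs deterministically. In each LOOCV
fold the pooled-variance two-sample t-test is computed per feature on the
training rows only, features with p strictly below the threshold (default
0.01; 0.5 and 0.001 are the usual sensitivity settings) are retained, and a
linear support-vector machine with C = 1 is fit. Nested (per-fold)
selection is the default because selecting before cross-validation leaks
the held-out subject into the filter; the non-nested variant is available
for comparison since published protocols are often ambiguous on this point.
If a fold selects nothing, it falls back to all features with a warning
rather than failing. Decision scores are oriented so positive means
patient; a score of exactly 0 is assigned to control. ROC curves pool
held-out scores across folds; AUC equals the normalized Mann–Whitney
statistic with ties counted ½.

The permutation test shuffles all subject labels and reruns the *complete*
pipeline — including per-fold selection — for each permutation, so the null
distribution reflects every adaptive step. The default p-value is the
+1-corrected estimator `(1 + #{null ≥ observed})/(B + 1)`, which cannot be
0; the plain proportion of null accuracies strictly above the observed one
is available and reproduces "p < 1/B"-style reports. Rerunning selection
inside every fold of every permutation is the dominant cost; the package
default B = 5000 is appropriate for a report, while the examples and tests
use B in the tens to hundreds.

**Pooled t, not Welch.** The pooled (Student) form matches the classical
"2-sample t-test" usage in this literature, including its demographics
tables; Welch is available in spirit by prefiltering, but the filter is a
ranking device, not an inference, so the distinction has little effect.

## Network anatomy

One weight vector is needed to speak about edges, but LOOCV produces one
per fold. The default "anatomy model" refits the classifier once on all
subjects with features selected on the full sample — a description of the
fitted discriminant, not an out-of-sample claim — and a consensus mode
(mean of fold weights over features selected in at least half the folds) is
provided as a robustness companion. Edges split by weight sign into a
positive (evidence toward patient) and a negative (toward control) network;
node degree is the number of incident edges within a signed network, hubs
are the k = 25 highest-degree nodes with ties broken by ascending node id,
and the fingerprint counts hubs per canonical network label. The package
ships only a deterministic toy label table; real analyses must supply their
atlas's assignment.

## The synthetic cohort generator

No imaging data ships with the package; the generator provides ground truth
for every downstream stage. It is a latent-factor model in which **planted
couplings are target instantaneous correlations**: every node has unit
variance by construction, a planted edge (i, j) carries a shared factor
entering node i with loading `sqrt(|c(t)|)` and node j with
`sign(c(t))·sqrt(|c(t)|)`, and private noise absorbs the complement. In
patients `c(t) = static_effect + dynamic_effect·s(t)` with `s(t)` a
mean-centered square wave flipping every `regime_length` samples (random
starting sign per subject and edge); in controls planted couplings are 0.
Consequences, verified in the tests: a dynamic effect swings windowed
correlation while cancelling from the full-series correlation; a static
effect shifts mean correlation only; node variances are identical across
groups, so nothing leaks into unplanted edges; and with both effects 0 the
groups are exchangeable. Planted edges form a node-disjoint matching so
each target correlation is exactly realizable, capping their number at
`floor(N/2)`.

Realism beyond the planted effects, with defaults chosen once:

* **Global component** (`global_signal_sd = 0.5`, about 20 % of node
  variance): a shared signal whose amplitude is log-normally jittered
  across subjects (sd 0.4) — subjects genuinely differ in global
  fluctuation strength, which is what makes GSR consequential — and drifts
  slowly within the scan (`global_dynamics_sd = 0.3`, AR(1) with
  coefficient 0.95 on the log amplitude), an arousal-like nonstationarity
  that gives all edges a shared component of windowed-correlation
  variability.
* **Temporal structure**: every signal passes an AR(1) filter
  (`ar_coef = 0.3`, per-subject sd 0.12) and a 3-sample moving average; at
  TR = 2 s the moving average has its low-pass cutoff near 0.074 Hz,
  emulating the 0.01–0.1 Hz character of preprocessed BOLD.
* **Geometry of regimes**: `regime_length = 50` samples by default. Regimes
  much shorter than the analysis window cancel within it — with w = 50, a
  25-sample regime leaves almost no windowed-correlation signature — so the
  default matches the window scale.
* `noise_sd` is an overall scale; correlation-based analyses are invariant
  to it.

The generator does **not** emulate hemodynamic response shapes, motion or
physiological artifacts, spatial autocorrelation between nodes, site
effects, or non-Gaussian BOLD features. Passing recovery tests therefore
shows the pipeline recovers the *kind* of effect it claims to detect, not
that it would perform identically on real data.

## Default analysis scale

The reference analysis used across tests and the acceptance script is
20 + 20 subjects, 30 nodes (435 edge features), T = 175 samples (126
windows at w = 50, s = 1), effects of 0.6 on 13 planted edges, and B in the
hundreds for permutations. These sizes make a complete dual-kind analysis,
including permutation inference, run in well under a minute on one core
while keeping every statistical contrast comfortably powered; the null
calibration study uses 50 cohorts of 10 + 10 subjects with 16 nodes for the
same reason.

## Below-chance LOOCV accuracy: a real pathology, faithfully reproduced

Users of this protocol should expect a counter-intuitive behaviour that the
package reproduces deliberately. When the features carry *no* group signal
and the selection filter is sparse (p < 0.01 keeps a handful of hundreds of
features), LOOCV accuracy does not hover near 50 %: it is wildly dispersed
across cohorts and often collapses far below chance. The mechanism is
selection conditioned on the held-out subject's absence: removing a subject
shifts its class's training mean away from it, the filter preferentially
retains features where that shift sharpened the spurious separation, and
the held-out subject then falls on the wrong side of the margin — in the
extreme, for every fold at once. A strong shared axis across features (the
global-amplitude axis of static connectivity, PC1 on the order of 80 % of
variance) dilutes the effect, which is why static null accuracies centre
near chance while dynamic-connectivity features — nearly independent across
edges — can invert almost completely. Two practical consequences: (1) a
below-chance accuracy (such as a static-connectivity classifier scoring
around 38 %) is a signature of a null, unstable feature set, not of
information; (2) only the permutation test, which pushes every permuted
labelling through the identical pipeline, yields a calibrated p-value —
comparing accuracy to 50 % does not. This is also why one arm of the
package's own recovery checks (the dynamic-connectivity classifier applied
to a cohort whose only effect is static) sits near 0 rather than near
0.5: the honest behaviour of the protocol, not a defect of the
implementation.

## Numerical choices and degenerate inputs

* Fisher z clipping at |r| = 1 − 1e-7; windowed estimates of identical
  nodes therefore show sub-1e-6 jitter rather than exact zeros.
* Dynamic variance accumulation guards against tiny negative rounding
  before the square root.
* Zero-variance nodes: edges set to 0 plus a warning (fixed feature
  dimension beats propagating NaN).
* Two-sample t with zero pooled variance: t = 0, p = 1 when means agree;
  p = 0 sentinel with a warning when they differ.
* Ties at exactly p = threshold are excluded (strict inequality).
* Seeds: cohorts are pure functions of their configuration; the permutation
  test takes its own seed; the pipeline driver reruns byte-identically for
  identical inputs and seed.

## Known limitations

LOOCV variance is high at these sample sizes, and fold-to-fold classifiers
are strongly correlated; accuracies should always be read together with the
permutation p. The anatomy refit describes the in-sample discriminant —
hub lists from 40-subject cohorts are illustrative, not inferential. The
package consumes cleaned ROI-level series by contract: no image-space
preprocessing, filtering, scrubbing, or atlas extraction is performed, and
the toy atlas labels exist so the fingerprint machinery can be exercised,
not to stand in for a real parcellation's network assignment.
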