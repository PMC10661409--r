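---
title: "Resting-state EEG features for AD/CN discrimination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG features for AD/CN discrimination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

Resting-state EEG in Alzheimer's disease shows three robust group effects
relative to cognitively normal (CN) controls: *spectral slowing* (power
shifts from alpha/beta/gamma toward delta/theta), *reduced signal
complexity* (lower entropy), and *decreased inter-channel synchrony*
(weaker functional connectivity). `adeeg` implements a complete epoch-level
analysis built around these effects:

1. **Preprocess** each 19-channel recording: re-reference to linked
   mastoids (A1–A2) when present, zero-phase Butterworth band-pass
   0.5–45 Hz, excise any 0.5-s window whose per-channel sample SD exceeds
   17 µV, and cut 4-s epochs with 50% overlap.
2. **Extract 18 features per epoch** in three families:
   - *spectrum*: mean, variance (N−1 denominator), IQR, the five relative
     band powers (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–25, gamma
     25–45 Hz) and total 0.5–45 Hz power from a Welch PSD;
   - *complexity*: approximate entropy (m = 1, r = 0.2·SD), permutation
     entropy (order 3), sample entropy (m = 2, r = 0.15·SD), and
     multiscale (coarse-grained) sample entropy at scale τ = 5;
   - *synchronization*: mean degree, mean clustering coefficient
     C_i = 2e_i/(k_i(k_i−1)), characteristic path length L, global
     efficiency, and small-worldness σ = γ/δ of the graph obtained by
     thresholding the absolute channel-correlation matrix at 0.7.
3. **Compare groups** feature-by-feature with Welch two-sample t-tests
   (direction = sign(mean AD − mean CN), stars at 0.05/0.01/0.001, no
   multiple-testing correction — the stars are descriptive).
4. **Classify epochs** as AD/CN with a decision tree, a random forest, or
   an RBF SVM under leave-one-person-out cross-validation (LOPO-CV): every
   epoch of one subject is the test set, all other subjects train the
   model, features standardized with training-fold statistics only.

## Parameter conventions worth stating

Several quantities of this kind differ across software conventions; the
package fixes them explicitly:

- **IQR** uses linear-interpolation ("type 7") quantiles; other quantile
  types give different IQRs on short series.
- **Welch PSD**: 1-s Hamming-tapered segments with 50% overlap inside each
  4-s epoch (7 averages, ~1 Hz resolution). The estimator variant is
  configurable; this default trades resolution against variance at the
  epoch lengths used here. Band energies are trapezoidal integrals of the
  density with ordinates interpolated at the band edges, so the five bands
  partition the 0.5–45 Hz total exactly and relative band powers sum to 1.
- **Band edges** are half-open `[lo, hi)` so 4, 8, 13 and 25 Hz are never
  double-counted.
- **ApEn/SampEn** compare templates under the Chebyshev
  (maximum-coordinate) distance. ApEn includes self-matches (Pincus
  convention); SampEn excludes them and counts unordered pairs over the
  N − m templates of the Richman–Moorman construction. A constant series
  has ApEn = PermEn = 0 by definition; a series with no (m+1)-template
  match has undefined SampEn and the epoch is dropped with a logged count.
- **PermEn** maps each window to the permutation that sorts it, ties
  broken by the earlier index (stable sort); natural log, unnormalized, so
  the maximum is ln n!.
- **MSE** anchors the tolerance r to the SD of the *original* series
  (common practice; a switch recomputes it on the coarse series) and
  reports the single scale-τ value (a switch averages scales 1…τ). Both
  choices are exposed because the convention is not universal.
- **Graphs**: binarization uses an inclusive threshold (entry ≥ 0.7 is an
  edge). C_i is defined 0 for nodes of degree < 2. Disconnected pairs are
  excluded from L (with the connected fraction logged) and contribute 0 to
  efficiency. The small-world null model is 20 degree-preserving
  double-edge-swap rewirings (10 × |E| swap attempts each, seeded); for
  graphs the swaps cannot change (complete, empty) σ = 1.
- **Artifact screen**: the 0.5-s window-SD rule (threshold 17, treated as
  microvolts of the calibrated signal) is a deliberately simple,
  fully reproducible screen applied before epoching; it does not attempt
  component-based artifact removal, and excise-and-concatenate seams are a
  known cost of that simplicity. Rejection is idempotent.
- **Filtering** is order-4 Butterworth applied forward–backward
  (zero-phase), chosen so filter latency cannot distort the entropy
  features; the effective roll-off is therefore that of the squared
  magnitude response (~7% residual RMS at 60 Hz, not an ideal brick wall).

## The 18-feature composition

The three time-domain statistics, five relative band powers, total
spectral power, four entropies and four classic graph metrics enumerate
17 features; mean degree — a natural graph summary already needed to
interpret the thresholded networks — is included as the 18th. The
composition is fixed in `feature_names` and asserted by the tests.

Scalar features are computed per channel and averaged across the 19
channels (`channel_aggregate = "feature_mean"`); a switch computes them on
the across-channel mean signal instead (`"signal_mean"`), since averaging
signals before or after feature computation are both defensible readings
of common practice. Network features are computed once per epoch from the
all-channel graph.

## Classifier settings

Hyperparameters are deliberately plain and config-exposed: decision tree
with Gini impurity and default `rpart` growth; random forest with 100
trees; SVM with RBF kernel, cost 1, and bandwidth from the median
heuristic (γ = 1/(2·median pairwise squared distance) on a deterministic
subsample of ≤ 300 training rows). Per-fold seeds derive deterministically
from the master seed, so every CV result is bit-reproducible.

## The synthetic cohort generator

No clinical recordings ship with the package; a seeded generator
(`generate_cohort`) produces CN-like and AD-like cohorts so every stage is
testable. Per rhythm, a latent source is white noise passed through an
AR(1) recursion (coefficient = `regularity`), restricted to the rhythm's
band by an FFT mask (disjoint supports make the five sources exactly
orthogonal, so realized band powers track the target profile), and scaled
to the profile's variance fraction. Each channel mixes `coupling` × the
shared source sum with (1 − `coupling`) × an independently drawn
per-channel sum, plus `noise_sd` × white noise, scaled to 10 µV RMS.

Defaults are the package's study conditions: 10 CN + 10 AD subjects,
2-minute recordings at 500 Hz, with

| group | δ/θ/α/β/γ profile | regularity | coupling | noise_sd |
|------|--------------------|------------|----------|----------|
| CN | 0.20/0.15/0.35/0.20/0.10 | 0.30 | 0.62 | 0.10 |
| AD | 0.35/0.25/0.20/0.12/0.08 | 0.65 | 0.60 | 0.10 |

The profiles encode slowing; the AR(1) coefficient encodes reduced
complexity; the coupling fraction encodes reduced synchrony. The
literature gives no quantitative effect sizes for these knobs, so the
values are design choices, fixed once from pilot simulations with three
aims: each effect family clearly expressed, correlation graphs in a
non-degenerate density regime at the 0.7 binarization threshold (CN ~0.75,
AD ~0.4 edge density, so path length is defined for essentially every
epoch), and window SDs of clean data comfortably below the artifact
threshold (10 µV RMS vs 17). They are conditions for testing the
machinery, not estimates of clinical effect sizes. The 10 µV amplitude
only affects mean/variance/IQR/total power, which is intended.

Generated subjects get seeds derived deterministically from the master
seed (a fixed integer hash of seed and subject index), so cohorts are
bit-reproducible and individual recordings can be regenerated in
isolation.

### What the generator does and does not emulate

It emulates group-dependent band-power profiles, signal regularity and
inter-channel coupling — nothing else. There is no 1/f background, no
alpha peak structure, no nonstationarity, no eye-blink or muscle
artifacts, no volume conduction or electrode geometry, and its
connectivity is homogeneous (every channel pair shares the same latent
sources). Passing tests therefore show that the *machinery* — filters,
estimators, graph metrics, cross-validation — behaves correctly and
recovers implanted effects; they say nothing about classification
performance on clinical EEG.

Two consequences of the simple construction are worth knowing:

- **Permutation entropy** at 500 Hz native sampling is dominated by
  sample-to-sample content near and above the band edge, where the groups
  barely differ; across every knob setting explored in pilot runs its
  group difference is tiny and tends to the *opposite* sign of the
  clinical expectation. The generator's complexity knob simply does not
  reach order-3 ordinal statistics at this sampling rate.
- **Small-worldness** of thresholded homogeneous-correlation graphs is
  density-driven with a heavy-tailed epoch distribution; since AD graphs
  are sparser by construction, σ does not reliably fall in AD the way it
  does in clinical cohorts, whose networks have genuine topological
  structure to lose. The corresponding acceptance check is left failing
  rather than redefining the generator around it.

## Degenerate inputs

Zero-power epochs (RBP undefined) and epochs with undefined sample
entropy or an edgeless graph are dropped from the feature table with a
logged count. A constant channel's correlations are set to 0 with a
notice. Recordings without mastoid channels pass re-referencing unchanged
(the synthetic montage carries none). Recordings shorter than one epoch
yield an empty epoch set with a warning.

## Problem sizes used by the tests

The test suite verifies estimator correctness against naive
direct-from-formula oracles (50 random series of length 100–500 for the
four entropies at 1e-10; 100 random graphs of ≤ 8 nodes for the graph
metrics at 1e-12) and runs the cohort-level checks on the default
10 + 10 × 2-minute cohort (~1,180 epochs), sizes chosen to exercise every
code path at desk scale. Structural unit tests use smaller cohorts
(seconds of signal at 100–250 Hz), which is why their absolute feature
values are not comparable to the study cohort's.

## Known limitations

Beyond the generator simplifications above: ICA/component-based artifact
removal is out of scope (the window-SD screen is the only artifact
handling); sub-band splits (α1/α2, β1–β3), alternative synchrony
estimators (Granger causality, phase coherence), source localization and
subject-level severity staging are not implemented; EDF I/O is not
provided — recordings are exchanged as delimited text matrices with a CSV
subject table.
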