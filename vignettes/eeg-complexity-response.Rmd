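---
title: "Predicting oxcarbazepine response from EEG complexity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting oxcarbazepine response from EEG complexity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Oxcarbazepine (OXC) is a first-line antiseizure medicine for newly diagnosed
focal epilepsy, but roughly a third of patients are not seizure-free (Engel
class II–IV) after a year of monotherapy, and there is no accepted biomarker
for predicting who will respond before treatment starts. `oxceeg` implements
a candidate pipeline: nonlinear complexity features of the pre-treatment
scalp EEG, fused with routine clinical covariates, feeding cross-validated
classifiers of the seizure-free (SF) versus not-seizure-free (NSF) outcome.

The package covers the full chain — synthetic cohort generation, EDF I/O,
preprocessing, two complexity estimators, feature assembly, SMOTE class
balancing, cross-validated gradient-boosted trees (GBDT) and linear SVM with
recursive feature elimination (RFE), and the cohort-comparison statistics —
with every stage seeded and tested. Because no patient EEGs are distributed
with the package, the synthetic cohort generator is a first-class module: it
emulates the statistical structure the analysis assumes and lets every
downstream claim be exercised end to end.

## Complexity estimators

Both estimators operate on binarized versions of a band-filtered,
average-referenced 15-s epoch (3 840 samples at 256 Hz) and share one
parsing primitive.

**LZ76 production parsing.** A binary sequence is scanned left to right; the
current word is extended while it can be reproduced as a substring of the
history extended to one symbol before the current position, and the first
extension that breaks reproducibility closes the word. The word count
$c(n)$ satisfies $c(n) \to n / \log_2 n$ for equiprobable random sequences,
which motivates the normalizer $b(n) = n / \log_2 n$.

- **Lempel–Ziv complexity (LZC):** the signal is binarized at its median
  (strictly above → 1, ties → 0) and
  $\mathrm{LZC} = c(n) / b(n)$. Median binarization depends only on ranks,
  so LZC is invariant under strictly monotone transforms of the signal.
- **Kolmogorov complexity (KC):** the true shortest-program length is
  uncomputable, so it is estimated on the *difference-binarized* sequence
  (positive successive difference → 1, otherwise 0; length $m = n-1$) with
  the Kaspar–Schuster normalization $c(m)\,\log_2 m / m$. Differences keep
  their signs under positive affine maps, so KC is affine invariant. A
  constant or monotone signal hits the floor $2 \log_2 m / m$.

The parser is implemented exactly (suffix automaton with minimal occurrence
end positions, linear time) and is pinned, exhaustively for all binary
strings up to length 12 and on 1 000 random strings, to a brute-force
substring-search oracle that is kept deliberately naive and independent.

Complexity is computed per (epoch, channel, band) and averaged over the 15
selected epochs to give one feature per channel–band pair. The mean is the
least-structured aggregation rule; classifying epochs individually would
multiply the sample size by 15 with strongly dependent rows, which we avoid.

## Preprocessing

1. zero-phase (forward–backward) Butterworth band-pass 0.5–30 Hz, order 4;
2. decomposition into the conventional clinical bands δ 0.5–4, θ 4–8,
   α 8–13, β 13–30 Hz (the four bands tile the broadband range);
3. segmentation into non-overlapping half-open 15-s windows starting at
   sample one, with 15 windows selected uniformly without replacement under
   a named seed (an optional per-window eligibility mask stands in for
   expert artifact/discharge vetting);
4. average reference: the instantaneous cross-channel mean is subtracted.

Filter order and band edges are package choices (they are the standard
clinical conventions); filters are designed by `signal::butter` and applied
by a C++ forward–backward kernel with 3 s of odd-reflection padding and
steady-state initial conditions. The padding length matters: the band-edge
poles have time constants of a few hundred samples, and 3 s makes boundary
transients negligible, which is also what makes zero-phase filtering commute
with time reversal in the tests. Because every stage is linear and identical
across channels, filtering the continuous recording and then slicing epochs
is exactly equivalent to filtering each epoch (this equivalence is asserted
to machine precision in the test suite); the package uses the continuous
order, which also avoids epoch-boundary transients. For narrow bands the
steady-state initial-condition system is numerically singular (a pole sits
next to $z = 1$); the minimum-norm solution is used, which is the right
limit because the near-null direction is the DC mode the band-pass rejects.

## The synthetic cohort generator

The generator defines the study conditions: 52 SF and 22 NSF subjects, 19
channels of the 10–20 system, 256 Hz, 15 epochs of 15 s per subject.

**EEG model.** Each channel is a sum of four band-limited oscillators (one
per clinical band, centre frequencies 2, 6, 10, 20 Hz; relative amplitudes
1.0, 0.7, 0.8, 0.45, a 1/f-flavoured profile) whose phases drift as a
smoothed random walk (drift steps of sd 0.3 rad per 0.25 s knot), plus white
Gaussian noise. Oscillation and noise are mixed by a per-subject noise
fraction $\nu$ and scaled to a 50 µV amplitude:
$x = 50\,[(1-\nu)\,\mathrm{osc} + \nu\,\mathrm{noise}]$. Complexity
estimators respond monotonically to the noise fraction, so drawing $\nu$
from class-dependent distributions (means $0.5 \mp e/2$ for SF/NSF, sd 0.05)
plants the empirically observed ordering — NSF more complex than SF — with a
single controllable knob, the effect size $e$.

**Clinical model.** The 15 covariates are sampled class-conditionally from
the reference cohort's marginal tables: categorical features from the
contingency counts, skewed positive quantities (ages, seizure frequency)
from log-normals matched to the median/IQR summaries, and follow-up time
from a normal matched to the mean/SD summary (truncated at one month). Covariates are mutually independent given the class label — the
reference tables publish only marginals, so any joint structure would be
invented; consequently the generator cannot test methods that exploit
covariate interactions.

**One knob controls all class separation.** The clinical tables are strongly
class-separated (seizure frequency most of all), so a generator that always
used them would leak class information even with identical EEG, and a
"no-effect" cohort would not be chance-level. The generator therefore
interpolates the clinical class-conditional parameters between the pooled
cohort (at $e = 0$: the two classes are statistically identical in every
respect) and the reference tables (reached at the default $e = 0.3$ and
above). At the default effect size the clinical marginals match the
reference tables exactly in expectation, which is what the calibration tests
check at $n = 5\,000$; at $e = 0.6$ the class noise fractions are 0.2 / 0.8,
the strong-effect condition used for planted-effect recovery.

What the generator does **not** emulate: epileptiform discharge morphology,
sleep staging, eye-blink/EMG artifacts, volume-conduction correlations
between channels, or any within-class correlation between covariates and
EEG. Passing tests therefore demonstrate the correctness and statistical
sanity of the *pipeline*, not clinical performance on real EEG.

## Class balancing and cross-validation

**SMOTE** (from scratch, as specified): each synthetic minority row is
$x_i + g\,(x_{nn} - x_i)$ with $g \sim U[0,1]$ and $x_{nn}$ one of the $K=5$
nearest minority neighbours (Euclidean distance); oversampling proceeds
round-robin over minority rows until the classes are exactly equal, original
rows stay first, and neighbour search never crosses class boundaries. When a
training fold's minority has at most $K$ members, $K' = \text{minority}-1$
is used instead of failing.

**Cross-validation** is stratified five-fold (stratification is required:
22 NSF over five unstratified folds would occasionally produce single-class
folds). Inside each fold, strictly train-only: the feature scaler (SVM
only), SMOTE, RFE (SVM only), and the classifier are fitted on the training
rows and the held-out fold is only scored. The per-fold fitted state is
checksummed, and the leakage audit recomputes it from the training rows
alone. Reported means are arithmetic averages over folds, not
pooled-confusion metrics.

- **GBDT:** gradient-boosted trees (via xgboost) at the standard GBM
  defaults — 100 trees, learning rate 0.1, depth 3 — single-threaded for
  determinism. Feature importance is impurity gain, the default tree
  importance, standing in for "absolute weights" which are undefined for
  trees. Scores are class probabilities; no scaling (trees are
  scale-invariant).
- **SVM:** linear kernel, $C = 1$ (e1071/libsvm), on z-scores fitted from
  the training rows. RFE removes 10% of the remaining features per
  iteration, recording nested subsets at sizes {all, 64, 32, 16, 8}; the
  retained set is chosen by 3-fold cross-validated accuracy within the
  training rows (ties favour the larger subset). Ranking uses
  $|w|$ of the separating hyperplane; scores are decision values.

The positive class is SF: with a 52/22 cohort, a recall near 0.9 alongside
specificities of 0.2–0.6 is only arithmetically possible when the majority
class is scored positive, and the unique small confusion matrix consistent
with the fold-1 worked-example panel (TP 9, FP 4, TN 1, FN 1) confirms it.
Undefined ratios (zero denominators) are reported as `NA`, never silently 0;
AUC uses midranks, so constant scores give exactly 0.5.

## Cohort statistics

Categorical features: Pearson chi-square **without** continuity correction —
the only variant that regenerates the reference statistics from their
group counts (e.g. family history 2/50 vs 2/20 → 0.832), including rows
with small expected counts. Quantitative features: Shapiro–Wilk on each
group at α = 0.05; both normal → pooled-variance t; otherwise Mann–Whitney
with the tie-corrected normal approximation Z (midranks, no continuity
correction, matching the convention of standard statistical packages at
n = 52/22). Benjamini–Hochberg correction is applied within a table family
(the EEG-feature comparisons form one family), not across tables. Two rows
of the reference clinical table do not regenerate from their group counts
by any standard chi-square variant (physical development and CNS infection,
apparent transcription errors); they are excluded from the reproduction
checks.

## Problem sizes and numerical choices

The planted-effect experiments run at the reference cohort size (74 subjects,
15 × 15-s epochs, 19 channels): 20 null cohorts (effect 0), 10 strong-effect
cohorts (0.6), and 20 label permutations of one default cohort. These sizes
put the chance-level band at roughly ±0.05 of AUC (3 standard errors over 20
seeds) while keeping the whole experiment within minutes on one core. Unit
and property tests use reduced cohorts (2 epochs, a dozen subjects), which
the streaming generator makes cheap; the acceptance checks are the ones run
at full scale.

Other numerical choices worth recording: epoch windows are half-open and
start at sample one; binarization ties map to 0 (deterministic, and constant
signals become minimal-complexity); zero differences in the KC binarization
map to 0 (a measure-zero event for continuous signals); chronological order
is kept after random epoch selection; every random draw (cohort, epoch
selection, SMOTE, folds, model) is controlled by a named seed, and derived
seeds stay within the 32-bit integer range.

## Known limitations

- The KC estimator is one member of a family; any compressor-based
  estimator satisfying the same invariances could be substituted; the choice
  is a convention, not a determined quantity.
- Independent-component artifact removal is out of the core pipeline
  (synthetic recordings are artifact-free); real-EDF users should clean
  their data upstream or rely on the per-epoch eligibility mask.
- Follow-up time is a post-treatment variable yet is listed among the 15
  clinical features; it is included by default for fidelity to the
  reference feature set, with `drop_follow_up` to exclude it.
- Reported classification performance on synthetic cohorts characterizes
  the pipeline under a known generative model, nothing more; no claim about
  real-EEG performance follows from it.
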