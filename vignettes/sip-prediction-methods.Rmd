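---
title: "Predicting self-interacting proteins from PSSM profiles: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting self-interacting proteins from PSSM profiles: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A self-interacting protein (SIP) is one whose identical copies bind each
other — homodimers and higher homo-oligomers. SIPs matter for enzyme
function, signalling and structural assembly, but experimentally confirmed
SIPs are scarce: curated sets contain roughly one positive for every eight to
eleven proteins (1441 SIPs against 15,938 non-SIPs in a curated human set;
710 against 5,511 in yeast). `sippred` predicts SIP status from sequence
profiles alone, with a pipeline built for exactly this regime: a fixed-length
profile feature, an unsupervised reduction, and an ensemble classifier whose
decision threshold adapts to the class imbalance.

```{r setup}
library(sippred)
```

## From sequence to a fixed-length feature

**PSSM.** Each protein is represented by an `H x 20` position-specific
scoring matrix (PSSM), the per-position amino-acid scores produced by
iterative profile search (PSI-BLAST, typically run at E-value 0.001 for 3
iterations; this package parses the ASCII output rather than running the
search). `parse_psiblast_pssm()` keeps the 20 log-odds columns and ignores
the percentage columns; the choice of log-odds over percentages is a package
decision — the two carry the same ranking information, and log-odds are what
the format's first block stores. When only a residue-frequency profile is
available, `pssm_from_profile()` computes the score of residue `b` at
position `a` as `sum_k p(a, k) q(b, k)` with `q` a Dayhoff-model mutation
matrix (PAM250 by default).

**FIR filtering.** The 20 columns of the PSSM are treated as signals along
the sequence and smoothed with a finite impulse response (FIR) low-pass
filter designed by the window method: the ideal low-pass impulse response
`h_d(n) = sin(w_c n) / (pi n)` is truncated to `N` taps and multiplied by a
window sequence. The filter acts as a conservation-profile smoother:
low-pass filtering emphasises runs of conserved positions over single-site
noise. The designed filter can be verified against the ideal response through
its integral square error (`integral_square_error()`); for rectangular
windows this error decreases monotonically in `N`, which the test suite
asserts.

The filter's cutoff, order and window are not determined by the method
itself, so the package fixes documented defaults: cutoff `0.3 * pi`, `N = 7`
taps, Hamming window. A short odd-length symmetric filter keeps linear phase,
has an integer-aligned centre, and does not wash out short sequences (the
curation rules admit proteins of only 50 residues). All three are
configurable through `pipeline_config()`.

One genuine ambiguity is the order of operations: filtering the `H x 20`
PSSM and then forming a Gram matrix, versus forming the `20 x 20` Gram matrix
first and filtering it. The package filters the PSSM columns first
(`firf_apply_to = "pssm_columns"`): filtering along the sequence is the only
reading in which the filter sees the signal structure that motivates it —
filtering a 20 x 20 matrix would make sequence length irrelevant to the
filter entirely. The alternative reading is preserved as
`firf_apply_to = "gram_rows"`.

**Gram features.** Sequences have different lengths, so the filtered matrix
`F` is collapsed into the `20 x 20` Gram matrix `t(F) %*% F`, whose row-major
flattening is the 400-dimensional feature vector. The Gram matrix is
symmetric positive semi-definite by construction, and its dimension is
independent of `H` — the property the whole construction exists for.
Convolution uses zero padding with same-length output and the filter centre
aligned, so `F` keeps its `H` rows; flattening is row-major by convention
(symmetry makes the choice harmless, but it must be fixed for
reproducibility).

**PCA.** The 400 features are reduced to 300 principal components
(`fit_pca()`), centring only — no variance scaling, since the Gram entries
share a scale. Eigenvector signs are fixed by making each component's
largest-magnitude loading positive, so fits are deterministic. By default PCA
is fit on the training folds only and applied to held-out folds; fitting it
once globally is available (`pca_global = TRUE`) but mixes test information
into the reduction, which is why it is not the default. When fewer than 301
samples are available the requested 300 components exceed the data rank and
the model truncates to the rank with a message — this is the normal situation
in the package's small synthetic runs.

## The random-projection ensemble

The classifier draws `B1 * B2` random `q x n` projection matrices with
unit-norm columns (Gaussian on the sphere by default, or Bernoulli ±1), and
partitions them in sampling order into `B1 = 10` non-overlapping blocks of
`B2 = 30` candidates. Within each block, every (projection, `k`) pair — `k`
from the grid `seq(1, 30, by = 8)`, i.e. {1, 9, 17, 25} — is scored by the
leave-one-out error of a k-nearest-neighbour classifier on the projected
training set, and the best pair is kept. Selection is per block and joint
over (projection, `k`); the alternative of a single global `k` is not what
"chosen from a block ... smallest estimate of the test error" describes.

Prediction aggregates the `B1` selected block classifiers: each block votes
by kNN on its own projected training set, and a sample is called positive
when the fraction of positive votes reaches the **voting threshold**, set to
the positive-class prior of the training labels. On balanced data this is
majority voting; at a 1:11 imbalance the threshold is ~0.083, so a single
positive block vote in ten already flags a SIP. This data-driven threshold is
what lets the ensemble keep non-trivial sensitivity at extreme imbalance,
where a 0.5-threshold vote would collapse to the majority class.

Determinism is enforced everywhere randomness or ties appear: the whole
ensemble is a function of one seed; kNN distance ties break toward the
smaller training index; kNN vote ties and vote fractions exactly at the
threshold are called positive. The projected dimension `q` is not pinned down
by the method; the default is `q = 5`, a standard operating point in the
random-projection ensemble literature, configurable and required to be
smaller than the feature dimension.

The kNN base learner and its leave-one-out estimate are implemented in the
package rather than delegated, because the deterministic tie rules above are
part of the method's contract and off-the-shelf kNN implementations break
ties at random. The test suite checks the implementation exhaustively against
a brute-force `O(N^2)` oracle on all small instances, including
deliberately tied distances.

## Evaluation

`run_cv()` performs stratified five-fold cross-validation: each class is
shuffled (seeded) and dealt round-robin, so per-fold class counts deviate by
at most one. Stratification is a package choice made for stability on
imbalanced data — with ~0.9 negatives, unstratified folds can fluctuate
enough to destabilise per-fold precision. Each fold reports the confusion
counts and accuracy, sensitivity, specificity, precision and Matthews
correlation coefficient, with any zero-denominator metric flagged as
undefined rather than coerced to 0; the summary row is the mean and
sample (n−1) standard deviation over folds. ROC curves sweep the vote
fraction; AUC is the trapezoidal area and equals the Mann–Whitney
concordance, which the tests verify exhaustively at small n. An RBF-SVM
baseline (`svm_cv()`, LIBSVM via e1071, `cost = 0.6`, `gamma = 0.02`) runs
under the identical protocol for comparison; its ROC scores are decision
values.

A useful internal consistency check, which the acceptance script computes:
feeding the curated dataset compositions together with a cross-validated mean
sensitivity and precision through the metric formulas pins down the remaining
metrics. At 1441:15938 with sensitivity 74.46% and precision 100%, accuracy
must be 97.88%, specificity 100% and MCC 85.31%; at 710:5511 with 77.03% and
99.62%, accuracy 97.34%, specificity 99.96% and MCC 86.31%. The package's
metric code reproduces these to well under 0.1 percentage points.

## Dataset curation rules

`build_dataset()` encodes the construction of the curated sets as testable
predicates. Sequences outside 50–5000 residues are removed (the length filter
is the only operational fragment criterion). A length-passing protein is a
positive when any of: (a) ≥1 small-scale self-interaction experiment, or
large-scale experiments of ≥2 *distinct* types — "two sorts" is read as two
types, not two runs; (b) an annotated homo-oligomer state; (c) more than two
publications. The criteria are OR-combined, following the "one of the
following conditions" phrasing. Negatives are proteins with *no*
self-interaction annotation of any kind — a protein with one weak large-scale
evidence is excluded from both classes. Every length-passing record lands in
exactly one of positive / negative / excluded, which the tests assert on a
synthetic annotation panel.

## The synthetic data generator

Real inputs require UniProt curation and PSI-BLAST profiles, so the package
ships a generator (`generate_dataset()`) that emulates the *shape* of the
problem: variable-length proteins (uniform in a configurable range inside
[50, 5000]), class imbalance at the curated compositions
(`imbalance_preset("human_like")` ≈ 1:11.06, `"yeast_like"` ≈ 1:7.76), and a
class contrast expressed the way a profile would express it — the positive
class shifts the propensity of 5 fixed signal residues (A, C, H, S, V) by
`effect_size` before renormalisation, and each position's score row is the
class propensity plus Gaussian noise, scaled by `score_scale = 10` onto the
integer log-odds magnitude of real PSSMs. The scaling is a pure overall
factor — neighbour order and PCA structure are invariant to it — but it keeps
the integer-rounded fixture files informative. Fixture files round scores to
integers for PSI-BLAST dialect fidelity; tests compare post-rounding.

What the generator does *not* emulate: evolutionary correlation along the
sequence, alignment-depth effects, residue-composition differences between
real SIPs and non-SIPs beyond the single propensity shift, and any
relationship between the sequence letters and the score rows. Passing the
synthetic end-to-end checks therefore shows that the pipeline recovers a
planted class contrast under realistic imbalance and length variation — not
that it attains any particular accuracy on real proteomes.

Two study conditions bracket the pipeline's behaviour and are asserted in the
acceptance tests at fixed seeds:

* **null** — `effect_size = 0` at the human-like 20:220 composition: the
  classes are exchangeable, and 5-fold CV accuracy must land within ±0.05 of
  the majority-class fraction (0.9167). This guards against both optimistic
  leakage (accuracy ≫ majority) and a broken threshold (accuracy ≪ majority).
* **strong signal** — `effect_size = 0.5` (five times the noise standard
  deviation) with 60+60 samples: CV accuracy must reach at least 0.95.

These sizes (240 and 120 proteins, lengths 50–200) are the package's chosen
desk-scale operating point: large enough for stable 5-fold stratification,
small enough that the whole suite runs in well under a minute per condition.

## Numerical and degenerate-input choices

* Convolution is computed directly (exact for short tap vectors), zero-padded,
  same-length, centre-aligned; an `H = 1` sequence passes through unchanged
  up to the centre tap.
* `integral_square_error()` uses trapezoidal quadrature on a 4096-point grid
  over [−π, π] with the designed response zero-phase aligned, so it measures
  magnitude error only.
* PCA eigenvalues are clipped at zero and rank is decided at a relative
  `1e-10` threshold; requests beyond the rank truncate with a message.
* `q` is capped at one less than the post-PCA dimension inside `run_cv()`,
  so small runs degrade gracefully instead of erroring.
* Unknown residues (X, B, Z) in parsed PSSMs are kept verbatim, scores
  included; nothing is imputed.

## Known limitations

* The package parses PSI-BLAST output but does not run the search; feature
  quality on real data inherits whatever database and parameters produced
  the profiles.
* The voting threshold equals the training prior; no calibration beyond that
  is attempted, and the "prior-corrected per-block vote" reading of the
  threshold is deliberately not implemented.
* `svm_cv()` uses the fixed published hyperparameters; it does not re-run the
  grid search that produced them.
* Comparison methods beyond the SVM baseline (SLIPPER, DXECPPI, PPIevo,
  LocFuse, CRS, SPAR) are out of scope; the consistency check above is the
  only contact point with their published numbers.
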