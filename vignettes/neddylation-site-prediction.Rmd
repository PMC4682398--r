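---
title: "Predicting neddylation sites from sequence-derived features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting neddylation sites from sequence-derived features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neddly)
```

## The problem

Neddylation is the covalent attachment of the ubiquitin-like modifier NEDD8
to a substrate lysine. Experimentally mapped neddylation sites are scarce —
on the order of fifty curated sites across a few dozen proteins — and no
sequence motif generalizes across substrates, so predicting which lysines
can be neddylated is a severely imbalanced classification problem (roughly
one positive per twenty candidate lysines) that must lean on more than the
raw sequence. `neddly` implements an end-to-end pipeline for this problem:
lysine-centred window featurization from sequence and from
sequence-derived structural predictors, minimum-redundancy maximum-relevance
(mRMR) feature ordering with incremental feature selection, and a
class-weighted radial-kernel support vector machine with decision-value
confidence thresholds. A deterministic synthetic-benchmark generator makes
the whole pipeline testable offline, without the external predictors.

## The classification unit: lysine-centred windows

Every lysine in every protein is a candidate site, represented by the
window of `2n + 1` residues centred on it (default flank `n = 10`, window
21 — the size that maximized cross-validated AUC in a sweep from 5 to 27;
`window_size_sweep()` reproduces the procedure). Positions beyond the
protein ends hold the gap sentinel `-`. Annotated sites are positive;
every other lysine is assumed negative, an assumption that necessarily
mislabels any yet-undiscovered site.

Before windows are extracted, redundant proteins are removed with a greedy
clustering (`greedy_identity_cluster()`): sequences are sorted
longest-first and each joins the first representative with global-alignment
identity above 40%, leaving no retained pair above the threshold. This has
the same exclusion property as CD-HIT at a 0.4 threshold; the alignment is
a standard Needleman–Wunsch global alignment (match 1, mismatch 0, gap −1)
and identity is matched columns over all alignment columns.

Windows are partitioned per class into train : holdout at 2:1 and the
holdout into validation : test at 1:2. Shares are rounded half-up on the
train and validation fractions with the remainder flowing to the later
set; applied to 51 positives and 1031 negatives this yields exactly
34/687 train, 6/115 validation and 11/229 test windows. The rounding rule
is a package choice — only the resulting counts are canonical.

## Feature construction

`assemble_features()` emits, in a fixed documented order (1150 features at
`n = 10`, names in `feature_names()`):

* **Positional one-hot** (20 per position) and **reduced-alphabet**
  (11 groups per position) indicators. The grouping pools residues with
  shared biochemistry ({IVLM}, {FYW}, {RKH}, {DE}, {QN}, {ST}, A, G, C, P,
  catch-all); it is a plain configurable table, so an alternative grouping
  can be substituted without code changes. Gap positions are all-zero;
  unknown residues (`X`) contribute nothing to the 20-letter families and
  fall into the catch-all group.
* **Composition**: per-window occurrence counts and window-to-protein
  frequency ratios, for residues and groups (a ratio is 0 when the residue
  is absent from the protein).
* **Evolutionary conservation**: the 20 PSSM log-odds per window position,
  parsed from PSI-BLAST ASCII matrices. Raw log-odds are used without
  rescaling — the SVM's kernel width absorbs the scale.
* **Secondary structure**: one-hot state of the central lysine from
  PSIPRED `.ss2`, plus a flag marking residues within
  `ceiling(0.15 * element_length)` of either end of their secondary
  structure element ("element termini"); the ceiling makes single-residue
  elements all-terminus.
* **Solvent accessibility**: the central lysine's binary exposed/buried
  call (WESA-style).
* **Flexibility** (FlexPred-style calls and confidences): a majority-vote
  window flexibility flag (ties count rigid) and the confidence-ratio
  feature `conf_rat` — 1 when the summed confidence of flexible residues is
  at least the rigid sum (an exact tie satisfies the ratio; a zero rigid
  sum counts as 1 whenever any flexible residue exists).
* **Disorder** (IUPred tendencies): the window mean and a binary call with
  an inclusive 0.5 cutoff.
* **Hydropathy**: Hopp–Woods means over the window and the pre-/post-lysine
  sub-windows (an all-gap sub-window contributes 0).
* **Volumes**: Kharakoz residue-volume sums per sub-window and their
  difference (pre minus post).
* **Termini**: whether the central lysine lies within the first or last
  `ceiling(0.10 * L)` residues (boundary included), plus a signed length
  feature (−L at the termini, +L otherwise — the signs are a package
  convention chosen so the two states remain distinguishable at any L).

Missing predictor tracks zero-fill their families with a warning by
default (`missing_profiles = "error"` hard-fails), so sequence-only
prediction degrades gracefully rather than silently changing meaning.

## Feature selection

Continuous features are discretized to {−1, 0, +1} at one standard
deviation around the mean (`t = 1`); binary features pass through, and
zero-variance features code to 0. mRMR ordering uses the
mutual-information difference (MID) criterion: the first feature maximizes
MI with the label; each next feature maximizes relevance minus mean MI
with the already-selected set. MI is the plug-in estimate in bits; ties
break lexicographically on feature names so the ordering is deterministic
and invariant to row order. Ordering stops at 50 features, a cap suited to
a dataset of ~50 positives.

Incremental feature selection then evaluates growing prefixes of the
ordered list by mean repeated stratified-CV AUC, re-tuning cost and gamma
on a reduced grid per prefix, and keeps the prefix with the maximum mean
AUC (ties resolve to fewer features).

## Model and evaluation

The classifier is a radial-kernel SVM (libsvm via `e1071`) with per-class
weights {negative: 1, positive: `w`} — the libsvm `C*weight` scheme that
counters the ~1:20 imbalance; `w = 15` is the default, the point where AUC
plateaus on this data shape, with the 1, 5, 10, 15, 20, 25, 30 sweep
available through `weight_candidates`. The full grids are cost 2^−5..2^15
and gamma 2^−15..2^3 in doubling steps (21 × 19 combinations); features
are deliberately not rescaled before the kernel, matching the wrapped
libsvm defaults, so the gamma grid spans the resulting scale range. Grid
ties on CV AUC break on validation-set sensitivity, then specificity —
sensitivity first because the positive class is tiny.

Predictions are thresholded on the SVM decision value at two confidence
levels: medium (0, the separating hyperplane) and high (1); high-confidence
positives are always a subset of medium ones.

Evaluation (`evaluate_strategies()`) reports accuracy, specificity,
sensitivity, MCC (at the medium threshold) and rank-based AUC — the
normalized Mann–Whitney statistic, identical to the trapezoidal area for
finite score sets and deterministic under ties — under self-consistency,
repeated stratified 5-/10-fold CV, and the validation and test partitions.
Stratified folds shuffle and split each class separately, so within-class
fold sizes never differ by more than one.

One evaluation choice deserves emphasis: **feature selection is re-run
inside every CV training fold** (the mRMR ordering is recomputed on the
fold's training part only; the prefix length and SVM configuration are the
single scalars chosen up front). Selecting features on the full training
set and then cross-validating the same rows inflates AUC through selection
bias — on a zero-signal benchmark the inflated estimate can sit far above
chance, while the nested estimator stays near 0.5. The package's CV
numbers are therefore slightly conservative rather than optimistic.

## Site-characterization statistics

`position_enrichment()` tests, for every window offset and residue, the
2×2 presence table (class × residue-present) with the chi-square test of
independence, Bonferroni-corrected over all tests performed. Presence means
"window has this residue at this offset", not a count. Continuity
correction is off by default (a flag turns it on), consistent with
treating the test as the large-sample approximation. Continuous features
use the two-sided Mann–Whitney U test (normal approximation with tie
correction). Degenerate tables — a residue present in every window of both
classes, or absent margins — are reported as statistic 0, p = 1 rather
than NaN. Motif baselines (`evaluate_motif()`) score PROSITE-style
lysine-anchored degenerate patterns as classifiers, which is how the known
cullin consensus motif and discovered motifs are compared against the SVM.

## The synthetic benchmark: what it does and does not show

`generate_benchmark()` emulates the curated dataset's *shape*: 25 proteins
of 600–1100 residues with uniform composition (so ~1080 lysines), 51
positive sites, and class signal planted in the feature families that
dominate the real selected-feature list — motif residues M at −1, R at −3,
V at −4, I at −5, A at −7 and an I/V/L/M residue at +8 (each with
probability 0.8), an elevated K log-odds at PSSM offset −7, acidic (D/E)
depletion in positive flanks, disorder (80% of positives vs 9% of
negatives), flexibility (39% vs 12%) and termini placement (57% of
positives vs the ~20% expected by chance; the negative-class disorder,
flexibility and termini rates are those observed in the real data).
`signal = 0` collapses every class-dependent rate to background, giving a
null benchmark. All five predictor files quantize values to their format
precision, so write→parse round-trips are exact.

What the generator does **not** emulate: residue autocorrelation and real
composition biases, evolutionary structure in PSSMs (columns are i.i.d.
noise plus the planted cell), physically coherent disorder/flexibility
tracks, or correlations between tracks. Passing the recovery checks
therefore demonstrates that the pipeline's machinery — featurization,
selection, weighting, evaluation — is correct and leak-free at the study's
scale and imbalance; it does not certify real-data performance, which
additionally depends on the external predictors and on biology the
generator does not model. The published headline numbers (CV AUC ≈ 0.95 on
the curated data) require the original UniProt sequences and live
PSI-BLAST/PSIPRED/IUPred/FlexPred/WESA runs, which is why the package's
checks are recovery properties on the synthetic benchmark instead.

## Problem sizes and numerical choices

Desk-scale defaults keep a full pipeline run in minutes while preserving
the study's structure: incremental selection evaluates prefixes 1–15 then
20, 25, …, 50 with 3-repeat 5-fold CV over a reduced grid (cost
2^{0,5,10} × gamma 2^{−7,−3}); the final grid search spans cost 2^−5..2^15
in 2^5 steps and gamma 2^−15..2^3 in 2^3 steps at weight 15 with 3
repeats; reported CV uses 10 repeats. The full 100-repeat protocol and
complete grids remain available through the function arguments. Other
numerical conventions: window-flexibility majority ties count rigid;
`conf_rat` treats a zero rigid-confidence sum as 1 when any flexible
residue exists; empty sub-windows contribute 0; MCC with a zero
denominator is 0; AUC ties contribute one half; greedy-selection and IFS
ties resolve deterministically (lexicographic / fewer features). All
randomness flows from explicit integer seeds — same seed, same bytes.

## Known limitations

* The Sezerman-style grouping ships as a best-effort 11-group default; the
  exact published table can be substituted via the `grouping` argument.
* The greedy clustering reproduces CD-HIT's exclusion property, not its
  word-filter heuristics; representatives can differ from CD-HIT's on
  borderline pairs.
* The signed termini feature's sign convention is a package choice; the
  two states are what matters to the classifier.
* With ~50 positives, validation-set tie-breaking rests on 6 windows;
  grid-search ties are therefore common and the documented deterministic
  fallback (earliest grid entry) matters for reproducibility.
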