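---
title: "Diversity-optimized pathway ensembles: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity-optimized pathway ensembles: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathvote)
```

## The problem and the model

Two-class classification of expression profiles (e.g. pathologic complete
response versus residual disease after chemotherapy) is a
high-dimension/low-sample-size problem: tens of thousands of genes, a few
hundred patients. pathvote addresses it by using curated pathways as the
unit of feature selection. Each pathway, restricted to its differentially
expressed member genes, becomes the feature set of one support vector
machine; the classifier is an ensemble of such pathway-restricted SVMs
combined by majority vote, with the members chosen by a two-stage
diversity-driven selection.

The pipeline, end to end:

1. **DE screening.** A per-gene two-group moderated t-test (empirical-Bayes
   variance shrinkage across genes) on the full, unbalanced training set;
   genes with raw p < `alpha` (default 0.05) form the DE list. No
   multiple-testing correction by default: the screen is a feature filter,
   not an inference, and the nominal cutoff is the standard convention for
   this use. Benjamini–Hochberg adjustment and a plain Welch t-test are
   available as options.
2. **DE pathways.** Each pathway is intersected with the DE list (exact,
   case-sensitive gene-ID match); pathways whose intersection is empty are
   dropped. The intersections are the base learners' feature sets.
3. **Base learners.** One SVM per DE pathway, with libsvm defaults (RBF
   kernel, cost 1, gamma = 1/p); features are standardized with training
   statistics. Each learner is scored by repeated balanced cross-validation
   (below) and the top `top_n` (default 35) by mean accuracy form the pool
   S.
4. **Diversity.** For each pair of learners, the disagreement measure

   D(i, k) = (N01 + N10) / (N11 + N10 + N01 + N00),

   the fraction of samples on which exactly one of the two is correct —
   the normalized Hamming distance between their 0/1 correctness vectors.
   Pairwise disagreements are computed on every resampling run and averaged,
   giving a symmetric matrix D with zero diagonal. Each learner's overall
   diversity is the double sum OD[i] = sum_j (D[i,j] + D[j,i]) = 2 × row
   sum.
5. **Preliminary optimization.** The pool is reordered by OD, descending
   (S*). Prefixes of S* of growing size are each scored by the
   cross-validated majority vote; m is the smallest prefix size achieving
   the maximum, and S' = S*[1:m].
6. **Second optimization (pruning).** While some not-yet-examined surviving
   pair has D below the threshold `theta` (default 0.15), the
   lowest-diversity such pair is examined: the four candidates — keep both
   (S1), drop one (S2), drop the other (S3), drop both (S4) — are scored
   under identical resampling streams, the most accurate wins, and ties
   (within 1e-6) resolve by the priority S4 > S3 > S2 > S1, i.e. prefer
   removing redundancy. Each pair is examined at most once and the ensemble
   never shrinks below one member. The survivors S'' are the final
   ensemble.
7. **Vote.** Members are retrained once on a seeded balanced subsample of
   the training set; predictions are majority votes, which are correct
   exactly when at least floor(T/2 + 1) of the T members are correct. For
   even T with an exact split, the vote of the member with the highest CV
   accuracy decides — a deterministic, seed-free rule (a fixed-label
   fallback would bias the positive class).

## The resampling protocol

Class imbalance is handled by undersampling, never by reweighting: a
balanced subsample is all samples of the minority class plus an equal-size
uniform draw from the majority class (e.g. 50 + 50 out of 50 vs 195). One
"run" is one balanced subsample split into `n_folds` (default 5) stratified
folds, with each fold held out once; the run's accuracy pools the held-out
predictions, and reported accuracies are means over `n_runs` (default 100)
runs.

Two readings of this protocol were possible; the package resolves them as
follows, and applies the same resolution everywhere:

- **Shared streams.** All learners (and all candidate ensembles during
  selection) see the *same* per-run subsample and fold partition, derived
  deterministically from the master seed and the run index. This is what
  makes the per-run pairwise disagreement well defined — both learners'
  correctness refers to the same held-out samples — and what lets the
  selection compare candidates without resampling noise between them. A
  consequence worth exploiting: the per-learner out-of-fold predictions can
  be computed once per run and cached, so the prefix sweep and the pruning
  candidates only recompute the vote. Tests assert the cached path equals
  naive re-evaluation exactly.
- **Correctness vectors.** A learner's correctness entry for sample j is 1
  when the sample was classified correctly in a strict majority of the runs
  that held it out, 0 otherwise (including samples never held out, which
  can occur for majority-class samples at small `n_runs`). This
  out-of-fold definition avoids resubstitution optimism; a single-fit
  resubstitution mode would systematically overstate agreement between
  accurate learners.
- **Test-set evaluation.** For a fixed fitted model, cross-validation on
  the test set is not meaningful; each evaluation run is instead a balanced
  random subsample of the test set scored by the unchanged model, which
  reproduces the per-run mean ± SD reporting structure. The model is never
  refit on test data.

Seeds: one master seed (the protocol's `seed`) spawns every stage seed
through a fixed integer derivation (a Lehmer-style hash of seed, stage and
run index, kept below 2^31), so identical seeds give byte-identical
selection traces and any stage can be re-run in isolation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | raw p-value cutoff of the DE screen |
| `top_n` | 35 | size of the accuracy-ranked learner pool S |
| `theta` | 0.15 | disagreement threshold below which a pair is examined for pruning (unitless, in [0,1]) |
| `n_runs` | 100 | balanced-resample runs per accuracy estimate |
| `n_folds` | 5 | folds per run |
| `kernel` | radial | SVM kernel (cost 1, gamma = 1/p in either case) |
| `min_prefix` | 1 | smallest prefix size scored in the preliminary optimization |

The defaults are the protocol's canonical values; `min_prefix = 3`
reproduces the common practice of starting the size sweep at three voters
(a one- or two-member "ensemble" is degenerate, though scoring it is
harmless, which is why the default starts at 1).

## The synthetic-data generator

`simulate_expression()` emulates the one data regime the method needs:
a two-class, genes-by-samples Gaussian matrix in which a chosen subset of
pathways carries a mean-shift class signal.

- Background genes are i.i.d. Normal(0, `noise_sd`²) on an additive
  (log-like) scale — the scale on which normalized microarray and log RNA-seq
  intensities live; no count model is attempted.
- Within a pathway, member genes share one latent factor with loading
  sqrt(`rho`), giving an equicorrelated block (pairwise correlation `rho`,
  default 0.3 — the magnitude typical of co-regulated transcriptional
  modules). A gene claimed by several pathways keeps the factor of the
  first; overlap is otherwise unrestricted, mirroring curated collections
  such as KEGG where genes belong to many pathways.
- Genes of the `n_informative_pathways` informative pathways gain
  `delta` × `noise_sd` in positive-class samples. Default `delta` = 1, a
  moderate single-gene effect that only becomes easy at the pathway level.
- Default cohort shape: 2000 genes, 50 pathways of 10–40 genes, 5
  informative, 50 positive vs 195 negative samples — the roughly 1:4
  imbalance of a neoadjuvant-chemotherapy response cohort, at a gene count
  scaled to desk size.

What the generator does **not** emulate: heavy-tailed and heteroskedastic
microarray noise, batch effects, probe-level artifacts, correlated
informative and background blocks beyond single-factor structure, and any
relationship between pathway membership and gene-gene regulation direction.
Tests passing on this generator therefore demonstrate the machinery
(screening, ranking, diversity algebra, selection, voting) and its
statistical calibration under clean Gaussian conditions — not performance
on real cohorts.

## Numerical choices

- **Standardization.** Feature standardization uses training-fold
  statistics only; constant features are centred and left unscaled rather
  than dropped, so feature sets keep their declared size.
- **Zero-variance genes** in the DE screen get p = 1 (never flagged) rather
  than an error.
- **Degenerate folds.** Stratified fold assignment is re-drawn (up to 100
  attempts) if any fold lacks a class; this can only persist when a class
  has fewer samples than folds, which is then a hard error.
- **Ties.** Learner ranking breaks accuracy ties by pathway ID
  (ascending); the OD reorder is a stable sort so OD ties keep accuracy
  order; m is the *smallest* prefix achieving the maximum (parsimony);
  pruning examines the lowest-D pair first with lexicographic pair-ID
  tie-break; accuracy "equality" in the S4>S3>S2>S1 rule means within 1e-6,
  which under shared seed streams is exact equality of identical ensembles.
- **Undefined metrics** (zero denominators) are reported as NA and excluded
  from across-run means instead of being coerced to 0, which would bias
  small balanced subsamples.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen so the full suite completes
in minutes while leaving each property statistically identifiable: null
calibration uses 200 datasets of 1000 genes (40 samples each); selection
oracle-equivalence uses pools of ≤ 5 learners with 5-run protocols, where
exhaustive search over all prefixes and all four pruning candidates is
feasible; the recovery study uses twenty replicates of a 2000-gene,
50-pathway, 60 vs 60 cohort with `delta` = 2 and 10-run protocols; the
reproducibility check runs the full pipeline twice at 500 genes. The
acceptance script runs the full default cohort (2000 genes, 100 vs 390
samples split in half) under the full 100 × 5 protocol.

## A structural property worth knowing

The disagreement of two learners is bounded below by the difference of
their accuracies and is near zero for mutually consistent accurate
learners. Under strong signal, the most accurate learners agree on almost
every sample, so they receive the *lowest* overall diversity and are placed
at the tail of S*. The prefix search then typically reaches its accuracy
maximum using earlier, noisier (or partially informative) learners, and the
signal-bearing pathways may never enter S' at all; when they do, their
mutual disagreement is below `theta` and the S4-first tie rule removes them
whenever the vote's accuracy is unchanged. In short: the selection
optimizes vote accuracy, and under strong, concentrated signal it does so
*without* the ground-truth pathways, recruiting instead diverse learners
that each carry partial signal (e.g. through pathway overlap). The
twenty-replicate recovery study in the test suite documents this: the
informative pathways reliably top the accuracy ranking, while the final
pruned ensemble is typically drawn from the diverse remainder. Users who
want the method for pathway *identification* rather than classification
should read the accuracy ranking (`rank_learners()`), not the final member
list.

## Known limitations

- Two classes only; no multi-class or survival extension.
- Majority vote is unweighted; no soft voting or stacking.
- The DE screen assumes roughly Gaussian, variance-stabilized expression;
  count data should be transformed (e.g. log-CPM) first.
- Probe-to-gene collapsing is out of scope: the expression matrix is
  assumed to have one row per gene.
- With `top_n` = 35 and 100 × 5 protocols the fit is compute-bound
  (thousands of small SVM fits); the shared-stream cache keeps the
  selection stages cheap, but the base-learner pass scales linearly in
  pathways × runs × folds.
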