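---
title: "Structural pathogenicity scoring: model, evaluation protocol and design notes"
author: "mova"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural pathogenicity scoring: model, evaluation protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mova)
```

## The problem and the model

Missense variants in disease genes are often pathogenic *because of where
they fall on the folded protein*: in several ALS genes (TDP-43, FUS, ...)
pathogenic substitutions cluster in compact 3D regions — hotspots — while
benign population variants scatter over the whole chain. Sequence-
conservation scores do not see this geometry. This package scores variants
per gene with a random forest trained on five features of the substituted
residue, all derived from the AlphaFold2-predicted structure of the
wild-type protein plus a substitution matrix:

* `x`, `y`, `z` — the arithmetic mean of the residue's atomic coordinates
  (Angstrom) in the AlphaFold model frame. These carry the positional
  (hotspot) signal.
* `plddt` — AlphaFold's per-residue confidence (0–100), read from the PDB
  B-factor column and averaged over the residue's atoms. Low pLDDT marks
  intrinsically disordered regions, which for some genes coincide with the
  pathogenic region.
* `delta_blosum62` — `S(ref, ref) − S(ref, alt)` under the standard NCBI
  BLOSUM62 half-bit matrix: 0 for a synonymous "substitution", larger for
  more evolutionarily disfavoured changes. The matrix is embedded as an
  integer constant and verified exhaustively against an independent copy in
  the test suite.

Coordinates are used raw, in the per-structure AlphaFold frame — no
centering or rotation. A model is therefore only meaningful for the
structure file it was trained against, which is the intended per-gene usage:
the frame is fixed per file, and the forest only ever compares coordinates
within that frame.

Training labels are `positive` (pathogenic, e.g. disease-mutation database
entries) and `negative` (population variants). The package consumes these as
a plain TSV; curation of real databases is out of scope.

## Classifier and its pinned defaults

`mova_config()` freezes what "default random forest settings" means so runs
are reproducible: 500 trees, `floor(sqrt(p))` candidate features per split
(2 for the 5-feature model), unlimited depth, no class weights. The score of
a variant is the fraction of trees voting for the positive class. One
degenerate case is handled explicitly: if every feature column is constant
on a training set, no split exists anywhere and the classifier returns the
training class ratio — the exact limit of a forest of root-only trees (the
underlying library does not terminate on such input).

The fitting backend is pluggable (`mova_config(backend = function(x, y01,
seed) ...)`), which the test suite uses to substitute deterministic stub
models; only the random forest backend is provided.

## Evaluation protocol

`mova_cv()` runs stratified 5-fold cross-validation repeated 5 times
(25 folds). Stratification assigns each class cyclically over folds, the
minority class going to the least-loaded folds first, so per-fold class
counts and per-fold sizes each differ by at most 1. Per fold, the model is
trained on the other four folds and scores the held-out fold; the package
reports:

* per-fold AUCs and their arithmetic mean (the cvAUC convention). AUC is
  computed as the Mann–Whitney rank statistic with ties counted 1/2, which
  the tests check against brute-force pair counting and an independent ROC
  implementation;
* a mean ROC curve by vertical averaging of the 25 fold curves on a shared
  101-point false-positive-rate grid (linear interpolation);
* each variant's mean held-out prediction across repeats — the "5F-MV"
  value (every variant is held out exactly once per repeat);
* a decision cutoff: the mean over all 25 folds of the Youden-optimal
  threshold. The Youden scan uses the observed scores as candidates, the
  rule `score >= t`, and breaks ties toward the smallest threshold;
  internally J is maximised in the exact integer form
  `TP·n_neg + TN·n_pos`, so float noise cannot break ties inconsistently.

Cross-validation requires at least `k` members of each class. The fold
*assigner* itself is more permissive (it only needs `2 ≤ k ≤ n`), because a
fold pattern like positives `{1,1,1,1,0}` for 4 positives is well defined
even though AUC would then be undefined on one fold; the CV drivers enforce
the stricter precondition.

Seeding is deterministic throughout: repeat `r` draws folds from
`seed + r − 1`, and the fold model of repeat `r`, fold `f` is fitted with
`seed + 1000 + (r−1)·k + (f−1)`. Two runs with one seed are bit-identical.

## Final ensemble scores

`mova_score_table()` fits 30 forests on the full labeled dataset with seeds
`seed..seed+29` and averages their predicted probabilities for *every*
possible substitution of the protein — length × 20 rows, including the
reference-identical rows, which are forced to 0. Averaging 30 runs shrinks
the run-to-run dispersion of the scores (on the reference simulation the
mean per-row standard deviation across replicate tables falls to about a
fifth of the single-run value, close to the 1/sqrt(30) expectation).

## The distance baseline

A deliberately simple comparator: score a variant by the (negated) minimum
Euclidean distance between its residue's mean coordinates and the residues
of the *training-split* pathogenic variants. Inside cross-validation the
pathogenic reference set is rebuilt per fold from training positives only;
the tests include injection checks proving held-out labels and coordinates
cannot reach it. `distance_as_feature_cv()` also adds this distance as a
sixth model feature, where training-side positives use leave-self-out
distances — otherwise the feature would be identically zero on the class
that defines it, a degeneracy the protocol description leaves open; at
least two training positives are therefore required.

## Fusion with external scores

`combine_cv()` fuses the forest with a precomputed score column (REVEL,
CADD, ...) by logistic regression, per CV fold: the forest is fitted on the
training split; the logistic model `label ~ prob + external` is fitted on
the training split using the forest's *out-of-bag* probabilities (training
inputs must not be optimistic resubstitution probabilities, and the
protocol does not specify this step — out-of-bag is the natural leak-free
choice inside a fold); the held-out fold is scored through the fitted
logistic model. The fit is plain maximum-likelihood `glm(family =
binomial)`; when the fold is (quasi-)separable the fit is replaced by a
ridge-stabilised logistic regression (`glmnet`, alpha 0, lambda 1e-3,
standardised), and a message says so. Records missing the external column
are dropped with a logged count, never imputed. Fold coefficients are
returned for inspection.

## The synthetic study

Because the real positive/negative curation sits behind licensed databases,
the package ships a generator that emulates the study conditions
end-to-end and makes every stage testable offline:

* **Structure**: a self-avoiding chain with fixed 3.8 Å steps (the
  Cα–Cα distance), excluded-volume radius 3.5 Å, confined to a sphere of
  radius `step·sqrt(length)` for compactness, one pseudo-Cα per residue,
  written as a single-chain PDB with pLDDT in the B-factor field. Defaults:
  400 residues; pLDDT 90 in the core and 40 in the last 10% of the chain (a
  disordered tail, so tests can probe whether pLDDT carries signal when
  positives are placed there).
* **Variants**: 50 positives, 90% of them at residues within 12 Å of the
  hotspot centre (residue `round(0.8·length)`, a C-terminal-ish location
  like the real hotspots), the rest uniform; 150 negatives uniform.
  Alternate residues are drawn uniformly and label-independently, so the
  substitution penalty is noise *by construction* — the ablation tests rely
  on this.
* **External score**: `informativeness · label + (1 − informativeness) ·
  U(0,1)`, default informativeness 0.5. Note a structural consequence of
  this definition: for informativeness ≥ 0.5 the column separates the
  classes perfectly (positives ≥ 0.5, negatives ≤ 0.5), so at the default
  the external score alone has AUC 1 and the fusion benchmark effectively
  demands the combined model not destroy a perfect predictor.

What the generator does *not* emulate: real backbone geometry and secondary
structure, residue-composition bias, multi-atom side chains, correlated
pLDDT profiles, or label noise. Passing the synthetic benchmarks therefore
demonstrates that the pipeline recovers positional clustering signal and is
leak-free and calibrated under the null — not that any particular real gene
will reach a given AUC.

## Problem sizes and runtime choices

The reference evaluation (tests and the acceptance script) uses the default
400-residue / 200-variant simulation, 5×5-fold CV with 500-tree forests,
averaged over 5 simulation seeds; ensemble-contract checks use 3 replicate
30-run tables. Unit tests use a 120-residue / 85-variant simulation and
150-tree forests, sizes at which every property under test is already
stable.

## Known limitations

* Per-gene training needs enough pathogenic examples; with fewer than ~10
  positives the stratified folds become degenerate and CV is refused below
  `k` per class.
* The model is frame- and isoform-bound: features come from one AlphaFold
  file, and a reference-residue mismatch between the variant table and the
  structure is a hard error by design.
* Scores are relative, per gene; they are not calibrated probabilities and
  are not comparable across genes.
* Only single-residue missense substitutions are in scope — no indels,
  multi-residue changes, or nucleotide-level input.
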