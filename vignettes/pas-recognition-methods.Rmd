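---
title: "Recognizing poly(A) signals with an omnivariate decision tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing poly(A) signals with an omnivariate decision tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pastree)
```

## The problem

Polyadenylation of a pre-mRNA is directed by a poly(A) signal (PAS), a
hexamer — canonically `AATAAA` — located upstream of the cleavage site. The
same hexamers occur throughout the genome with no role in 3'-end formation
(*pseudo-PAS*), so recognizing a functional PAS from genomic DNA alone must
rely on the flanking sequence: the GU/U-rich downstream sequence element
(DSE), the U-rich upstream element (USE), and broader compositional biases.
`pastree` classifies 206-nt windows — 100 nt of upstream flank, the 6-nt
hexamer at window positions 100–105 (0-based), 100 nt of downstream flank —
as true PAS versus pseudo-PAS, separately for the 12 most common human
hexamer variants. `AATAAA` and `ATTAAA` form the *PAS-strong* category; the
ten rarer variants are *PAS-weak*.

## The feature encoding (218 values)

Every window is mapped to 218 named numeric features via a versioned
registry (`feature_registry()`, version `r pastree:::.REGISTRY_VERSION`):

* **Dinucleotide weight-matrix scores (2).** Two 16 × (L−1)
  position-specific dinucleotide probability matrices are fitted on the
  training data, one on true-PAS windows and one on pseudo-PAS windows
  (Laplace pseudocount 1). A window's score against a matrix is
  \(\sum_j \log_2\!\big(p_{r(j),j} / Pb_{r(j)}\big)\) over the dinucleotide
  observed at each start position, with uniform background
  \(Pb_i = 1/16\). As printed elsewhere, the score formula also sums the
  15 *unmatched* matrix rows per position; each contributes the constant
  \(\log_2(1/Pb_i)\), adding \(15 \cdot 4 \cdot (L-1)\) bits to both class
  scores equally and changing no decision. The default therefore sums
  matched rows only; `score_2mer(..., mode = "literal")` reproduces the
  printed constant-offset form.
* **Positional information gain (1).** For each non-hexamer position
  \(P\), nucleotide occurrences in the two classes give per-nucleotide
  entropies \(E(P,X)\) and a class-prior entropy \(E(P)\) through the same
  two-class entropy formula \(-\frac{c_1}{c_1+c_2}\log_2\frac{c_1}{c_1+c_2}
  -\frac{c_2}{c_1+c_2}\log_2\frac{c_2}{c_1+c_2}\). The default gain is the
  weighted (mutual-information) form \(\mathrm{Gain}(P) = E(P) - \sum_X w_X
  E(P,X)\) with \(w_X\) the fraction of training windows carrying \(X\) at
  \(P\); this follows the textbook definition the formula cites, is
  non-negative, and vanishes exactly when the class-conditional
  distributions coincide. The unweighted sum, which can go negative, is
  available as `mode = "literal"`. The per-window *gain score* is
  \(\sum_P \mathrm{Gain}(P)\, \log_2\!\big(f_{\mathrm{true}}(x_P,P) /
  f_{\mathrm{pseudo}}(x_P,P)\big)\) with pseudocount-smoothed per-position
  class frequencies — high for PAS-like windows, 0 for all windows when no
  position is informative. The hexamer positions are excluded throughout:
  they are identical in both classes by construction.
* **Top-position frequencies (8).** The 20 highest-gain upstream and 20
  highest-gain downstream positions are selected on training data (ties
  toward the smaller index); the frequencies of A, C, G, T within each
  20-position set give 4 + 4 features.
* **Structural-profile window averages (16 × 8 = 128).** Sixteen published
  di-/tri-nucleotide physicochemical conversions (A-philicity, protein–DNA
  twist, propeller twist, bendability, duplex stability free energy, DNA
  bending stiffness, Z-DNA stability, DNA denaturation, nucleosome
  positioning, base stacking, B-DNA twist, duplex disrupt energy, protein
  deformation, radical cleavage intensity, bending propensity, melting
  temperature) re-encode each 100-nt flank as a numeric profile. Each flank
  is divided into four 25-nt sub-sequences and the mean profile value per
  sub-sequence is one feature — granular enough to separate the DSE/USE
  bands from less relevant regions without carrying all ~199 per-position
  values per scale. Profiles are computed per flank so no value spans the
  hexamer or the flank junction.
* **Compositional features (79).** Mono- (8) and di-nucleotide (32)
  frequencies per flank; in-frame codon-position nucleotide frequencies
  with frames anchored at the hexamer edge (24); and 15 whole-window
  descriptors over the 200 flank nt (4 base frequencies, GC/AT content,
  GC/AT skew, mono- and di-nucleotide entropy, CpG observed/expected,
  purine fraction, longest A-, T- and any-base homopolymer runs).

All training-dependent components (matrices, gain profile, top positions,
normalization) are fitted **only** on the training rows of each fold.
Features are min–max normalized to (−1, 1) via
\(\mathrm{norm}_i = (x_i - (\max_i + \min_i)/2) / ((\max_i - \min_i)/2)\);
validation/test rows reuse the training parameters and may exceed the
range. Constant training features normalize to 0 with a warning.

### Structural-scale tables

The published conversion tables are not redistributable inside this
package, so the bundled file
(`inst/extdata/structural_scales.synthetic.tsv`) carries **synthetic
stand-in values** drawn once from realistic per-scale ranges; the file name
and header say so. All profile/window machinery treats the tables as data,
and the test suite checks the machinery against slicing oracles, so
swapping in literature tables via `load_structural_scales(path)` changes
numbers but not correctness.

## The classifier: an omnivariate tree searched by a GA

An *omnivariate* decision tree allows every internal node to be a full
classifier rather than a single-feature threshold. `pastree` grows a
complete binary skeleton of depth `max_depth` (default 3, i.e. 7 internal
slots); each slot holds one of four families with grid hyperparameters:

| family | implementation | grid |
|---|---|---|
| `univariate_tree` | entropy-split tree (Rcpp) with C4.5-style pessimistic pruning | confidence 0.1 / 0.25 / 0.5 |
| `neural_net` | single-hidden-layer network, L-BFGS, tanh/logistic | hidden 5 / 10 / 20 / 40 |
| `random_forest` | bagged entropy trees with per-split feature sampling (Rcpp) | trees 50–500, mtry sqrt / log2 / all |
| `multinomial_logistic` | ridge-penalized logistic (glmnet) | ridge 1e-4 / 1e-2 / 1 |

Routing is by predicted class: samples a node predicts as class 0 go left,
class 1 right, and each child's classifier is fitted on exactly the routed
subset. A slot becomes a leaf when the genome prunes it, its routed data is
pure, its size falls below `min_node_size` (default 30), or it sits at
`max_depth`; the leaf label is the routed majority (ties resolve toward the
parent majority, then the positive class) and the leaf score is the routed
true-PAS fraction. The routing rule and leaf-labeling are design choices —
the published description leaves them open — chosen as the simplest scheme
consistent with two-way branching on "the data reaching the node".

A genetic algorithm searches the joint space of pruning mask, per-slot
family and hyperparameter indices. The genome holds, per slot, a prune bit,
a 2-bit family index and two grid indices; decode/encode is an exact
bijection. Fitness is the validation-split error of the tree fitted on the
training split; selection is tournament (size 3), variation is uniform
crossover (0.9) and per-gene mutation (0.03), with elitism 1 — so the
best-so-far fitness is non-increasing. Defaults (population 40, 25
generations) are sized for minutes-scale per-variant runs; the original
operator settings are not published. Fitness ties prefer more-pruned
genomes, then earlier appearance, for reproducibility and an Occam bias
consistent with the pruning goal. Every fitness evaluation derives its RNG
stream from `(seed, genome)`, so parallel evaluation (`n_workers`) is
bit-identical to serial.

## Evaluation protocol

`make_cv_splits()` builds label-stratified 5-fold splits; within each fold
a stratified 15% of the training portion (floor per class — the published
protocol states 15% with no rounding rule) is held out as the validation
set driving the GA, and the test fold is touched exactly once. Per-variant
confusion counts are pooled over folds (micro-average); whether the
original work micro- or macro-averaged is not stated, and micro-averaging
is robust to unequal fold sizes. The headline metric is
`error rate = (FP + FN) / (TP + TN + FP + FN)`, with size-weighted averages
across variants.

For PAS-weak variants, `pool_weak_training()` expands a fold's training
data with **all** records of the other nine weak variants — following the
protocol's wording that pooling uses the nine remaining variants' data plus
the target's training portion. Test records come only from the target
variant, so no pooled record can leak into testing.

## The synthetic generator

`default_profiles()` + `generate_dataset()` emulate the qualitative
per-position nucleotide distributions of the three window classes: a mildly
A/T-rich position-independent background for pseudo-PAS (A/T 0.30, C/G
0.20); a strong-variant template with a T/GT-rich DSE band at window
positions 122–147 (k-mer offsets +16..+41 past the hexamer) and a T/C-rich
USE band at 76–100; and a weak-variant template with whole-flank downstream
A enrichment and block-wise variable upstream composition.
`signal_strength` in [0, 1] linearly interpolates the true class between
background (classes exchangeable) and template. Sampling is independent per
position — sufficient to exercise every feature family, though it does not
reproduce the dinucleotide dependence, cleavage-site heterogeneity or real
chromosome-21 background of genomic data. A green end-to-end test therefore
establishes that the pipeline recovers a planted positional signal, not
that it attains the published benchmark error rates (those require the
external benchmark data, which is out of scope here).

Band geometry is fixed and documented so that position-recovery assertions
have ground truth: at `signal_strength = 1` the fitted gain profile peaks
inside the DSE band and at least 15 of the top-20 downstream positions fall
within it.

## Numerical choices and edge cases

* Pseudocount 1 (Laplace) everywhere a probability is estimated from
  counts; `score_2mer` raises an error directing the user to smoothing if
  an observed dinucleotide has probability 0.
* `0·log 0 := 0` in every entropy; `positional_entropy(0, 0)` is an error.
* Windows containing `N` are rejected by default (`allow_n = TRUE` keeps
  them at extraction; features are defined over `{A,C,G,T}` only).
* Coordinates are 0-based half-open internally; GTF input (1-based
  inclusive) is converted on read. `hexamer_start` is the leftmost hexamer
  base on the reference strand for both strands; minus-strand windows are
  reverse-complemented so the hexamer reads in transcript orientation.
* Pseudo-PAS sampling scans both strands (functional PAS occur on both)
  and excludes true-PAS hexamers by coordinate overlap, not sequence
  identity.
* Nodes whose routed data leaves a class with fewer than two samples fall
  back to a constant majority classifier (several families cannot be
  fitted there).
* CV requires at least `k` records per class; constant features normalize
  to 0; an empty validation set is an error for the GA.

## Known limitations

* The exact 218-feature inventory of the original method is in unpublished
  supplementary material; the registry here reconstructs every named
  family with a documented composition summing to 218, and is versioned so
  models refuse mismatched feature sets.
* Structural-scale values are synthetic stand-ins (see above).
* The GA defaults and the tree's routing/labeling rules are this package's
  own choices where the publication is silent; they are recorded here
  rather than claimed as reproductions.
* Published benchmark error rates are not reproducible without the
  external datasets; the acceptance suite instead checks printed
  structural/arithmetic quantities and property-based recovery on
  synthetic data.
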