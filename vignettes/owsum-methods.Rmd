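---
title: "Weighted-sum structure–odor classification: model, conventions, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-sum structure–odor classification: model, conventions, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owsum)
```

## The problem

Odor prediction asks: given only a molecule's structure, which odor
descriptor (floral, fruity, sickening, ...) will a human panel assign to
it?  Panel datasets are multilabel — a molecule may smell like several
things at once — and small, so black-box learners are hard to interrogate.
OWSum takes the opposite route: a linear, fully inspectable classifier
whose every prediction decomposes into named substructure contributions.

Molecules are encoded as SMILES, features as SMARTS substructure
patterns, and only *presence* is recorded: the occurrence matrix is
binary by construction, so a molecule with five ester groups counts the
ester feature once.  This deliberately prevents small, frequently
repeated fragments from dominating the sums.

## The model

For feature $F_j$ and class $C_i$, the weight is the conditional
probability estimated by counting over the training set:

$$G_{j,i} = \Pr(F_j \mid C_i)
        = \frac{\#\{\text{molecules with } F_j \text{ and } C_i\}}
               {\#\{\text{molecules with } C_i\}}.$$

A multilabel molecule contributes to every class it carries.  The
influence of a feature on a class is the weight times a variant-specific
weighting factor $a_{i,j}$:

$$I_{i,j} = a_{i,j} \cdot G_{j,i}.$$

The package implements the four weighting variants:

| variant | $a_{i,j}$ | resulting $I_{i,j}$ |
|---|---|---|
| `same_weighted` | $1$ | $G$ |
| `tfidf_weighted` | $\mathrm{tfidf}_{i,j}$ | $G^2 \cdot \mathrm{idf}$ |
| `tfidf_over_prfc` | $\mathrm{tfidf}/G$ | $\mathrm{tfidf}$ |
| `tfidf_over_prfc_times_prcf` | $\mathrm{tfidf}\cdot\Pr(C_i\mid F_j)/G$ | $\mathrm{tfidf}\cdot\Pr(C_i \mid F_j)$ |

with

$$\mathrm{tfidf}_{i,j} = \frac{\#(F_j, C_i)}{\mathrm{len}(C_i)}
  \cdot \log\!\left(\frac{|C|}{\sum_{C_n : F_j \in C_n} 1}\right).$$

The term-frequency factor coincides with $G_{j,i}$ by definition (both
are the within-class occurrence fraction); the suite asserts this
identity on random instances.  The idf factor counts how many classes
contain the feature at least once: a feature present in every class gets
idf $= 0$, one confined to a single class gets $\log|C|$.

To classify molecule $O_k$, the influences of its present features are
summed per class,

$$S_{i,k} = \sum_{F_j \in O_k} I_{i,j},$$

and the argmax class set is predicted.  Two situations produce no
prediction (`status = "unpredictable"`): the molecule has no usable
feature, or its argmax spans *all* classes (a completely uninformative
tie).  A tie over a proper subset is returned as a multi-class
prediction.  Features never seen in training are excluded from the model
and contribute nothing at prediction time — the model cannot weigh
evidence it never observed.

**Feature selection.**  With `feature_selection = TRUE` (the default),
features with idf $= 0$ are dropped from scoring: they occur in every
class and cannot separate anything.  Under `tfidf_weighted` this is
provably a no-op for predictions (their influence is already zero), which
the suite also checks.

## Numerical choices

* **Log base.**  The idf logarithm's base is configurable
  (`log_base`, default $e$).  Changing base multiplies every tf-idf
  influence by the constant $1/\ln b$, so argmax sets — and therefore all
  predictions — are invariant; the suite verifies base $e$ vs base 10.
* **The $G = 0$ singularity.**  `tfidf_over_prfc` divides by $G$; where
  $G = 0$ the influence is defined as 0, the limit of
  $\mathrm{tfidf}\cdot(1/G)\cdot G$.  No defined value changes.
* **Ties.**  Score ties are detected with a relative tolerance of
  $10^{-9}$ against floating-point jitter in sums; tied classes are all
  returned.
* **Degenerate inputs.**  Empty classes abort training with the class
  named; molecules with all-zero feature rows flow through and come out
  unpredictable; features absent from the training rows are flagged
  untrained and dropped.

## Validation protocol

Two accuracies are reported as percentages: *overall* divides correct
predictions by all tested molecules, *predicted* by the predictable ones
only.  A prediction is correct when it is a subset of the true descriptor
set.  Unpredictable molecules are neither correct nor incorrect but stay
in the overall denominator, so overall $=$ predicted $\times$ coverage.

Because the classifier predicts a single argmax set while truth is
multilabel, one-vs-rest ROC AUC and MCC are computed under two
conventions for a molecule that carries the focus class plus others and
whose prediction hit one of the others: *underestimated* keeps
true $= 1$, pred $= 0$ (the hit is scored a miss — a lower bound);
*overestimated* reassigns the molecule to the rest class (true $= 0$,
pred $= 0$ — an upper bound).  Both use the hard 0/1 predictions as
scores; rank-based AUC then equals (sensitivity + specificity)/2, which
is why the underestimated class mean can never exceed the overestimated
one — both confusion-table fractions only improve under the relabeling.
When truth is constant for a class the AUC is undefined and excluded
from the class mean (logged, not imputed).  MCC uses the standard
confusion-table formula with one convention: truth and prediction both
all-zero scores 1 (a vacuously perfect rest assignment, arising only in
overestimated mode); any other zero-denominator table scores 0.

Cross-validation shuffles molecules under an explicit seed into `k`
near-equal unstratified folds (a stratified option exists behind a
flag), refits everything — counts, idf, selection mask — on each training
complement, and pools held-out predictions before computing per-class
metrics and class means (per-fold averaging sits behind `per_fold`).
The feature catalog is fixed across folds; a fold whose training split
lacks a class warns and simply cannot predict it.

## Descriptor overlap and panel preprocessing

Panel vocabularies are redundant: broad descriptors (e.g. "fragrant")
co-occur with nearly everything and make per-descriptor prediction
ill-posed.  The overlap of two descriptors is

$$\mathrm{overlap}(d_1, d_2) =
  \frac{\#M_{d_1 \cap d_2}}{\min(\#M_{d_1}, \#M_{d_2})} \in [0, 1],$$

1 when the rarer descriptor's molecules are contained in the other's,
0 when disjoint.  `preprocess_panel()` turns a molecules-by-descriptors
percent-applicability table into a multilabel dataset in five ordered
stages: threshold at `applicability_min` (inclusive, default 25%), keep
descriptors with at least `min_molecules` molecules (inclusive, default
10), drop descriptors whose mean overlap with the survivors exceeds
`mean_overlap_max` (strict, default 0.49), drop an explicit manual list
(the shipped recipe removes "heavy" and "light", labels known to be used
inconsistently across individuals), and finally drop unlabeled
molecules.  The mean-overlap screen is computed once on the
post-support-filter descriptor set; an iterative mode that rescreens
after each drop is available behind `iterative = TRUE`.  Inclusive
versus strict boundaries follow the literal wording of the filter
definitions.

## MCS feature catalogs

Feature catalogs are built by pairwise maximum common substructure over a
reference corpus.  No installed R package computes MCS, so the package
implements it directly: atoms compare at element level and bonds by
order; compatible atom pairs form the modular-product graph whose maximum
cliques (via igraph) are the maximal common mappings; the largest
connected component of the best mapping is emitted when it has at least
`min_atoms` atoms (default 2).  This is the maximum common *induced*
subgraph — adopted as the MCS definition here — and the test suite checks
its atom counts pair-by-pair against an independent Python/RDKit
`rdFMCS` oracle on the bundled corpus.

Emitted SMARTS writes atoms as `[#Z]` and bonds with their exact order
symbol, except ring bonds, which additionally allow the aromatic
alternative (`-,:`, `=,:`): structure blocks are kekulized on parsing, and
this keeps a pattern derived from a kekulized ring matching the same ring
under aromatic perception.  De-duplication is by exact string after the
deterministic emitter (SMARTS has no canonical writer in the toolkit);
the same corpus and parameters therefore always produce a byte-identical
catalog.  Each pair runs under a configurable `pair_timeout` (default
5 s) and times out with a warning, never fatally.  Corpus-scale pairwise
MCS over hundreds of thousands of purchasable compounds is out of scope
by construction: the operation accepts any corpus, ships a small bundled
one, and reads user-supplied precomputed catalogs from plain text.

## The synthetic generator

`simulate_molecules()` plants one diagnostic fragment per class — ester
for fruity, thioether for sickening, phenol for medicinal, aliphatic
C=C for floral, quaternary carbon for woody, carboxylic acid for
perfumery — and assembles each molecule as 1–3 shared decoy fragments
plus the class motif, yielding chemically valid SMILES whose motif is
provably detectable by its SMARTS and by no other class's.  Label noise
replaces the label (never the structure) with a random other class;
multilabel adds a second label.  Fragment order matters: motifs are
appended last and decoys never end in a heteroatom, so concatenation
cannot mutate a motif (e.g. esterify an acid).

What the generator emulates: class-diagnostic substructures diluted by
uninformative shared fragments, label noise, and multilabel assignment.
What it does not: realistic odorant chemistry, correlated motifs,
graded structure–activity strength, or panel measurement noise.  A
perfect cross-validated accuracy on clean synthetic data therefore
demonstrates correct recovery machinery, not real-world predictive
performance, which on panel data is bounded well below 100%.

Default study sizes — six classes of ten molecules, five folds — keep a
full cross-validated run in the order of seconds while leaving each
training split large enough that every class survives the shuffle in
practice.

## Worked toy example

The four-molecule fixture realizes the documented miniature worked
scheme with real chemistry: two esters labelled `A` (phenyl acetate,
ethyl acetate) and two sulfur compounds labelled `B` (thiophenol,
ethanethiol) against ester/benzene/sulfur SMARTS features.

```{r toy}
toy <- toy_fixture()
occ <- occurrence_table(toy$molecules, toy$catalog)
occ
fit <- owsum_fit(occ, label_table(toy$molecules), variant = "tfidf_weighted")
tidy(fit)
predict(fit, toy$molecules)
```

The benzene ring occurs in both classes (idf $= 0$, deselected); the
ester and sulfur features are class-unique (idf $= \ln 2$), giving the
influence $\ln 2 \approx 0.693$ that each molecule's score inherits.

## Known limitations

* Influences are reported unnormalized, exactly as the equations define
  them; magnitudes are only comparable within a fitted model.
* OpenBabel's SMARTS and aromaticity perception is the single matching
  authority; patterns relying on another toolkit's aromaticity model may
  match differently.
* The clique-based MCS is exact but exponential in the worst case; the
  per-pair timeout is the safety valve for pathological pairs, and very
  large corpora are expected to arrive as precomputed catalogs.
* No probability calibration or thresholded multilabel output: the
  classifier predicts argmax sets only, and the evaluation conventions
  above exist precisely to score that honestly against multilabel truth.
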