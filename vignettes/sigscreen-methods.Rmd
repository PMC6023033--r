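---
title: "Methods: Signature descriptors, GA-SVM ensembles and overlap-gated screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Signature descriptors, GA-SVM ensembles and overlap-gated screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ligand-based virtual high-throughput screening (vHTS) ranks a candidate
compound library by its predicted activity against a target before anything
is pipetted.  `sigscreen` implements a complete ligand-based pipeline of the
kind used for serine-protease inhibitor discovery (the motivating target is
complement factor C1s, assayed by fluorogenic substrate cleavage): a small
labelled training set of actives and inactives is turned into fragment
descriptors, an ensemble of cross-validation-tied linear SVM classifiers
plus one IC50 regressor is selected by a genetic algorithm, and candidates
are accepted only when the whole ensemble agrees, the predicted potency is
useful, and the compound lies inside the training set's applicability
domain.  Validated hits are folded back into the training set and the cycle
repeats.

## Atomic Signatures

A molecule is reduced to a heavy-atom colored graph: element, aromatic
flag and formal charge per atom; order or aromaticity per bond.  Hydrogens
stay implicit, stereochemistry is ignored (the descriptor is
constitution-only), and multi-component inputs are reduced to the largest
covalent fragment, since that is the assayed species.

The *atomic Signature* of a root atom at height *h* is a canonical string
for the subtree obtained by expanding bonds outward from the root for *h*
steps, never stepping back along the bond just traversed.  The dialect used
here renders each atom as `[X]` (aromatic atoms lower-case, charges
appended), prefixes each child with its bond symbol (`''`/`=`/`#`/`:`), and
sorts the fully rendered child strings lexicographically (C collation) at
every branch point, which makes the string invariant under atom relabeling.
When a neighborhood is exhausted before the requested height (methane at
height 1), the rendered string equals its lower-height form but is still
recorded under the requested height; this keeps the per-height invariant
"sum of counts = number of heavy atoms" exact.  Whether such degenerate
strings should instead be merged across heights is a genuine convention
choice; `build_matrix(dedupe_degenerate_heights = TRUE)` exposes the other
convention.

The *molecular Signature* is the multiset of atomic Signatures over all
atoms at all requested heights (default 0, 1, 2 — high enough to encode
ortho/meta/para substitution patterns, small enough to keep vocabularies in
the hundreds for drug-like molecules).  A library's descriptor matrix has
one row per compound and one column per unique signature, with occurrence
counts as values; each column carries its observed (min, max) occurrence
window over the compounds that contain it.

Aromaticity follows the parser's perception (Kekulé structures are
aromatized before fragmentation, via OpenBabel/ChemmineR ring perception).
Aromatic versus Kekulé rendering changes signature identity, so one
convention must be fixed; the aromatic convention groups positional isomers
of substituted rings into shared ring signatures, which is what the
modelling wants.

## PCA pre-filter

Signature vocabularies outgrow the compound count quickly, so the matrix is
column-centered and the covariance eigendecomposed; components are kept up
to a cumulative variance cutoff (default 0.95) and each column's importance
is the sum over kept components of |loading| weighted by the component's
variance fraction.  The default rule keeps columns at or above the mean
importance.  A constant column has zero importance by construction and is
never kept.  The exact "significance" rule behind the published descriptor
counts is not stated anywhere we could follow, so both the cutoff and the
rule (`mean` / `nonzero`) are exposed as arguments.

## GA-SVM model search

Chromosomes are bit vectors over the PCA-selected columns.  A chromosome's
fitness is its subset's 10-fold cross-validated accuracy (classification)
or negative RMSE (regression), maximized over the SVM cost grid; the
training metric at the best cost breaks ties.  Fold assignment is
stratified by class and is a pure function of the seed and the labels, so
fitted ensembles are exactly reproducible.  GA defaults follow the
published protocol: elitism 0.7, crossover 0.8, mutation 0.1, population
1000, at most 1000 generations, stop after 100 without improvement.
Operator semantics mirror binary-GA convention (single-point crossover per
offspring, single random bit-flip per individual, elite fraction copied
unchanged); tournament selection of size 2 picks parents.  An all-zero
chromosome is assigned `-Inf` fitness and can never be returned.  Fitness
values are cached by subset, so repeated evaluation of elite chromosomes is
free and small search spaces are effectively enumerated.

The classifier is a soft-margin linear SVM (C-classification) over the cost
grid 0.01 to 1 in steps of 0.01; the regressor is a nu-SVR with nu = 0.2
over the same grid.  The grid/nu split is a convention of the underlying
toolkit family: the published protocol lists both parameters without
assigning them to tasks, and this assignment matches the defaults of the
cited implementations.  Classes are coded active = +1, so a larger decision
value means more confidently active.  Models are stored as plain linear
weights and intercept, which makes screening a dot product and makes the
JSON serialization toolkit-independent.

All final-population chromosomes tied on (cross-validation error, training
error) are kept, deduplicated by feature subset — there is no non-arbitrary
way to pick one, so the screen later requires unanimity across all of them.
Tied-model *counts* are runtime- and seed-specific and are reported, not
asserted.  The regression is trained on the actives alone, over the
actives' own Signature vocabulary, with log10(IC50/uM) as the default
target (predictions are exponentiated back to uM; `regression_target =
"linear"` disables the transform).

Overfitting control is exactly the pipeline's own: the PCA pre-filter
trims the vocabulary, cross-validation is the fitness, and no additional
correction is layered on top.

## Overlap and staged criteria

The applicability-domain metric is the overlap
Ω = (number of unique candidate signatures found in the training vocabulary
at an occurrence count inside the training (min, max) window) / (number of
unique candidate signatures).  A training compound scores Ω = 1 against its
own windows; a compound sharing nothing with the training set scores 0.
Signatures outside the training vocabulary reduce Ω but are silently absent
from the linear models' dot products — the models simply cannot see them,
which is precisely why Ω is needed as a separate gate.  Ω is monotone
non-decreasing as the training set grows, because windows only widen.

Two staged criteria sets are shipped: the strict first-round set
(Ω = 1, every classifier's decision value > 2, predicted IC50 < 50 uM) and
the relaxed second-round set (Ω ≥ 0.9, every value > 0, IC50 < 50 uM).
Score and IC50 comparisons are strict inequalities, the overlap bound is
non-strict, exactly as the protocol prints them.  Whether the decision
value should be margin-normalized is not specified anywhere; the raw value
is used and the thresholds keep their conventional meaning (distance from
the separating hyperplane in weight units).  Screening is chunked
(`chunk_size`) so memory stays constant in library size, and verdicts are
pure functions of (candidate, ensemble, criteria).

## Filters

PAINS removal matches SMARTS substructure families locally; the shipped
file is a curated subset of the published families, hand-written from their
public descriptions, and is a replaceable data file.  The original
work used an external web service for this step, so exact removed-compound
counts depend on the list in use and are not reproducible from the text.
"Similar structure" removal is implemented as signature-set Tanimoto ≥ 0.9
against the identified PAINS (threshold and reference set configurable);
the similarity metric was unspecified, and the signature-set Tanimoto keeps
the whole pipeline inside one descriptor family.

## Assay reduction

Percent inhibition is `100 * (1 - (signal - blank)/(control - blank))` with
blank and control aggregated by arithmetic mean over their plate columns
(8-row x 12-column plates: compounds in columns 1-9, protein check in 10,
blank in 11, control in 12).  The IC50 is the linear interpolation *in
concentration* of the adjacent dilution pair bracketing 50% inhibition
(eight four-fold dilutions, 50 uM down to 3.05 nM); if no pair brackets
50%, the compound is inactive.  Log-concentration interpolation would be
the pharmacologically smoother choice, but plain linear interpolation of
the bracketing points is the protocol's stated reduction, so it is the
default; non-monotone curves use the bracket nearest the highest
concentration and are flagged.  A compound is called active only when
every replicate (typically three) yields an IC50; partial crossings are
recorded as inactive with a weak-activity flag.  Validated calls are
appended to the training library (`augment_training_set`), which refuses
duplicate ids rather than silently resolving label conflicts.

## The synthetic-data generator

`generate_library()` builds benzene/pyridine scaffolds with 0-4 decoy
substituents (halogens, methyl, methoxy, ester, nitrile, ...) at the
ortho/meta/para/anchor positions and plants a primary sulfonamide
pharmacophore with probability `active_fraction` (default 0.118, the
active:inactive imbalance of the motivating training assay).  With the
default deterministic rule, activity coincides exactly with pharmacophore
presence and active IC50s are log-normal (median 5 uM, sdlog 0.6, keeping
most mass inside the tested 0.003-50 uM window).  Because no decoy contains
sulfur, the planted signal maps onto sulfur-rooted signatures, giving every
stage a knowable ground truth.  `generate_plate()` simulates plates from a
one-site saturating curve, `inhibition = c/(c + IC50)`, plus Gaussian
fluorescence noise.

What the generator does *not* emulate matters for interpreting green
tests: real chemical series have correlated scaffolds, activity cliffs,
assay artifacts and label noise; the planted rule is a single perfectly
informative substructure.  Passing the recovery tests therefore shows the
machinery is correct (the search finds a recoverable signal, the domain
gate excludes extrapolation, the reduction recovers planted potencies); it
does not certify hit rates on real libraries.

## Numerical and testing choices

Test and example problem sizes are chosen to exercise every code path at
desk scale: training libraries of 120-200 compounds, candidate libraries
of 25-1000, GA populations of 20-80 with 12-60 generations and a coarse
3-5 point cost grid (the planted signal is linearly separable, so the
search converges immediately; fitness caching makes small subset spaces
effectively exhaustive), 10-fold cross-validation throughout.  The
acceptance script trains on 200 compounds and screens 500.

The triplicate plate-recovery check compares the low-noise triplicate mean
against the *noiseless interpolation value*, not the true IC50: with
four-fold dilution spacing, linear-in-concentration interpolation carries a
deterministic bias (a true 5 uM recovers as 6.41 uM from the 3.125/12.5 uM
bracket) that the separate noiseless check bounds by the bracketing
interval.  The Monte-Carlo check is therefore a pure noise-stability
statement.

Known limitations: charges are read from the V2000 atom-block charge
column (the convention OpenBabel writes); signature canonicalization sorts
child strings rather than minimizing over all orderings, which is a valid
canonical form but a different string than a minimization dialect would
produce; tied-model counts depend on seed and population size; and the
shipped PAINS list is deliberately small — reproduction of any published
filtered-set size requires the exact list that produced it.
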