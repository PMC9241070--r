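---
title: "Classifying physiological and adventitious metal-binding sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying physiological and adventitious metal-binding sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

More than a third of experimentally determined protein structures contain
at least one metal ion, but not every observed metal site is biologically
meaningful.  Cations present during purification or crystallization can
bind opportunistically — typically at the protein surface, with few
protein-donated coordination bonds — and such *adventitious* sites are
easily mistaken for functional, *physiological* metal sites.  `mbsnet`
implements a pipeline for making that call from a 3D structure: geometric
extraction of metal-binding sites (MBSs), a per-residue feature encoding of
the chain harboring the site, a convolutional-recurrent neural classifier
with a confidence score, a perturbation-based feature-importance statistic,
the standard binary-classification metric suite, and an interpretable
rule-of-thumb baseline.

## Site extraction

The geometric definitions follow the MetalPDB conventions:

* **Donor atoms** — non-hydrogen atoms strictly within 3.0 Å of a metal
  atom.  Atoms of other metal ions are never counted as donors.
* **Metal ligands (first coordination sphere)** — residues or chemical
  species containing at least one donor atom.
* **Environment (second sphere)** — every other residue or species with at
  least one atom strictly within 5.0 Å of any ligand atom.  Metal atoms are
  sites themselves, never environment members.
* **Polynuclear merging** — metals whose *protein* ligand residues overlap
  belong to one site; independent sites must have disjoint metal-binding
  protein residues.  A shared water does not merge two sites.
* **Filtering** — sites with no protein donor atom are discarded, as are
  heme-ligated sites (configurable het-code list, default HEM/HEA/HEB/HEC).

Both cutoffs are strict (`<`), mirroring the "smaller than" convention at
3.0 Å and applied consistently at 5.0 Å.  Only the first model of a
coordinate file is used; for alternate locations the highest-occupancy
altloc wins (ties resolved to the lowest altloc letter).  Coordinates are
taken from the asymmetric-unit content as deposited — no symmetry
expansion — and features are computed on a single chain of record (the
protein chain contributing the most donor atoms; lexicographic
tie-break).  Residues are mapped to sequence positions 1..L in the order
they appear in the coordinate records; author-numbering gaps do not create
positional gaps.  Unobserved (SEQRES-only) residues are not represented.

## The 29 per-residue features

Each site is encoded as an `L × 29` matrix over the full chain of record:

| columns | content |
|---|---|
| 1–20 | amino-acid frequencies from the PSFM (order A,C,D,E,F,G,H,I,K,L,M,N,P,Q,R,S,T,V,W,Y) |
| 21–22 | absolute (Å²) and relative (%) solvent accessibility |
| 23–25 | binding-role one-hot: ligand, environment, other |
| 26–29 | secondary-structure one-hot: helix, sheet, turn, other |

The position-specific frequency matrix is computed from a user-supplied
multiple sequence alignment (aligned FASTA or A3M; insertion states
removed).  Alignment columns are projected onto the query; columns where
strictly more than half the sequences are gapped are masked and carry the
query one-hot, so every residue keeps a conservation row.  Nonstandard
residues are ignored in the counts.

Absolute accessibility comes either from a NACCESS-style `.rsa` file
(all-atom values; both the chain-id and chain-less dialects are parsed) or
from the built-in Shrake–Rupley implementation (probe 1.4 Å, 960
quasi-uniform mesh points per heavy atom, Bondi radii), always computed on
the isolated chain with metals, waters and other chains removed.  Relative
accessibility is `100 × absolute / reference`, with the theoretical
Gly-X-Gly maxima of Tien et al. (2013) as the bundled reference table;
values above 100 are kept (extended conformations).  Secondary structure
uses a DSSP file when available (H/G/I → helix, E/B → sheet, T → turn,
else other) and otherwise a coarse Cα-geometry fallback; the choice is
deliberately permissive because secondary structure carries little signal
for this task.

The role encoding is one-hot rather than the ordinal 0/1/2: three separate
indicator columns are what brings the total to 29, and they let the first
network layer weigh ligand and environment membership independently.

## The classifier

The network reads the matrix row by row: a width-7 one-dimensional
convolution (64 channels by default; zero padding preserves length) builds
a local representation of each residue's neighborhood, a unidirectional
gated recurrent (GRU) layer integrates the sequence and is read out only at
its final hidden state `h_L` — a fixed-size global representation of the
site — and a linear layer with two output neurons plus softmax yields
`[P(physiological | S), P(adventitious | S)]`.  The *confidence* of a
prediction is the absolute difference of the two probabilities, and the
class call is physiological iff `P(physiological) > β` (default β = 0.5;
ties go to adventitious, making the positive call conservative).

Training minimizes cross-entropy with the physiological-class contribution
scaled by 1.7 to offset the class imbalance of annotated zinc data.  Sites
are processed per sequence — no cross-site padding — in mini-batches of 32,
with Adam (learning rate 1e-3 by default), early stopping on a validation
set, and restoration of the best-validation-loss parameters.  All
randomness (initialization, epoch shuffling, the augmentation stream) is
drawn from, or seeded by, the R RNG, so a fixed `seed` reproduces the
training trajectory bitwise.

Three numerical choices deserve explanation:

* **Fixed feature-type scaling.**  The two accessibility columns are
  divided by 100 inside the model (the divisors are stored and re-applied
  at prediction), putting all inputs on an order-one scale.  A data-driven
  z-scoring was rejected: it rescales each feature by 1/sd, which turns a
  domain-magnitude perturbation of a [0,1] frequency column into a
  ~7–10 sd input excursion and makes the importance probe (below)
  nonspecific.
* **Bounded convolution activation (tanh).**  A bounded first nonlinearity
  caps the damage any single out-of-range input can inject into the
  recurrent state.
* **Sparse input layer.**  The convolution weights receive a proximal L1
  step (default 0.4) on top of decoupled weight decay (1e-3), so inputs
  without a persistent gradient signal end with *exactly zero* first-layer
  weights, and a domain-scaled Gaussian augmentation of the training inputs
  (0.15 × each column's empirical range) supplies the corresponding
  shrinkage pressure.  Together these make the network provably blind to
  features it does not use — the property that lets the importance
  statistic return zero for an uninformative column instead of an
  out-of-distribution artifact.

The architecture constants (filter width 7, 64 channels, hidden size 128)
are configurable defaults of this package, not canonical values; the
recurrent cell is gated (GRU) for trainability, and recurrence is
unidirectional because only `h_L` is read.

## Cross-validation

`mbsnet_cv()` implements the rotating 10-fold protocol: folds are
stratified by label (each fold's class ratio matches the dataset within one
site per class) and optionally grouped, so clusters of equivalent sites
never straddle folds.  In rotation *t*, fold *t* is the held-out test set,
fold *t* mod *k* + 1 is the validation set for early stopping, and the
remaining *k* − 2 folds train the model.  Every site is predicted exactly
once as test data; accuracies are reported per fold (mean ± sd) alongside
the pooled confusion matrix and pooled ROC.

## Feature importance by perturbation

The importance of feature *i* is the accuracy the model loses when that
feature is degraded on the test set:

```
S_i^p = S_i + α_i g,   g ~ N(0, 1) per residue
I_i   = Acc(Y_targ, Y) − Acc(Y_targ, Y_noise(i))
```

where `α_i` is the magnitude of the feature's domain, estimated as the
empirical max − min over the training folds.  Perturbed values are not
clipped — the formula is purely additive.  For reporting, the 20
amino-acid columns are perturbed individually while the three role columns
and the four secondary-structure columns form one group each (24 groups);
grouped columns are perturbed jointly with independent noise per column.
`importance_over_folds()` repeats this per cross-validation rotation with
that rotation's model and training-fold magnitudes and reports mean ± sd
over the folds.  Reduced-feature retraining experiments are a recipe, not
a separate algorithm: pass column-subset matrices to `mbsnet()`.

## The rule baseline

The interpretable reference classifier calls a site physiological when any
clause fires (OR-combination — each condition is independently strong):

* the MBS involves **≥ 20 protein residues**, or
* the protein chain provides **≥ 4 amino-acid ligands**, or
* (only when a cutoff is configured) the mean absolute accessibility of the
  ligands is below the cutoff.  No default cutoff is set: the
  accessibility distributions of the two classes overlap too widely for a
  reliable threshold, even though physiological ligands do tend to be
  buried.

Both count thresholds are inclusive.  A possible poly-His purification tag
(more than two His ligands within a terminal 12-residue window) triggers a
warning but never changes the call.

## The synthetic-data generator

Real annotated MBS datasets require a curated structural database and
per-chain alignments, so the package ships a generator that emulates the
class-conditional structure of annotated zinc sites and makes the whole
pipeline testable offline:

* **Site size** (ligand + environment residues): ligand count from a
  per-class categorical distribution (physiological mass concentrated on
  3–4, adventitious on 1–2), environment count negative-binomial with the
  class means anchored at 22.3 (physiological) and 12.5 (adventitious)
  residues.
* **Chain length** is drawn independently of the site (30 + NB, mean 55),
  so total length carries no label information — an early design in which
  the chain grew with the site let the classifier cheat by counting rows.
* **Ligand accessibility**: overlapping log-normals (physiological
  median 10 Å², adventitious 25 Å²); all other residues share one wide
  log-normal (median 20 Å², σ_log 1.4 — a substantial buried fraction, as
  in folded chains), capped at a physical ceiling of 250 Å².  Sharing one
  non-ligand distribution across classes encodes the observation that
  second-sphere exposure is class-independent.
* **Conservation**: Dirichlet rows centred on a true residue.
  Physiological ligands are deeply conserved Cys/His (Dirichlet boost 18);
  adventitious ligands have a similar identity mix but shallow conservation
  (boost 5) — the discriminating signal is the conservation *pattern*, not
  the identity.  35% of non-site positions are strongly conserved
  distractors enriched in typical structural/catalytic residues; without
  them, conservation alone would give away the site location, which real
  chains do not allow.
* **Secondary structure**: background multinomial, class-independent.

A `synthetic_spec()` override mechanism exposes every parameter; and
`equalize_classes()` produces the matched null generator (identical class
parameters) under which a trained classifier should sit at chance.  An
optional 30th pure-noise column supports the importance-null harness.

What the generator does *not* emulate: real coordination geometry and
chemistry, fold-dependent correlation between neighboring residues'
features, alignment-depth effects on PSFM quality, and inter-site
redundancy (homologous sites across structures).  Passing tests on
synthetic data therefore demonstrate that the machinery — extraction,
encoding, optimization, fold discipline, importance arithmetic — behaves
correctly and can recover planted class structure of realistic effect
size; they do not certify accuracy on real structural data.  Toy structure
files with exact metal–atom distances (`generate_toy_structure()`) cover
the geometric rules at their boundaries.

## Problem sizes and runtime posture

The test and reproduction scripts use a deliberately moderate scale chosen
to exercise every component on one CPU: synthetic datasets of 1 000 sites
(500 per class) for the 10-fold cross-validation and its label-shuffled
control, a 32-channel/48-hidden network trained up to 60 epochs with
patience 12 and learning rate 2e-3, importance over all 10 rotations with
the default 24 groups, a 10-seed noise-column null on 400-site datasets,
4 000 draws for generator calibration, and 100 random structures of up to
~200 atoms for the extraction oracle.  The full-size defaults (64
channels, hidden 128) remain available for larger experiments.

## Degenerate inputs and edge policies

* Zero-length sequences are rejected at every encoding stage.
* A metric whose denominator is zero (e.g. PPV with no positive calls) is
  reported as `NA`, never silently as 0.
* Confidence bins are right-open except the last (`[0.9, 1.0]`), so a
  confidence of exactly 1 is counted once; the aggregate high-confidence
  band uses a strict `> 0.85` cutoff by default.
* A classification score exactly at β classifies as adventitious.
* Constant features get magnitude 0 with a warning, making their
  perturbation a no-op.
* PSFM columns with no standard residues fall back to the query one-hot.

## Known limitations

* Metal identity is taken at face value from the coordinate file; no
  occupancy or chemical-identity validation is attempted.
* MSAs are consumed, never computed; PSFM quality is bounded by the
  supplied alignment.
* The coordinate-geometry secondary-structure fallback is coarse; supply a
  DSSP file where fidelity matters (the feature's overall influence on
  classification is small).
* The iron use case is plain inference through a zinc-trained model; no
  transfer learning is provided.
* Biological assemblies are not reconstructed; interface sites are
  evaluated on a single chain.
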