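---
title: "Reaction-informed hit expansion with miniscifunnel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-informed hit expansion with miniscifunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miniscifunnel)
```

## Scope

`miniscifunnel` implements a computational funnel for expanding
N-heteroaromatic hit molecules by Minisci-type C-H alkylation: radical
decarboxylative coupling of an azine with a carboxylic acid under silver
catalysis and persulfate oxidation.  The package covers the machine-readable
reaction-data layer (a SURF-compatible tab-separated dialect), molecular
graph featurization, a graph transformer neural network (GTNN) that predicts
reaction yield from the two reactant graphs plus categorical reaction
conditions, out-of-distribution cross-validation regimes, virtual library
enumeration by reaction templates, and a staged multi-parameter
prioritization funnel.  A synthetic-data generator with a planted,
recoverable yield surface makes all of it testable end to end without any
experimental download.

## Reaction records and outcomes

A reaction record holds the N-arene and acid structures (SMILES), five
categorical condition fields (reagent/oxidant, solvent, catalyst, additive,
atmosphere), the numeric plate variables (temperature in deg C, time in h,
concentration in mol/L, scale in mol) and the mono- and di-alkylation
yields.  Yields are held internally as fractions in [0, 1] and serialized as
percent, since LC-MS area reports are conventionally percentages while model
outputs live on [0, 1].  Mono plus di yields occasionally oversum slightly
in area-percent data, so the sum is clipped at 1 rather than rejected.  The
*total yield* is `min(1, mono + di)`, and the *binary outcome* is positive
when the total yield reaches the 5% LC-MS detection threshold; the boundary
is inclusive.

## Molecular graphs

Atoms are featurized as the concatenation of four one-hot blocks: 12
elements (H, C, N, O, F, P, S, Cl, Br, I, Si, Se), ring membership,
aromaticity, and hybridization (SP3, SP2, SP, and S for unhybridized atoms,
notably hydrogen) - 20 dimensions, exactly four bits set.  Hydrogens are
explicit nodes.  Edges are covalent bonds.  Elements outside the list (e.g.
boron) are rejected with a named error rather than silently collapsed.

In 3D mode each molecule carries an ensemble of conformers, and every edge
is annotated with a Fourier encoding of its interatomic distance:
`[sin(f_k r), cos(f_k r)]` for K frequencies.  The default basis uses K = 16
frequencies geometrically spaced so their half-periods span 0.5-12 angstrom,
covering covalent bonds through through-space distances.  Distance features
enter messages only; by default the 3D edge set remains the covalent bond
graph (the most literal reading of a message sum over bonded neighbors), and
a fully connected variant is intentionally left out of scope of the default
configuration.

### Conformers

Conformers are generated by the package's own seeded distance-geometry-style
embedder: random Gaussian initial coordinates refined by gradient descent on
a harmonic force field with bond-length targets (covalent radii sums,
shortened with bond order), 1-3 distance targets from the central atom's
ideal angle, and a soft repulsion between atoms three or more bonds apart.
Distinct conformers are distinct random initializations relaxing into
different local minima; embeddings that fail a bond-length quality check are
retried up to five times with fresh derived seeds before raising an error.
The same structure and seed give bitwise identical coordinates, which the
reproducibility contracts require.  The embedder is deliberately light: it
has no aromatic planarity or torsional terms, so ring geometries are
approximate.  Since the default 3D featurization only consumes *bonded*
distances, this mainly affects the fully-connected variant; the invariance
guarantees (rigid motions leave all predictions unchanged) hold regardless
of embedding quality.

## Reaction conditions

The five categorical condition fields are one-hot encoded per category and
concatenated, in the order reagent, solvent, catalyst, additive, atmosphere.
With the training campaign's vocabulary (four reagents, four solvents, 11
catalysts, four additives, two atmospheres) the vector has length 25 with
exactly five bits set.  Unseen labels raise an error by default; an `<UNK>`
level can be enabled per category, but deliberately is not the default
because silently collapsing condition categories corrupts extrapolation
experiments.

## The GTNN

Both reactant graphs pass through a shared two-layer atom-embedding MLP and
then through two *unshared* towers of three message-passing rounds.  One
round updates atom `i` as

    h_i^{l+1} = h_i^l + phi(h_i^l, sum_{j in N(i)} psi(h_i^l, h_j^l, r_ij))

where `psi` and `phi` are two-layer MLPs, the neighbor sum is the
permutation-invariant aggregator (an atom with no neighbors receives the
zero vector), and `r_ij` is the Fourier distance encoding in 3D mode (absent
in 2D).  The residual form of the update is an architectural choice
following the E(3)-equivariant GNN lineage this model family descends from;
it stabilizes optimization at these depths.  The per-round representations
`[h^1, h^2, h^3]` are concatenated, transformed by an MLP, and pooled into a
fixed-length molecular vector by attention with learnable seed queries - the
pooling core of a graph multiset transformer.  Two attention heads are the
default, with four available; neither head count is asserted as canonical.  The two molecular
vectors and a learned linear embedding of the condition one-hot are
concatenated and mapped through a final MLP to a scalar squashed into
[0, 1] by a logistic function.  Both targets - continuous total yield and
the 0/1 binary outcome - are trained as regression with MSE loss.

With the full-size configuration (hidden width 128, embedding width 64,
first post-pooling layer 256, three rounds, two heads) the model has
about 1.7-1.8 million trainable parameters.

### Training

Training uses minibatch Adam, MSE loss, a step learning-rate decay (factor
0.5 every 100 epochs; a decay-once variant is selectable since either
reading of "applied after 100 epochs" is defensible), and exponential
moving-average smoothing of the weights with factor 0.9.  The smoothing is
interpreted as an EMA over *weights* used for validation and testing - the
most common meaning of a smoothing factor in this training idiom - and can
be disabled.  Early stopping keeps the parameters from the epoch with the
lowest validation MAE; the validation set is a seeded random 10% of the
training partition.  In 3D mode one
conformer per unique molecule is drawn per epoch (a per-molecule-per-epoch
compromise of per-step random selection that lets all occurrences of a
molecule in an epoch share one tower evaluation), and test-time predictions
average the forward passes over all conformers.

The output bias is initialized at the logit of a 20% yield prior rather
than 0.5.  HTE reaction data are dominated by low yields, and starting the
squashed output near the data's scale avoids an early plunge into the flat
region of the logistic where MSE gradients vanish.

Batches stack all graphs into one node set with per-node graph indices, and
each unique molecule is evaluated once per batch with its pooled vector
scattered to the reactions that use it.  The numerical core is implemented
twice: a readable R reference (also backing the exported
`message_passing_layer()` and `pool_graph()` operations) and a compiled
C++ fast path used for training; the test suite pins the two together to
machine precision and checks the analytic gradient against central finite
differences.

### Reduced desk-scale configuration

`gtnn_config_reduced()` scales the model to hidden width 32 (embedding 16,
post-pooling 64) and 200 epochs so that a full training run takes minutes on
one CPU.  Two settings differ from the full-size defaults, both fixed as
part of this configuration's design: the minibatch is enlarged to 256 with
the learning rate raised to 2e-3 (few large steps fit a short CPU schedule
better than many small ones, and larger batches maximize the
shared-molecule savings above), and a decoupled weight decay of 1e-4 is
applied because at this capacity the dominant failure mode is memorizing
the yield noise of individual training reactions rather than the planted
structure - the decay trades a little training fit for materially better
held-out error.

### Ensemble inference

Funnel-facing yield predictions are made by a small ensemble: three models
trained on the same split with independently derived initialization and
shuffling seeds, predictions averaged (`train_gtnn_ensemble()`).  Short CPU
trainings of the reduced configuration show meaningful run-to-run variance
in held-out error; averaging a few models removes most of it while also
improving the error itself, and the three-model mean is the package's
standard inference procedure for synthesizability assessment.

## Cross-validation regimes

Four split modes probe increasingly hard generalization: `0D` shuffles
reactions (novel combinations of known reactants), `1DN` holds out whole
N-arenes, `1DA` whole acids, and `2D` both at once.  Entities are identified
by canonical SMILES (via Open Babel), so one molecule spelled two ways
cannot leak across folds.  In the 2D regime the arene and acid entity sets
are partitioned independently and paired fold-by-fold; a fold's test set is
the intersection (records whose arene *and* acid are both held out), and
records with exactly one novel component are dropped from that fold entirely
rather than returned to training - the conservative choice that keeps
training free of held-out entities.  On a fully crossed grid with equal
partitions at k = 2 this yields exactly 1/4 test cells and 1/2 dropped
cells per fold.  Remainder entities are distributed round-robin after a
seeded shuffle, and identical seeds reproduce identical assignments
bitwise.

## Synthetic data

The generator emulates the screening campaign's shape: 80 N-arenes by 59
acids by a 24-well plate (the six silver salts and four additive levels of
the published plate design, with single oxidant, solvent and atmosphere),
sampled at 12% grid coverage, with a 30% positive rate at the 5% threshold.
Arenes are drawn from a parametric grammar over azine/diazine/quinoline
cores with small substituents; acids are branched/cyclic alkyl carboxylic
acids under 230 g/mol.  The latent yield is

    clip01(base + arene_effect + acid_effect + catalyst:additive + noise)

with independent Gaussian effects (defaults: arene sd 0.14, acid sd 0.10,
interaction sd 0.07, noise sd 0.05 - scales chosen once so that entity
effects dominate the noise the way reactivity differences dominate replicate
error in plate data).  The intercept `base` is calibrated by a quantile of
the sampled latents so the positive rate hits its target by construction.
The total yield is split into mono/di components with the di share at most
the mono share.  Because the surface is additive plus one condition
interaction, held-out-entity splits are *provably* harder than random
splits - a novel arene carries an unseen effect no model can recover - which
reproduces the qualitative 0D-versus-1D/2D ordering without claiming its
magnitudes.

What the generator does **not** emulate: real electronic structure-activity
relationships (effects are random per entity, so a model can only memorize
entities, not extrapolate chemistry), Minisci regiochemical competition,
correlated LC-MS measurement error, or plate/batch effects.  Passing tests
therefore demonstrate that the machinery - featurization, training,
splitting, evaluation - is correct and that planted signal of realistic
magnitude is recoverable; they say nothing about predictive accuracy on real
reaction data.

With the noise switched off, ordinary least squares on entity/condition
dummies reproduces the unclipped part of the surface to 1e-6, which the test
suite uses as a parameter-recovery check.

## Virtual library enumeration

The Minisci template replaces the hydrogen at a scaffold's alkylation site
with the acid's decarboxylated alkyl fragment (the acid minus CO2), by
direct SMILES graph editing.  Site indices refer to atoms in the order they
appear in the *input* SMILES (0-based).  When no site is designated,
`suggest_site()` applies the classic selectivity rule for protonated
azines: prefer an aromatic C-H ortho to a ring nitrogen, then para within
the same six-membered ring, ties broken by lowest atom index.  One product
per (scaffold, acid) pair is the default so the library size is exactly the
pair count; a multi-site mode and canonical de-duplication exist behind
flags.  Every product must satisfy the heavy-atom balance
`heavy(product) = heavy(scaffold) + heavy(acid) - 3`.  Acids are pre-filtered
on molecular weight strictly below 230 g/mol (the boundary is excluded) and
a minimum fraction of sp3 carbons.  Stereo tags in acid fragments are
carried through textually; parities are not re-derived.

## The prioritization funnel

Candidates flow through nested stages with inclusive thresholds: stage 1
keeps predicted pIC50 >= 6, stage 2 additionally requires predicted yield
>= 5% (synthesizability), stage 3 tightens potency to pIC50 >= 8.  ADME
endpoints (LogD, LYSA solubility in ug/mL, P-gp efflux ratio, PAMPA
permeability in 1e-6 cm/s) *annotate and rank* by default instead of
eliminating - sequential hard cuts on model outputs propagate model error,
so fixed ADME thresholds are intentionally not applied unless the strict
mode is requested.  The final ranking is deterministic: descending predicted
pIC50, ties by descending predicted yield, then lexicographic candidate key.
The subsequent manual selection step (availability, chemist judgment) is
explicitly out of scope: the funnel emits the annotated stage-3 list and
stops.

Scorers are pluggable: any function mapping a candidate table to one value
per row can be registered under a named endpoint.  The built-in
`potency:synthetic` and `adme:toy-logp` scorers are deterministic toys for
pipeline testing and reproduce no published model; the yield scorer wraps a
trained GTNN checkpoint.

`pIC50 = 9 - log10(IC50/nM)` and `LipE = pIC50 - cLogP` are provided as
exact conversions.

## Numerical choices

* Attention logits are clamped at +/-30 before the softmax (removing the
  need for a per-graph max subtraction); clamped entries receive zero
  gradient.
* The logistic output is clamped at +/-35 logits against overflow.
* Empty neighbor sums and empty attention groups follow the zero-vector
  convention; no silent NaNs (asserted over randomized fixtures).
* Degenerate metric inputs error loudly: Pearson on a constant vector is a
  `degenerate_input_error`, precision without predicted positives is
  reported as undefined rather than zero, and a single-fold standard
  deviation is flagged undefined.
* All randomness fans out from one user seed through named substreams
  (structures, dataset, split, initialization, per-epoch shuffling,
  conformers), so components are independently reproducible.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` exercise the reduced configuration
on a synthetic dataset of 2,000 reactions, train three model seeds per split
regime (0D and 2D), enumerate a 125 x 211 virtual library, and check the
generator's calibration on 5,000 reactions.  These sizes are the package's
chosen desk-scale demonstration: large enough for the planted-signal and
ordering checks to be stable across seeds, small enough to run in minutes on
a single CPU.

## Known limitations

* The conformer embedder is a light-weight stand-in for force-field-grade
  conformer generation; geometries are approximate.
* Aromaticity perception trusts lowercase SMILES notation (with a limited
  alternating-bond fallback for Kekule input); exotic aromatic systems
  should be supplied in aromatic notation.
* The synthetic yield surface is additive by design; it cannot certify
  chemical extrapolation, only machinery correctness.
* The binary outcome is evaluated by thresholding predicted yield at 5%; a
  dedicated binary regression head is available but funnel decisions use
  thresholded yields.
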