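---
title: "Modelling dTm from structure-based descriptors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dTm from structure-based descriptors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A single-point mutation changes a protein's melting temperature by an
amount dTm (degrees C, mutant Tm minus wild-type Tm; positive =
stabilizing).  `thermoforest` implements a quantitative
structure-property relationship (QSPR) approach to predicting dTm: a set
of physicochemical descriptors is computed for each mutant from nothing
but a PDB structure and the identity of the substitution, a
random-forest regressor maps descriptors to dTm, and every prediction is
accompanied by an applicability-domain verdict that says whether the
model should be trusted for that query at all.

This vignette records the model, its parameters and the design decisions
behind them, in enough detail that a user can judge what the package
does and does not claim.

# Descriptor blocks

Descriptors are organised in named blocks that can be assembled in any
combination (`assemble()`):

**A (amino acid), 54 columns.**  Eighteen per-residue property scales,
each contributing the wild-type value (`_first`), the mutant value
(`_second`) and their difference (`_diff`).  The scale list (helix,
sheet and coil propensity, aromaticity, branchness, bulkiness, charge,
octanol-to-water transfer free energy, flexibility, hydrophobicity,
logD, molecular weight, mutability, pI, two polarity scales, van der
Waals volume, consensus hydrophobicity) is fixed; the shipped *values*
are documented literature scales (Chou-Fasman propensities, Zimmerman
bulkiness and polarity, Grantham polarity, Fauchère-Pliška transfer free
energies, Bhaskaran-Ponnuswamy flexibility, Kyte-Doolittle
hydrophobicity, Dayhoff mutability, Eisenberg consensus hydrophobicity,
free amino-acid molecular weights, standard pI values, side-chain van
der Waals volumes).  Two scales are explicit surrogates: `logD` is the
Fauchère-Pliška scale with a -2 ionisation correction for D/E/K/R, and
`aromaticity`/`branchness` are ring-count and C-beta-branching
indicators.  The whole table lives in one editable TSV
(`inst/extdata/aa_properties.tsv`), so users holding the original scale
collection can substitute it via `load_property_table()`.

**L (local structure), 9 columns.**  The environment of the wild-type
residue: `totalArea` (reference solvent-accessible surface area of the
free residue including backbone), `buriedArea` (totalArea minus the
observed SASA in the folded structure), `hydrophobicArea` (observed SASA
of carbon and sulfur atoms), `hydrophobicRatio`, `fractionBuried`
(buriedArea/totalArea, clipped to [0, 1]) and a four-way one-hot
encoding of the secondary-structure class (helix/beta/coil/turn).  The
one-hot encoding was chosen over an ordinal code because tree ensembles
handle indicators naturally and no ordering of the classes is defensible.

SASA is computed with an in-package Shrake-Rupley implementation: each
heavy atom is a sphere of radius r_vdw + 1.4 Å (water-sized probe)
sampled with a deterministic golden-spiral point set (960 points per
atom by default); the accessible fraction is the share of points outside
all neighbouring inflated spheres.  Radii are C 1.70, N 1.55, O 1.52,
S 1.80 Å (overridable); hydrogens are ignored throughout — all
descriptors are heavy-atom quantities.  With 960 points the two-sphere
overlap case agrees with the analytic spherical-cap area to well under
1%, and doubling the point count moves a whole-protein total by less
than 1%.  Because the point set is fixed in the laboratory frame,
sampled areas are rotation invariant only to within this discretisation
error.

The reference state behind `totalArea` is the central residue of an
extended Gly-X-Gly tripeptide (phi = -139, psi = 135) built from ideal
geometry.  The table is shipped (`inst/extdata/reference_areas.tsv`) and
regenerable (`regenerate_reference_areas()`); regeneration reproduces
the shipped values to well under 1 Å².  Literature reference-area
tables derived from other conformer conventions differ by a few Å²; the
`fractionBuried` clip to [0, 1] absorbs the residual mismatch for fully
exposed residues.

Secondary structure comes from backbone hydrogen-bond patterns in the
Kabsch-Sander style.  The amide hydrogen is placed 1 Å from N along the
preceding peptide's C=O direction; a bond is called when the
electrostatic energy E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)
falls below -0.5 kcal/mol.  Two consecutive i→i+4 bonds make a helix
(3-10 and pi variants are not distinguished — the model uses four
collapsed classes), bridge ladder patterns (parallel or antiparallel)
make beta, isolated i→i+3 bonds make turn, and everything else —
including chain termini and residues with missing backbone atoms — is
coil.  Priority on overlap: helix > beta > turn.

**G (global structure), 14 columns.**  Whole-protein property deltas
between the wild type and a *naive mutant*: radius of gyration,
eccentricity (1 - smallest/largest gyration-tensor eigenvalue),
accessible/hydrophobic/hydrophilic surface area, volume (sum of mean
residue volumes), net formal charge (side chains at pH 7 plus one
positive/negative charge per chain terminus), dipole moment magnitude
over charged-group centroids (e·Å), helix ratio, and four hydrodynamic
surrogates derived from the compact-globule approximation Rh = 0.77 Rg
(frictional coefficient ∝ Rh, diffusion ∝ 1/Rh, sedimentation ∝
mass/Rh, mobility ∝ charge/Rh, all reported as unitless relative
quantities — only the deltas enter the model).  These formulas are
in-package substitutes for the whole-protein property calculators of
commercial modelling suites; they reproduce the *roles* of those
descriptors, not their numerical values.  A few of the suite-specific
descriptors (Henry's function, zeta dipole/quadrupole moments,
charge/zeta potential at the Debye length) have no defensible
first-principles substitute and are deliberately not implemented.

The naive mutant (`build_naive_mutant()`) replaces the side chain with
an idealized template grown by internal-coordinate extension (standard
bond lengths and angles, rotatable chi angles at 180 degrees, planar
rings, L chirality verified against crystallographic impropers) on the
unchanged backbone N-CA-C frame.  There is no repacking, rotamer search
or minimisation: steric strain in the mutant is part of what the G
deltas measure, and anything more would re-implement the
molecular-mechanics mutagenesis that is explicitly out of scope.

**totE / indE / tiE (energy), imported.**  Per-mutant ddG energies from
external molecular-mechanics packages enter through
`load_energy_table()`: one `totE` column (final ddG, kcal/mol) and any
number of individual functional terms.  `tiE` is the *union* of the totE
column and the indE columns — the printed sum formula in the source
material describes the descriptor-set combination, not an arithmetic
sum, and no summed column is ever created.  The package never runs an
energy calculation itself.

# Structure preparation

`read_pdb()` parses ATOM and HETATM records (bio3d underneath),
preserves author numbering and insertion codes, and resolves alternate
locations by highest occupancy with ties broken toward altloc `A`.
`strip_non_protein()` removes waters, ions, ligands and nucleic acids,
maps selenomethionine to methionine (SE → SD), drops hydrogens, and
fails loudly when nothing remains.  Multi-chain files keep all protein
chains; descriptors are computed in the context of the full stripped
assembly, since occlusion "by protein" does not care which chain does
the occluding.  If the structure's residue at a mutant's (chain,
position) disagrees with the table's wild-type amino acid, the pipeline
raises an error instead of computing descriptors for the wrong residue.

# The forest and its protocols

`train_forest()` fits the classic bagged regression forest (CRAN
`randomForest`, the implementation family used for this model class)
with the fixed settings: **100 trees, unlimited depth, mtry =
ceiling(p/3), minimum node size 5**, no hyper-parameter optimisation.
Splits minimise node variance — the regression criterion.  (Descriptions
of this model class sometimes name the Gini index, which is defined only
for classification; for a continuous dTm response, variance reduction is
the criterion actually in effect.)  Every stochastic step is seeded;
training is bit-reproducible.

The ensemble prediction is the mean of the per-tree predictions, and
`predict_forest()` returns the full per-tree matrix because the
applicability-domain criterion needs it.  It follows that predictions
are always bounded by the training response range — the model cannot
extrapolate beyond observed dTm values, a structural limitation shared
by all tree ensembles.

**Validation** (`cross_validate()`) is 10 rounds of five-fold
cross-validation: each round partitions the mutants into five folds
(an 80/20 train/test split per fold), each mutant is held out exactly
once per round, and the round's metrics are computed on its pooled
held-out predictions — one value of each metric per round, ten values
in total.  Metrics: MAE, squared Pearson (r²) and Spearman (rho²)
correlations, and — through the two-class rule *stabilizing iff
dTm > 1 °C* — accuracy Q = (TP+TN)/n, TPR = TP/(TP+FN),
FPR = FP/(FP+TN), MCC, and AUC with the predicted dTm used directly as
the ranking score.  (A printed TPR formula in the source material reads
TP/(TP+TN); that is a typographical slip — the true-positive rate is by
definition TP/(TP+FN), which is what this package computes.)  The ROC
sweep runs over unique score thresholds with trapezoidal integration,
which resolves ties by rank-averaging and makes the AUC identical to the
Mann-Whitney concordance probability; the test suite verifies this
against exhaustive pair counting and against an independent ROC
implementation.

**Model comparison** (`bootstrap_compare()`): each of 1000 trials
independently resamples each model's ten per-round metric values with
replacement and averages them; model A is significantly better than B
when its average wins in more than 95% of trials.  Resampling is
independent per model (not paired) and exact ties count one half — both
conventions are choices this package documents rather than inherits.

**Descriptor significance** (`importance_threshold()`): permutation
importance (mean increase in out-of-bag squared error when a column is
shuffled) can be non-zero by chance, so the screen trains `n_null = 10`
forests on y-scrambled copies — responses randomly reassigned to the
wrong mutants, destroying any real structure-property relationship — and
keeps only descriptors whose real importance exceeds the maximum
importance seen in any null model.  On 50 columns of pure noise the
screen admits at most about one false positive.

# Applicability domain

A prediction is trusted when the **population variance of the per-tree
predictions** for the query is smaller than a reference variance derived
from cross-validation (`ad_assess()`).  Tree ensembles disagree most
where training data are sparse, so this flags distribution-shifted
queries without requiring any explicit descriptor-space distance.

The reference (`cv_reference_variance()`) defaults to the **variance of
the cross-validated models' prediction errors** (pooled held-out
residuals over all rounds).  An alternative reading — aggregating, over
training mutants, the variance of each mutant's held-out predictions
across rounds — is implemented as `method = "per_mutant"` (mean or
median aggregation), but it is kept for diagnostics only: round-to-round
spread of forest *means* is suppressed by averaging over trees, so that
reference lands one to two orders of magnitude below any query's
per-tree variance and declares essentially every query out of domain.
The residual reference lives on the same scale as the ensemble variance,
and with it the package reproduces the qualitative behaviour expected of
this criterion: in-distribution queries yield intermediate out-of-domain
fractions, shifted queries approach 100%, and the fraction is monotone
in the reference.

# The synthetic generator

`simulate_dataset()` draws independent standard-normal descriptors and
sets dTm = sum(coef × descriptor) + N(0, noise_sd); the attainable r²
(var(signal)/(var(signal)+noise²)) is returned alongside, so
cross-validation results can be checked against an analytic ceiling.
The default study conditions used by the tests and the acceptance script
are **n = 400 mutants, two active descriptors with coefficients 3 and 2,
three pure-noise descriptors, noise_sd = 2 °C**, giving an attainable
r² of 0.76 — a deliberately well-posed regime that exercises the default
forest settings (100 trees, minimum node 5) meaningfully at a size that
keeps a 10×5-fold protocol fast on one CPU.  The applicability-domain
experiment uses a heterogeneous training set — 360 core mutants plus a
sparse wide tail of 40 drawn at three times the descriptor scale —
because real mutant benchmarks are exactly that shape (a dense core of
heavily studied substitutions, typically alanine scans, plus a thin tail
of rare types), and it is this heterogeneity that gives the reference
variance its discriminating power.  In-distribution and shifted query
sets (mean shift of 4 descriptor SDs) then differ cleanly in their
out-of-domain fractions.

What the generator does *not* emulate: correlated descriptors, heavy
tails in dTm, the discrete block structure of one-hot secondary
structure, or any physics.  Passing synthetic tests therefore
demonstrates that the machinery (training, validation, significance
screening, AD) is correct, not that the descriptors capture protein
energetics; performance claims on real mutants can only come from a real
curated benchmark, which the user must supply (see the acceptance tests
for the expected layout).

`make_ideal_helix()` and `make_beta_hairpin()` provide geometry with
known ground truth: a phi/psi = -57/-47 helix whose interior must be
assigned helix, and two antiparallel extended strands placed by a
deterministic search (over flip axis, inter-strand offset and register
shift, clash-constrained) that maximises backbone hydrogen bonds.

# Numerical choices and degenerate inputs

* Probe radius 1.4 Å, 960 sphere points, golden-spiral layout: all
  configurable; defaults chosen so the analytic two-sphere check passes
  within 2% with margin and regeneration of the reference table is
  reproducible.
* Exactly duplicated atoms get zero area (with a warning) and do not
  occlude their twin.
* A residue with observed SASA of zero has fractionBuried 1 and
  hydrophobicRatio 0; negative buried areas arising from radius-table
  mismatches clip to fractionBuried 0.
* A constant response trains a valid degenerate forest (every tree
  predicts the constant).  A single-tree forest has ensemble variance 0,
  with a warning.
* Constant descriptor columns are kept (forests tolerate them) but
  reported.
* Mutants with any missing requested descriptor are dropped with a
  count, never imputed.
* Stability boundaries are closed exactly as defined: dTm = 1 °C is
  *not* stabilizing (two-class) and *is* neutral (three-class);
  ddG = -1 kcal/mol is destabilizing.  Fraction-buried strata close at
  their printed edges: <= 0.71, (0.71, 0.91], > 0.91.
* Mutant-type coverage uses the 19×19 = 361 possible-substitution
  convention of the field's benchmark descriptions.

# Known limitations

* The A/L/G descriptor values are substitutes for proprietary
  implementations; models trained here will not numerically match
  models trained on descriptor exports from commercial suites, though
  the descriptor roles and the modelling protocol are the same.
* The naive mutant is unrepacked; G deltas conflate substitution effects
  with template strain.
* Pure-R SASA is O(atoms × points × neighbours); adequate for
  descriptor computation per mutated residue and for the fixture sizes
  used here (seconds for a few hundred atoms), slow for very large
  complexes.
* The forest cannot predict dTm outside its training range, and — like
  every model of this class — degrades on mutant types absent from
  training; that is precisely what the applicability-domain report is
  for.
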