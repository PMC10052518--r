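---
title: "Predicting Fc/FcRn binding affinity from interface features: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Fc/FcRn binding affinity from interface features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcaffinity)
```

## The problem

The serum half-life of an IgG antibody is largely set by the pH-dependent
binding of its Fc portion to the neonatal Fc receptor (FcRn): the complex
forms in acidified endosomes, rescuing the antibody from lysosomal
catabolism, and releases at the neutral pH of plasma. Engineering Fc
mutations that tune the equilibrium dissociation constant (KD) of this
interaction is a standard route to longer-lived (or deliberately
short-lived) therapeutic antibodies. This package implements a structure
to affinity regression pipeline for that problem: Fc variants given as
mutation strings in EU numbering (e.g. `M252Y/S254T/T256E`) are modeled in
3D on a reference Fc/FcRn co-complex, featurized at the binding interface,
and regressed against measured `log10(KD)` values.

The pipeline has five stages, each an independent module:

1. **Structure I/O** — parse a PDB co-complex into a flat atom table with
   declared chain roles (Fc, FcRn alpha chain, beta-2-microglobulin) and
   declared EU-numbering offsets.
2. **Mutator** — build each variant's 3D model by deterministic side-chain
   replacement on the fixed backbone.
3. **Interface features** — per-residue accessible/buried surface areas and
   solvation energies plus complex-level interface counts; 147 features by
   default.
4. **Dataset curation** — harmonize assay pH, log-transform KD, remove
   effective-signature duplicates, split into the two learning sets.
5. **Learning / screening** — standardization, four regressors, importance
   based feature elimination, correlation pruning, 10-fold cross-validation
   with a shuffled-label control, and in silico random-library screening.

## Variant modeling

Side-chain replacement grafts ideal template geometry (fixed internal
coordinate tables per amino acid) onto the unchanged backbone N–CA–C
frame; the CB dihedral fixes chirality. The chi1 dihedral — and chi2 where
the side chain extends that far — is scanned in 30-degree steps, and the
rotamer minimizing a soft-sphere clash score

\[ \sum_{\text{pairs } i,j} \max(0,\; r_i + r_j - d_{ij})^2 \]

against every atom outside the mutated residue is kept, ties going to the
first rotamer in scan order. The procedure is deliberately simple: no
backbone relaxation, no energy model, chi3 and beyond stay at template
values. It replaces an interactive point-and-click mutagenesis step with a
reproducible, testable one: identical inputs give bitwise-identical
coordinates. Because downstream features are surface areas and 3.5–4.0 Å
contact counts, the coarse 30-degree granularity is adequate; ring-closure
bonds in the template construction are approximate for the same reason.
Crystal structures carry no hydrogens, so all geometry uses heavy atoms
only, with radii C 1.70, N 1.55, O 1.52, S 1.80 Å (default 1.70).

Applying a variant twice is, by contract, an error: after the first
application the wild-type precondition no longer holds, and a mismatch
between the expected and found residue stops the run rather than warning.

## Interface features

Solvent-accessible surface area (SASA) uses Shrake–Rupley quadrature: each
atom's sphere, inflated by the 1.4 Å water-probe radius, is sampled on a
deterministic quasi-uniform point set (960 points by default) and points
inside any other inflated sphere are occluded. The test suite checks the
quadrature against an independent Monte-Carlo occlusion oracle (uniform
random points, 10^5 per atom) to within 2% on random clusters. Because the
point set has a fixed orientation, SASA is invariant under rigid motion
only to quadrature tolerance (about 1%); all contact counts are exactly
invariant.

Per residue, the catalog records ASA (SASA summed over the residue's atoms
in the complex), BSA (isolated-chain SASA minus ASA — the area buried on
binding, not clipped at zero), and an atomic solvation energy
`sum(ASP(element) * SASA(atom))` with Eisenberg–McLachlan-style constants
(C +0.016, S +0.021, N/O −0.006 kcal/mol/Å^2). Complex-level features are:
interface residue count (BSA > 0.1 Å^2), solvation gain
`E(complex) − sum E(chains)`, hydrogen bonds (donor–acceptor N/O pairs
across chains within 3.5 Å, from a fixed per-residue chemistry table),
salt bridges (Asp/Glu carboxylate vs Lys/Arg/His side-chain nitrogens
within 4.0 Å, one per residue pair), CA–CA contacts within 4.0 Å, the mean
hydrogen-bond distance, paired hydrophilic residues (both members of
\{S,T,N,Q,Y,H,K,R,D,E\}; Cys and Trp are excluded as borderline) with any
heavy-atom pair within 4.0 Å, and the number of atoms in contact between
beta-2-microglobulin and the Fc. Two further features are deliberately
labelled surrogates: an interface hydrophobicity score (fraction of buried
area contributed by apolar atoms) and a binding-energy surrogate
(`−solvation gain + 0.5 × H-bond count`), standing in for opaque
crystallographic-suite outputs whose exact formulas are not public; their
absolute values should never be compared with those tools, only used as
covariates. A wide-cutoff (3.9 Å) hydrogen-bond count and an
atom-pair-resolved salt-bridge count fill the same role.

The default catalog is 21 Fc interface positions (EU 251–257, 285, 286,
288, 307–311, 314, 428, 433–436) × \{ASA, BSA, solvation\} = 63, plus 24
receptor-side residues × 3 = 72, plus the 12 complex-level features — 147
in total. The receptor-side list is rebuilt per reference complex by
ranking FcRn/B2M residues by buried area (always including FcRn position
129 when present), because the canonical published list is not available
as data; it ships as an editable catalog, not a hard-coded constant.

Cutoffs the literature leaves unstated (paired-hydrophilic, B2M–Fc atom
contacts) default to 4.0 Å, matching the other contact cutoffs, and are
arguments, not constants. The CA–CA cutoff of 4.0 Å is unusually tight for
backbone contacts; it is implemented as specified and configurable. The
mean hydrogen-bond distance is the mean donor–acceptor distance of the
counted bonds (not the spacing between bond midpoints, which is another
reading of the same phrase).

## Dataset curation

Affinity tables mix records measured at pH 7.0 (SPR, homogeneous
protocol) with records measured at pH 6.0 by less accurate assays. Since
log KD is close to linear in pH over 6.0–7.4, a single multiplicative
factor harmonizes them: the ratio of wild-type KD at the two pH values,
`8.8e-5 / 1.3e-6`, rounded to 68. pH 6 KDs are multiplied by the factor
and all responses become `log10(KD)` at pH 7 scale. Non-binder records
carry no usable KD and are excluded with a logged count.

Because only the catalog positions enter the features, two variants that
differ off-catalog (the classic pair: `S239K/T256E` vs `L235R/T256E`) have
identical feature vectors. Such effective-signature duplicates are removed
keeping the first occurrence (a geometric-mean-KD collapse is available
behind a flag). The first learning set (FLS) is the homogeneous pH 7 SPR
subset; the second (SLS) adds the harmonized pH 6 records; both are
deduplicated, and FLS ⊆ SLS by signature.

## Learning

Features are standardized to zero mean and unit variance; in
cross-validation the scaler is refitted on each training fold and applied
to the held-out fold, so held-out data never leak into standardization.
Constant columns are dropped with a warning. The four regressors use fixed
hyperparameters:

* **MLR** — ordinary least squares with intercept.
* **SVR** — radial-basis kernel, C = 1, epsilon-tube 0.1, tolerance 1e-3,
  gamma = 1/p.
* **RFR** — random forest with maximum tree depth 10, impurity importance,
  library defaults otherwise (500 trees).
* **MLP** — two hidden layers of 20 and 2 tanh units, linear output,
  squared loss with L2 penalty alpha = 20 on the weights, full-batch BFGS
  with analytic gradients, at most 4000 iterations, tolerance 1e-5, seeded
  Glorot initialization. It is implemented in the package because no
  installed R package provides a multi-hidden-layer perceptron regressor;
  the strong penalty intentionally limits overfitting at the cost of raw
  cross-validated fit.

Importance is model-appropriate: absolute standardized coefficients (MLR),
impurity importance (RFR), and seeded permutation importance — the mean
R-squared drop over 10 permutations — for SVR and MLP, floored at zero and
normalized to sum 1. Feature elimination repeatedly drops the
lowest-importance feature and accepts the drop while mean 10-fold CV
R-squared stays within a tolerance (default 0.01) of the *initial* model;
the first rejected drop stops the loop. Correlation pruning then drops,
from every pair with |Pearson r| at or above 0.9 (descending |r|, ties by
feature id), the member with lower importance. Both thresholds are
unstated in the source literature; 0.01 and 0.9 are conventional defaults
and are exposed as arguments. R-squared is the standard coefficient of
determination against the held-out fold mean and may be negative — the
expected outcome of the shuffled-label control, which permutes responses
(seeded) and reruns the same cross-validation.

## Synthetic data: what it emulates, and what it does not

Curated patent-derived Fc variant panels are proprietary and not publicly
deposited, so the package generates its own study conditions:

* **Toy complexes with planted geometry** for exact-count testing: short
  peptide chains in which each requested interaction (hydrogen bond, salt
  bridge, CA contact, hydrophilic pair, B2M contact) sits in its own
  14 Å slot at an exact stated distance, with every other cross-chain pair
  kept outside cutoff + 0.5 Å. The manifest bookkeeps cross-feature
  implications (a salt bridge within 3.5 Å is also a hydrogen bond; every
  salt bridge is a hydrophilic pair), so each manifest count is an exact
  oracle for the featurizer.
* **A synthetic reference complex**: the 21 Fc catalog positions with
  wild-type IgG1 identities on one backbone line, facing a 16-residue
  FcRn segment (author numbering 120–135, including 129) and an 8-residue
  B2M segment at a 7.5 Å backbone separation, side chains from the
  template tables. The separation was chosen once so that the wild-type
  complex has a genuine, modest interface (nonzero buried area, at least
  one hydrogen bond) and mutations perturb both per-residue areas and
  contact counts.
* **Variant/affinity tables**: unique variants with 1–5 mutations over
  the 21 positions (sizes uniform; the curated datasets allow up to 12 per
  variant, capped accordingly at parse time), responses
  `log10 KD = −7 + w · scaled(features) + N(0, 0.15)` with weights on
  surface areas of frequently mutated positions and one contact count,
  sized so the response spread (roughly 1.3 log units) resembles published
  variant panels. Seventeen percent of records are stored at pH 6.0 as
  `KD/68` (so curation must invert the encoding), five duplicate pairs are
  planted with off-catalog decoys (`S239K`/`L235R`), and three non-binder
  rows are appended. Defaults sit in `synthetic_truth()` and were fixed
  once as the package's study conditions.

The generator validates that every weighted feature actually varies in
the sampled design and fails loudly otherwise, rather than silently
generating an unlearnable truth.

What passing on this synthetic material shows: the geometry, curation and
learning machinery are internally correct, leakage-free, and can recover a
known generative model through the full mutate-featurize-standardize-fit
path. What it does not show: performance on real Fc/FcRn data — the
synthetic truth is (by default) linear in the features, the reference
geometry is idealized rather than crystallographic, measurement error is
Gaussian and homoscedastic, and the mutation distribution is uniform
rather than patent-biased. Cross-validated R-squared on the synthetic
tables should not be quoted as an estimate of real-data accuracy.

## Numerical choices and degenerate inputs

* SASA quadrature: 960 points, probe 1.4 Å; coincident atom centers are an
  error (degenerate geometry), as are non-positive probes and fewer than
  100 points. Contact detection adds a 1e-9 Å^2 slack on squared distances
  so pairs planted exactly at a cutoff are not lost to roundoff.
* BSA may be a tiny negative number of quadrature magnitude; it is
  reported as computed, not clipped.
* An epsilon-SVR trained on a constant response has no support vectors;
  prediction then falls back to the training mean, which lies inside the
  tube of every training point.
* Rotamer ties (all-clash-free isolated residues) resolve to the first
  scanned rotamer, chi ascending from −180 degrees.
* Altloc records resolve to the highest occupancy, ties alphabetically.
* Duplicate groups resolve keep-first by input order, making curation
  order-stable and idempotent.
* All stochastic steps (fold assignment, permutation importance, library
  sampling, table generation) take explicit integer seeds.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at
n = 500 variants with noise 0.15 log units, 10-fold cross-validation for
all four regressors, 20 Monte-Carlo SASA clusters at 10^5 samples per
atom, and 300/300/200-variant mut3/mut5/mut8 libraries — sizes chosen so
the whole suite completes in a few minutes on a single core while keeping
estimation error well inside the asserted tolerances.

## Known limitations

* The mutator never moves the backbone; strongly clashing mutations are
  placed at the least-bad rotamer rather than refined.
* Which copy of a crystallographic homodimer is mutated, and the
  chain-role assignment in general, must be pinned in configuration —
  nothing is inferred from the file.
* The two surrogate features are not comparable in absolute value to the
  crystallographic-suite quantities they stand in for.
* Only equilibrium KD is modeled; association/dissociation kinetics are
  out of scope.
* Insertion codes are not carried through residue identification; complexes
  relying on them need renumbering upstream.
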