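---
title: "Energy-feature SVM prediction of interface hot spots: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-feature SVM prediction of interface hot spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hspred)
```

## The problem and the model

Alanine-scanning mutagenesis replaces one residue at a time with alanine
and measures the change in binding free energy ΔΔG of a protein–protein
complex. Because alanine has no side chain beyond Cβ, each measurement
isolates the contribution of one side chain; residues with
ΔΔG ≥ 2 kcal/mol are the *hot spots* that dominate binding. `hspred`
predicts these labels from structure alone.

The model is deliberately physics-first: rather than learning from
sequence or generic descriptors, each candidate residue is described by
interaction energies that an alanine mutation would delete or perturb.
The complex is split, per candidate, into the mutated side chain (a), a
same-side environment shell (b), and a partner-side shell (c), both
shells taken within `shell_radius` of the candidate's Cβ. Four energy
terms are summed over a×c, b×c and a×b, giving 12 features. The b×c
("environment inter-molecular") term deliberately excludes the mutated
side chain, so it measures how well the *surrounding* interface would
hold together without that side chain — the a×c term carries the side
chain's own direct contribution.

A linear SVM is the classifier throughout: it is robust at the few
hundred labelled mutations realistically available, and its fitted model
reduces to an explicit weight per energy term plus a decision threshold,
which keeps the scoring function physically interpretable and trivially
serializable. A residue is called a hot spot when its score is strictly
greater than zero; a score of exactly zero is a non hot spot.

## Energy terms and their constants

All constants live in `energy_config()` so the functional forms can be
re-tuned without code changes. Units are Å and kcal/mol.

* **van der Waals**: 12-6 Lennard-Jones,
  $E = \epsilon_{ij}[(r_{min,ij}/r)^{12} - 2(r_{min,ij}/r)^6]$ with
  $\epsilon_{ij} = \sqrt{\epsilon_i\epsilon_j}$,
  $r_{min,ij} = r_{min,i} + r_{min,j}$, capped at +10 kcal/mol so a
  single modelled clash cannot dominate a feature.
* **Hydrogen bond**: a heavy-atom, distance-only 12-10 potential,
  $E = \epsilon_{hb}[5(r_0/r)^{12} - 6(r_0/r)^{10}]$ with
  $\epsilon_{hb} = 2$ kcal/mol, $r_0 = 2.9$ Å, active for
  $2.0 < r \le 3.5$ Å between a donor heavy atom and an acceptor. Both
  donor→acceptor orientations of a pair are summed. No angular weighting
  is applied: the package works on heavy atoms only and never places
  hydrogens.
* **Coulomb**: $E = 332.0637\, q_iq_j / (\epsilon(r)\, r)$ with the
  distance-dependent dielectric $\epsilon(r) = 4r$, the standard implicit
  screening choice for heavy-atom models.
* **Desolvation**: a symmetric EEF1-style Gaussian solvent-exclusion
  term, $E = -f(i,j) - f(j,i)$ with
  $f(i,j) = \frac{\Delta G^{free}_i}{2\pi^{3/2}\lambda_i r^2}
  e^{-((r-r_{min,i})/\lambda_i)^2}V_j$, cut off at 9 Å. Burying
  hydrophobic carbons is favourable (positive $\Delta G^{free}$),
  burying polar atoms costs energy.

No extra pair cutoff is applied to the first three terms — the regions
are already spatially bounded by the shell.

Atom parameters (vdW radii and well depths, simplified partial charges
on polar and charged groups, EEF1-style solvation parameters, and
donor/acceptor flags) are a bundled whitespace-delimited table
(`inst/extdata/atom_params.tsv`), one row per (residue, atom), with
element-based fallback rows for unrecognised names. It is a simplified
parameter set, chosen for robustness rather than thermodynamic fidelity;
users can pass a replacement table of the same shape.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `shell_radius` | 10.0 | Å | radius of regions (b) and (c) around the Cβ |
| `contact_cutoff` | 5.0 | Å | heavy-atom distance defining interface residues |
| `ddg_threshold` | 2.0 | kcal/mol | hot-spot label threshold (inclusive, ≥) |
| `r_min` | 0.2 | — | correlation floor of the baseline feature filter |
| `r_max` | 0.8 | — | redundancy bound excluding feature pairs from subsets |
| `C_grid` | 0.01…100 | — | SVM soft-margin costs searched in the inner loop |
| `class_weight_grid` | 1, 2, 5 | — | extra cost for missed hot spots (minority class) |

The interface definition and the shell radius are genuinely open design
choices — there is no community-standard numeric definition of "at the
interface" — and both are therefore configuration, with defaults in the
range structural studies commonly use (4–6 Å contacts, 8–12 Å
environment shells). The hot-spot threshold of 2 kcal/mol follows the
established alanine-scanning convention, with the boundary counted as a
hot spot. Candidate sites exclude Gly and Pro (no comparable side chain;
backbone-constrained) and Ala itself; residues missing their Cβ or more
than two side-chain heavy atoms are skipped with a warning rather than
imputed, since imputation would fabricate the very energies being
measured.

## Specialist classifiers and feature selection

The general model uses every feature whose absolute Pearson correlation
with measured ΔΔG exceeds `r_min`. Arginine and glutamic acid get
specialist models because their energetics are systematically atypical
(long, charged side chains; strong electrostatic compensation). With only
a few dozen Arg/Glu mutations in a realistic training set, fitting
separate models *on those rows only* would overfit immediately. The
design here instead trains every candidate on **all** mutations and lets
the target amino acid enter only through model choice: all subsets of
size 3 or 4 of the baseline features are enumerated (excluding pairs
correlated above `r_max`, which would be redundant; Arg candidates may
additionally include the intra-molecular Coulomb term), each candidate's
hyper-parameters are grid-searched by pooled inner-CV F1 over all
mutations, and the candidate whose pooled inner predictions score the
best F1 *on the target amino acid* wins. Ties break to the smaller, then
the earlier subset in canonical order, which keeps selection
deterministic.

Per-amino-acid F1 is computed on inner-CV predictions pooled across
folds rather than averaged per fold: with only a handful of target-type
rows per fold, per-fold F1 is frequently degenerate (zero denominators)
and averaging it is noisy; pooling is stabler.

## Cross-validation hygiene

Homologous complexes share interface architecture, so random row-level
splits leak information. Folds are therefore built over *homology
clusters* (an input column, `cluster_id`): clusters are shuffled by seed
and dealt round-robin into outer folds (default: leave-one-cluster-out),
and inner folds are built the same way within each outer-training set.
Standardization, the correlation filter, the subset search and the
hyper-parameter grid are all re-fit per outer fold on training clusters
only. `nested_cv()` records, per fold, every training row index touched
and the held-out rows, and the test suite asserts their disjointness; a
planted label-leak sentinel feature reaches F1 = 1 only through genuine
outer-test scoring.

The specialist set defaults to {Arg, Glu}. An automatic weak-amino-acid
detector (flagging amino acids whose training-set F1 under the general
model falls below a floor) would comply with the same hygiene, but the
shipped default hard-codes the two established weak types to keep the
ensemble's behaviour predictable.

## What the synthetic generators emulate — and what they do not

`generate_feature_dataset()` draws the 12 features from a seeded
multivariate normal, produces ΔΔG = 1.5·(w*·x − b) + ε kcal/mol from a
known weight vector, labels at the 2 kcal/mol threshold, flips labels at
a 5% noise rate, and deals rows round-robin into 8 clusters. The default
weights are negative on six interaction-energy features (favourable
energies mark hot spots) and sized to give a hot-spot prevalence of
roughly 20–25%, the minority-class regime of real alanine-scanning
compilations; `n = 500` rows approximates the scale of curated mutation
datasets. A per-amino-acid weight override can plant divergent
energetics (e.g. Glu rows driven by hydrogen-bond terms), which is how
the specialist-vs-general contrast is exercised.

`generate_toy_complex()` builds two idealized chains on parallel axes
and aims the side chains of designated residues across the gap so their
tips come within 4 Å of the partner — a guaranteed, known interface
contact. Geometries are deliberately *not* physical beyond what the
energy terms need: planted side-chain bonds stretch to bridge the gap,
there is no packing, no secondary structure and no relaxation.
Consequently, passing tests demonstrate correctness of the machinery
(parsing, region partitioning, energy summation, training, routing,
fold hygiene) and qualitative behaviours (planted contacts rank first;
specialists help where energetics diverge) — they do not certify
predictive accuracy on real crystal structures, which depends on the
energy parameterization in ways toy geometry cannot probe.

## Numerical choices and degenerate inputs

* Zero interatomic distance is a hard error (duplicate atoms), not a
  capped energy.
* Constant feature columns standardize to themselves with a warning
  (division by zero sd would poison the SVM).
* Metric conventions: precision, recall, F1 and MCC are defined as 0
  whenever their denominator vanishes, keeping small per-amino-acid
  strata well defined.
* libsvm orients decision values by the first label it encounters; the
  wrapper re-orients weights so positive scores always mean hot spot.
* Grid-search and selection ties break deterministically (first grid
  point, smaller subset, enumeration order), so a fixed seed gives
  byte-identical reports.
* Scores are computed from the serialized weight vector and stored
  standardization statistics; the training backend is never needed at
  prediction time, and round-tripping a model through its weight table
  reproduces backend decision values to well under 1e-6.

## Problem sizes

The shipped tests and the acceptance script run the nested CV at
n = 400–500 rows with 8 clusters and a reduced grid
(C ∈ {0.1, 1, 10}, class weight ∈ {1, 2}); these sizes give stable
estimates for the synthetic conditions while keeping a full run in the
low minutes on one core. The defaults (`training_config()`) retain the
wider grid for real-data use.

## Known limitations

* Heavy-atom model: no hydrogens, hence no angular hydrogen-bond
  geometry; aromatic and weak C–H···O bonds are ignored.
* No side-chain repacking or relaxation after the in-silico mutation —
  energies are computed on the wild-type conformation.
* The bundled atom parameters are simplified; absolute energies should
  not be interpreted thermodynamically, only as classifier features.
* Homology clustering is an input, not computed: the package trusts the
  user's `cluster_id` assignments.
* mmCIF input, NMR ensembles and missing-side-chain reconstruction are
  out of scope; only the first model of a multi-model PDB file is read.
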