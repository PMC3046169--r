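# hspred: hot spot residue prediction at protein–protein interfaces

Protein–protein interactions usually depend on a handful of interface
residues — *hot spots* — whose mutation to alanine raises the binding free
energy substantially (conventionally ΔΔG ≥ 2 kcal/mol). Mapping them
experimentally by alanine-scanning mutagenesis is slow and expensive;
`hspred` predicts them computationally from the structure of a complex.
It is aimed at structural biologists and method developers who want a
fully scriptable, offline re-implementation of the energy-feature +
linear-SVM approach to computational alanine scanning, complete with a
synthetic-data module so every stage can be exercised without downloading
structures.

## The method

For every candidate interface residue (any non-Gly/Pro/Ala residue with a
heavy atom within 5 Å of the partner protein), the complex is partitioned
into three regions around the residue's Cβ:

* **(a)** the mutated side chain — the heavy atoms beyond Cβ, i.e. exactly
  what an alanine mutation removes;
* **(b)** same-side atoms within a 10 Å shell of the Cβ (excluding the
  residue's own atoms);
* **(c)** partner-side atoms within the same shell.

Four pairwise molecular-mechanics energy terms — a 12-6 Lennard-Jones
potential, a distance-only 12-10 hydrogen-bond potential, Coulomb
electrostatics with a distance-dependent dielectric ε(r) = 4r, and an
EEF1-style Gaussian solvent-exclusion desolvation term — are summed over
the three region pairings (a×c *side-chain inter-molecular*, b×c
*environment inter-molecular*, a×b *side-chain intra-molecular*), giving a
12-component energy vector per residue.

A linear soft-margin SVM turns standardized features into a score
s(x) = Σₖ wₖxₖ − b; residues with s > 0 are called hot spots. Three
classifiers form the ensemble:

* **SVM_X**, the general model, trained on the features whose absolute
  Pearson correlation with measured ΔΔG exceeds 0.2;
* **SVM_R** and **SVM_E**, specialists for arginine and glutamic acid —
  the amino acids general models historically handle worst. Each is
  trained on *all* mutations but uses a feature subset (3 or 4 features,
  excluding mutually redundant pairs with |r| > 0.8; Arg candidates may
  add the intra-molecular Coulomb term) chosen to maximize inner-CV F1 on
  the target amino acid.

Performance is estimated by nested cross-validation in which homology
clusters of complexes are never split across train and test, and both the
hyper-parameter grid and the specialist subset search run strictly inside
the inner loop. Reported measures are precision P = TP/(TP+FP), recall
R = TP/(TP+FN), their harmonic mean F1, and the Matthews correlation
coefficient.

## Worked example

Train an ensemble on a synthetic labelled dataset, then scan a toy
complex with a planted interface contact:

```r
library(hspred)

ds  <- generate_feature_dataset(synthetic_feature_spec(n = 400, seed = 7))
fit <- hspred(ds$table, training_config(C_grid = c(0.1, 1, 10),
                                        class_weight_grid = c(1, 2), seed = 7))
fit
#> Hot-spot prediction ensemble
#>   general model: 5 features {vdw_sc_inter, hbond_sc_inter, desolv_sc_inter, vdw_env_inter, hbond_env_inter}
#>   R specialist: {vdw_sc_inter, hbond_sc_inter, desolv_sc_inter, vdw_env_inter}
#>   E specialist: {vdw_sc_inter, hbond_sc_inter, desolv_sc_inter, hbond_env_inter}

round(coef(fit)[c(fit$model_X$feature_ids, "threshold"), ], 3)
#>                  SVM_X  SVM_R  SVM_E
#> vdw_sc_inter    -1.274 -1.279 -1.234
#> hbond_sc_inter  -0.756 -0.761 -0.676
#> desolv_sc_inter -0.519 -0.419 -0.541
#> vdw_env_inter   -0.603 -0.620     NA
#> hbond_env_inter -0.417     NA -0.409
#> threshold        1.565  1.499  1.384

tc <- generate_toy_complex(toy_complex_spec("KSELWSNQT", "DSYKLSTRN",
                                            planted1 = 5, seed = 3))
cx <- read_complex(tc$pdb, "A", "B")
predict_complex(fit, cx)
#>   chain resnum wt_aa      score hotspot_call
#> 1     A      5     W  0.1300432            1
#> 2     B      4     K -0.6698510           -1
#> 3     B      5     L -0.9149457           -1
#> 4     B      6     S -0.6098123           -1
```

The weights are negative because favourable (more negative) interaction
energies mark hot spots; the planted tryptophan at A5 — the only residue
whose side chain packs across the interface — is the one predicted hot
spot and tops the score ranking. On real structures the same call is
`read_complex("complex.pdb", side1 = "A", side2 = "B")` followed by
`predict_complex()`, or the bundled command line:

```sh
Rscript inst/cli/hspred predict --pdb complex.pdb --side1 A --side2 B \
    --model model_dir --out predictions.tsv
```

with `train`, `cv` and `synth` subcommands covering the rest of the
pipeline.

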