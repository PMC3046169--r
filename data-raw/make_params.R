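# Generates inst/extdata/atom_params.tsv: one row per (residue, atom) with
# CHARMM-like vdW parameters, simplified partial charges on polar/charged
# groups, and EEF1-style Gaussian solvent-exclusion parameters.
# Run from repo root: Rscript data-raw/make_params.R

source("R/topology.R")

# atom classes: rmin (A, per-atom, rmin_ij = rmin_i + rmin_j), eps (kcal/mol),
# dG_free (kcal/mol), lambda (A), volume (A^3)
classes <- list(
  CH3 = c(2.06, 0.078, 1.50, 3.5, 23.7),
  CH2 = c(2.01, 0.055, 0.52, 3.5, 22.4),
  CH1 = c(2.28, 0.032, -0.19, 3.5, 14.7),
  CR  = c(1.99, 0.070, 0.08, 3.5, 18.4),   # aromatic CH
  C   = c(2.00, 0.110, 0.00, 3.5, 14.7),   # carbonyl / guanidinium / carboxyl C
  NH1 = c(1.85, 0.200, -5.95, 3.5, 11.2),  # amide / ring NH
  NH2 = c(1.85, 0.200, -5.45, 3.5, 11.2),
  NR  = c(1.85, 0.200, -4.00, 3.5, 4.4),   # ring N acceptor
  NC  = c(1.85, 0.200, -20.00, 6.0, 11.2), # charged N (Lys NZ, Arg NE/NH)
  O   = c(1.70, 0.120, -5.33, 3.5, 10.8),  # carbonyl O
  OH  = c(1.77, 0.152, -5.92, 3.5, 10.8),
  OC  = c(1.70, 0.120, -10.00, 6.0, 10.8), # carboxylate O
  S   = c(2.00, 0.450, -3.24, 3.5, 14.7)
)

# backbone (all residues): name -> c(class, charge, donor, acceptor)
backbone <- list(
  N  = list("NH1", -0.40, TRUE,  FALSE),
  CA = list("CH1",  0.40, FALSE, FALSE),
  C  = list("C",    0.55, FALSE, FALSE),
  O  = list("O",   -0.55, FALSE, TRUE),
  CB = list("CH2",  0.00, FALSE, FALSE)
)

# side-chain atom assignments per residue
sc <- list(
  ALA = list(),
  ARG = list(CG = list("CH2", 0), CD = list("CH2", 0.20),
             NE = list("NC", -0.20, TRUE, FALSE), CZ = list("C", 0.50),
             NH1 = list("NC", 0.25, TRUE, FALSE),
             NH2 = list("NC", 0.25, TRUE, FALSE)),
  ASN = list(CG = list("C", 0.95), OD1 = list("O", -0.55, FALSE, TRUE),
             ND2 = list("NH2", -0.40, TRUE, FALSE)),
  ASP = list(CG = list("C", 0.50), OD1 = list("OC", -0.75, FALSE, TRUE),
             OD2 = list("OC", -0.75, FALSE, TRUE)),
  CYS = list(SG = list("S", -0.23, TRUE, FALSE)),
  GLN = list(CG = list("CH2", 0), CD = list("C", 0.95),
             OE1 = list("O", -0.55, FALSE, TRUE),
             NE2 = list("NH2", -0.40, TRUE, FALSE)),
  GLU = list(CG = list("CH2", 0), CD = list("C", 0.50),
             OE1 = list("OC", -0.75, FALSE, TRUE),
             OE2 = list("OC", -0.75, FALSE, TRUE)),
  GLY = list(),
  HIS = list(CG = list("CR", 0), ND1 = list("NR", -0.36, TRUE, TRUE),
             CD2 = list("CR", 0.36), CE1 = list("CR", 0.36),
             NE2 = list("NR", -0.36, TRUE, TRUE)),
  ILE = list(CG1 = list("CH2", 0), CG2 = list("CH3", 0),
             CD1 = list("CH3", 0)),
  LEU = list(CG = list("CH1", 0), CD1 = list("CH3", 0),
             CD2 = list("CH3", 0)),
  LYS = list(CG = list("CH2", 0), CD = list("CH2", 0),
             CE = list("CH2", 0), NZ = list("NC", 1.00, TRUE, FALSE)),
  MET = list(CG = list("CH2", 0.05), SD = list("S", -0.10, FALSE, FALSE),
             CE = list("CH3", 0.05)),
  PHE = list(CG = list("CR", 0), CD1 = list("CR", 0), CD2 = list("CR", 0),
             CE1 = list("CR", 0), CE2 = list("CR", 0), CZ = list("CR", 0)),
  PRO = list(CG = list("CH2", 0), CD = list("CH2", 0)),
  SER = list(OG = list("OH", -0.54, TRUE, TRUE)),
  THR = list(OG1 = list("OH", -0.54, TRUE, TRUE), CG2 = list("CH3", 0)),
  TRP = list(CG = list("CR", 0), CD1 = list("CR", 0.35),
             CD2 = list("CR", 0), NE1 = list("NH1", -0.35, TRUE, FALSE),
             CE2 = list("CR", 0), CE3 = list("CR", 0), CZ2 = list("CR", 0),
             CZ3 = list("CR", 0), CH2 = list("CR", 0)),
  TYR = list(CG = list("CR", 0), CD1 = list("CR", 0), CD2 = list("CR", 0),
             CE1 = list("CR", 0), CE2 = list("CR", 0),
             CZ = list("CR", 0.54), OH = list("OH", -0.54, TRUE, TRUE)),
  VAL = list(CG1 = list("CH3", 0), CG2 = list("CH3", 0))
)

rows <- list()
add_row <- function(res, atom, cls, charge, donor = FALSE, acceptor = FALSE) {
  p <- classes[[cls]]
  rows[[length(rows) + 1]] <<- data.frame(
    residue = res, atom = atom, vdw_rmin = p[1], vdw_epsilon = p[2],
    partial_charge = charge, solv_dG_free = p[3], solv_lambda = p[4],
    solv_volume = p[5], is_donor_heavy = as.integer(donor),
    is_acceptor = as.integer(acceptor))
}

for (res in .aa3) {
  for (atom in names(backbone)) {
    if (res == "GLY" && atom == "CB") next
    # Pro backbone N has no H: not a donor
    b <- backbone[[atom]]
    donor <- b[[3]] && !(res == "PRO" && atom == "N")
    add_row(res, atom, b[[1]], b[[2]], donor, b[[4]])
  }
  # Ala CB is a methyl, Thr/Val/Ile CB are CH1
  for (atom in names(sc[[res]])) {
    a <- sc[[res]][[atom]]
    add_row(res, atom, a[[1]], a[[2]],
            if (length(a) >= 3) a[[3]] else FALSE,
            if (length(a) >= 4) a[[4]] else FALSE)
  }
}

# element fallbacks for unknown (residue, atom) combinations; residue "*"
fallback <- list(C = list("CH2", 0), N = list("NH1", 0, TRUE, FALSE),
                 O = list("O", 0, FALSE, TRUE), S = list("S", 0))
for (el in names(fallback)) {
  f <- fallback[[el]]
  add_row("*", el, f[[1]], f[[2]],
          if (length(f) >= 3) f[[3]] else FALSE,
          if (length(f) >= 4) f[[4]] else FALSE)
}

tab <- do.call(rbind, rows)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
con <- file("inst/extdata/atom_params.tsv", "w")
writeLines(c(
  "# Atom physics parameters: CHARMM-like 12-6 vdW (rmin is per-atom,",
  "# rmin_ij = rmin_i + rmin_j), simplified partial charges on polar and",
  "# charged groups, EEF1-style Gaussian solvent-exclusion parameters.",
  "# Units: A, kcal/mol, elementary charges, A^3. Rows with residue '*'",
  "# are element-based fallbacks for unrecognised atom names."), con)
write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)
cat("wrote", nrow(tab), "rows\n")
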