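# Standard heavy-atom topology of the 20 amino acids.
# Backbone is N, CA, C, O; CB present for all but Gly. "Side chain" here
# always means the heavy atoms beyond CB -- the atoms an alanine mutation
# removes.

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W",
          "Y", "V")

.sidechain_atoms <- list(
  ALA = character(0),
  ARG = c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CG", "OD1", "ND2"),
  ASP = c("CG", "OD1", "OD2"),
  CYS = "SG",
  GLN = c("CG", "CD", "OE1", "NE2"),
  GLU = c("CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CG1", "CG2", "CD1"),
  LEU = c("CG", "CD1", "CD2"),
  LYS = c("CG", "CD", "CE", "NZ"),
  MET = c("CG", "SD", "CE"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CG", "CD"),
  SER = "OG",
  THR = c("OG1", "CG2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CG1", "CG2")
)

#' Convert between 3-letter and 1-letter amino-acid codes
#'
#' @param x Character vector of codes.
#' @return Character vector of converted codes; NA for unknown codes.
#' @export
aa_three_to_one <- function(x) .aa1[match(toupper(x), .aa3)]

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) .aa3[match(toupper(x), .aa1)]

#' Heavy side-chain atom names beyond C-beta
#'
#' @param resname 3-letter residue code.
#' @return Character vector of atom names (empty for Ala/Gly).
#' @export
sidechain_atom_names <- function(resname) {
  resname <- toupper(resname)
  if (!resname %in% .aa3) stop("unknown residue name: ", resname)
  .sidechain_atoms[[resname]]
}

#' Full heavy-atom set of a residue
#'
#' @param resname 3-letter residue code.
#' @return Character vector: backbone (+CB except Gly) plus side chain.
#' @export
residue_atom_names <- function(resname) {
  resname <- toupper(resname)
  bb <- c("N", "CA", "C", "O")
  if (resname != "GLY") bb <- c(bb, "CB")
  c(bb, sidechain_atom_names(resname))
}

#' Mutable amino-acid codes
#'
#' The 17 amino acids that are candidates for alanine mutation: Ala itself
#' has nothing to mutate, Gly has no C-beta, Pro is conformationally
#' constrained; all three are excluded.
#'
#' @return Character vector of 17 one-letter codes.
#' @export
mutable_amino_acids <- function() setdiff(.aa1, c("A", "G", "P"))
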