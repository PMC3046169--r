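#' Load an atom physics parameter table
#'
#' Reads a whitespace-delimited table with one row per (residue, atom) and
#' columns \code{residue, atom, vdw_rmin, vdw_epsilon, partial_charge,
#' solv_dG_free, solv_lambda, solv_volume, is_donor_heavy, is_acceptor}.
#' Rows with residue \code{"*"} are element-based fallbacks used (with a
#' warning) for atom names not present in the table. The bundled default is
#' a simplified CHARMM-like / EEF1-style set; users can supply their own.
#'
#' @param path Path to the table; default the bundled set.
#' @return data.frame of parameters.
#' @export
load_atom_parameters <- function(path = system.file("extdata",
                                                    "atom_params.tsv",
                                                    package = "hspred")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("residue", "atom", "vdw_rmin", "vdw_epsilon", "partial_charge",
            "solv_dG_free", "solv_lambda", "solv_volume", "is_donor_heavy",
            "is_acceptor")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("parameter table missing columns: ",
                         paste(miss, collapse = ", "))
  stopifnot(all(tab$vdw_rmin > 0), all(tab$vdw_epsilon >= 0),
            all(tab$solv_lambda > 0), all(tab$solv_volume >= 0))
  tab
}

# guess the element from a PDB atom name (heavy atoms only)
.element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  el <- substr(nm, 1, 1)
  el[substr(nm, 1, 2) %in% c("CL", "BR", "FE", "ZN", "MG", "SE")] <-
    substr(nm, 1, 2)[substr(nm, 1, 2) %in% c("CL", "BR", "FE", "ZN", "MG", "SE")]
  el
}

#' Read a two-sided protein-protein complex from PDB text
#'
#' Parses a PDB file (first model only; altloc 'A' or blank kept; HETATM and
#' waters dropped; hydrogens removed), restricts to the chains named in the
#' two sides, and assigns per-atom physics parameters from the parameter
#' table. Atom names absent from the table receive element-based fallback
#' parameters with a warning.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param side1,side2 Character vectors of chain identifiers defining the
#'   two sides of the interface. Must be disjoint and all present.
#' @param params Atom parameter table from \code{\link{load_atom_parameters}}.
#' @return An object of class \code{hspred_complex}: a list with
#'   \code{atoms} (data.frame of parameterized heavy atoms; one row per
#'   atom with coordinates, residue identity, side label and physics
#'   parameters), \code{side1}, \code{side2}.
#' @export
read_complex <- function(pdb, side1, side2,
                         params = load_atom_parameters()) {
  side1 <- unique(as.character(side1))
  side2 <- unique(as.character(side2))
  both <- intersect(side1, side2)
  if (length(both))
    stop("chain(s) on both sides: ", paste(both, collapse = ", "))
  if (is.character(pdb) && length(pdb) > 1 ||
      (length(pdb) == 1 && grepl("\n", pdb))) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), tmp)
    on.exit(unlink(tmp))
    pdb <- tmp
  }
  p <- suppressWarnings(bio3d::read.pdb(pdb, multi = FALSE, rm.alt = TRUE,
                                        verbose = FALSE))
  at <- p$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  have <- unique(at$chain)
  for (ch in c(side1, side2))
    if (!ch %in% have) stop("chain ", ch, " not found")
  at <- at[at$chain %in% c(side1, side2), , drop = FALSE]
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- .element_from_name(at$elety[bad])
  keep <- toupper(elem) != "H" & at$resid != "HOH"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0) stop("no heavy atoms left after filtering")

  ins <- at$insert
  ins[is.na(ins)] <- ""
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = toupper(elem),
    resname = at$resid, chain = at$chain,
    resno = paste0(at$resno, ins), resno_num = at$resno,
    x = at$x, y = at$y, z = at$z,
    side = ifelse(at$chain %in% side1, 1L, 2L),
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in PDB input")

  key <- paste(atoms$resname, atoms$name)
  idx <- match(key, paste(params$residue, params$atom))
  unknown <- is.na(idx)
  if (any(unknown)) {
    fb <- match(paste("*", atoms$element[unknown]),
                paste(params$residue, params$atom))
    still <- is.na(fb)
    if (any(still)) {
      # last resort: treat as generic carbon
      fb[still] <- match("* C", paste(params$residue, params$atom))
    }
    idx[unknown] <- fb
    warning(sum(unknown), " atom(s) without specific parameters; ",
            "element-based fallback used (e.g. ",
            paste(utils::head(unique(key[unknown]), 3), collapse = ", "),
            ")")
  }
  pc <- params[idx, c("vdw_rmin", "vdw_epsilon", "partial_charge",
                      "solv_dG_free", "solv_lambda", "solv_volume",
                      "is_donor_heavy", "is_acceptor")]
  rownames(pc) <- NULL
  atoms <- cbind(atoms, pc)
  atoms$is_donor_heavy <- atoms$is_donor_heavy > 0
  atoms$is_acceptor <- atoms$is_acceptor > 0
  structure(list(atoms = atoms, side1 = side1, side2 = side2),
            class = "hspred_complex")
}

#' @export
print.hspred_complex <- function(x, ...) {
  cat("Protein-protein complex:", nrow(x$atoms), "heavy atoms\n")
  cat("  side 1: chain(s)", paste(x$side1, collapse = ", "),
      sprintf("(%d atoms)\n", sum(x$atoms$side == 1L)))
  cat("  side 2: chain(s)", paste(x$side2, collapse = ", "),
      sprintf("(%d atoms)\n", sum(x$atoms$side == 2L)))
  invisible(x)
}

# residue-level index: unique (chain, resno) keys in file order
.residue_keys <- function(atoms) unique(paste(atoms$chain, atoms$resno))

#' Identify candidate interface residues
#'
#' A residue is at the interface when at least one of its heavy atoms lies
#' within \code{contact_cutoff} of a heavy atom on the other side. Gly, Pro
#' and Ala are excluded (they cannot be meaningfully alanine-mutated), as
#' are residues with a missing C-beta or more than two missing side-chain
#' heavy atoms (skipped with a warning rather than imputed).
#'
#' @param complex \code{hspred_complex}.
#' @param contact_cutoff Heavy-atom contact distance, Angstrom.
#' @return data.frame with one row per candidate site: \code{chain},
#'   \code{resno} (PDB numbering, insertion code appended), \code{resname},
#'   \code{wt} (1-letter code), \code{cbx, cby, cbz} (C-beta coordinates),
#'   sorted by chain then residue number.
#' @export
find_interface_residues <- function(complex,
                                    contact_cutoff = energy_config()$contact_cutoff) {
  stopifnot(inherits(complex, "hspred_complex"), contact_cutoff > 0)
  a <- complex$atoms
  x1 <- as.matrix(a[a$side == 1L, c("x", "y", "z")])
  x2 <- as.matrix(a[a$side == 2L, c("x", "y", "z")])
  if (nrow(x1) == 0 || nrow(x2) == 0) return(.empty_sites())
  d2 <- .cross_dist2(x1, x2)
  cut2 <- contact_cutoff^2
  contact1 <- which(apply(d2 <= cut2, 1, any))
  contact2 <- which(apply(d2 <= cut2, 2, any))
  keys <- c(paste(a$chain, a$resno)[a$side == 1L][contact1],
            paste(a$chain, a$resno)[a$side == 2L][contact2])
  keys <- unique(keys)
  .sites_from_keys(complex, keys)
}

.empty_sites <- function() {
  data.frame(chain = character(0), resno = character(0),
             resname = character(0), wt = character(0),
             cbx = numeric(0), cby = numeric(0), cbz = numeric(0),
             stringsAsFactors = FALSE)
}

# build the candidate-site table for given "chain resno" keys, applying the
# mutability and completeness filters
.sites_from_keys <- function(complex, keys) {
  a <- complex$atoms
  akey <- paste(a$chain, a$resno)
  out <- list()
  skipped <- character(0)
  for (k in keys) {
    rows <- a[akey == k, , drop = FALSE]
    resname <- rows$resname[1]
    if (resname %in% c("GLY", "PRO", "ALA")) next
    if (!resname %in% .aa3) next
    cb <- rows[rows$name == "CB", , drop = FALSE]
    expected <- sidechain_atom_names(resname)
    n_missing <- length(setdiff(expected, rows$name))
    if (nrow(cb) == 0 || n_missing > 2) {
      skipped <- c(skipped, k)
      next
    }
    out[[k]] <- data.frame(
      chain = rows$chain[1], resno = rows$resno[1], resname = resname,
      wt = aa_three_to_one(resname),
      cbx = cb$x[1], cby = cb$y[1], cbz = cb$z[1],
      resno_num = rows$resno_num[1], stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped incomplete residue(s): ",
            paste(skipped, collapse = ", "))
  if (!length(out)) return(.empty_sites())
  s <- do.call(rbind, out)
  s <- s[order(s$chain, s$resno_num, s$resno), , drop = FALSE]
  rownames(s) <- NULL
  s[, c("chain", "resno", "resname", "wt", "cbx", "cby", "cbz")]
}

# squared distances between two coordinate matrices (n1 x 3, n2 x 3)
.cross_dist2 <- function(x1, x2) {
  outer(rowSums(x1^2), rep(1, nrow(x2))) +
    outer(rep(1, nrow(x1)), rowSums(x2^2)) - 2 * tcrossprod(x1, x2)
}

#' Side-chain atoms removed by an alanine mutation
#'
#' Returns the row indices (into \code{complex$atoms}) of the residue's
#' heavy atoms beyond C-beta, i.e. excluding N, CA, C, O and CB.
#'
#' @param complex \code{hspred_complex}.
#' @param chain,resno Residue identity (resno as character, insertion code
#'   appended, or numeric).
#' @return Integer vector of atom row indices (possibly empty).
#' @export
side_chain_atoms <- function(complex, chain, resno) {
  a <- complex$atoms
  sel <- a$chain == chain & a$resno == as.character(resno)
  if (!any(sel)) stop("residue ", chain, " ", resno, " not found")
  which(sel & !a$name %in% c("N", "CA", "C", "O", "CB"))
}
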