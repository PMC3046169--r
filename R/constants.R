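#' Canonical energy feature names
#'
#' The 12 per-residue energy features: four pairwise energy terms (van der
#' Waals, hydrogen bond, Coulomb electrostatics, desolvation) evaluated over
#' three region pairings around the candidate residue:
#' \describe{
#'   \item{sc_inter}{mutated side chain (a) vs. partner-side shell (c)}
#'   \item{env_inter}{same-side shell (b) vs. partner-side shell (c)}
#'   \item{sc_intra}{mutated side chain (a) vs. same-side shell (b)}
#' }
#' Order is pairing-major, term-minor; all downstream tables, weight vectors
#' and subset enumerations use this canonical order.
#'
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  terms <- c("vdw", "hbond", "coulomb", "desolv")
  pairings <- c("sc_inter", "env_inter", "sc_intra")
  as.vector(vapply(pairings, function(p) paste(terms, p, sep = "_"),
                   character(4)))
}

#' Energy-model configuration
#'
#' All constants of the pairwise energy model live here so functional forms
#' can be re-tuned without code changes. Units: kcal/mol and Angstrom.
#'
#' @param shell_radius Shell radius around the candidate residue's C-beta
#'   defining regions (b) and (c), Angstrom.
#' @param contact_cutoff Heavy-atom distance defining interface contact,
#'   Angstrom.
#' @param lj_cap Clash cap on the 12-6 Lennard-Jones term, kcal/mol.
#' @param hb_eps Hydrogen-bond well depth, kcal/mol.
#' @param hb_r0 Hydrogen-bond optimal heavy-atom distance, Angstrom.
#' @param hb_rmin,hb_rmax Hydrogen bonds contribute only for
#'   \code{hb_rmin < r <= hb_rmax}.
#' @param coulomb_k Electrostatic conversion constant, kcal*A/(mol*e^2).
#' @param dielectric_slope Distance-dependent dielectric: eps(r) = slope * r.
#' @param desolv_cutoff Gaussian solvent-exclusion cutoff, Angstrom.
#'
#' @return Named list of constants.
#' @export
energy_config <- function(shell_radius = 10.0,
                          contact_cutoff = 5.0,
                          lj_cap = 10.0,
                          hb_eps = 2.0,
                          hb_r0 = 2.9,
                          hb_rmin = 2.0,
                          hb_rmax = 3.5,
                          coulomb_k = 332.0637,
                          dielectric_slope = 4.0,
                          desolv_cutoff = 9.0) {
  stopifnot(shell_radius > 0, contact_cutoff > 0, hb_r0 > 0,
            dielectric_slope > 0, desolv_cutoff > 0)
  list(shell_radius = shell_radius, contact_cutoff = contact_cutoff,
       lj_cap = lj_cap, hb_eps = hb_eps, hb_r0 = hb_r0,
       hb_rmin = hb_rmin, hb_rmax = hb_rmax, coulomb_k = coulomb_k,
       dielectric_slope = dielectric_slope, desolv_cutoff = desolv_cutoff)
}

# run RNG-dependent code under a temporary seed, restoring global state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
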