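# Pairwise energy terms and the three-region decomposition around a
# candidate residue. All energies in kcal/mol, distances in Angstrom.
# Heavy-atom model throughout: hydrogen bonds are scored on donor/acceptor
# heavy-atom distance, with no angular weighting.

#' Partition atoms into the three structural regions around a site
#'
#' For a candidate residue the complex decomposes into: (a) the mutated
#' side chain (heavy atoms beyond C-beta); (b) same-side atoms within
#' \code{shell_radius} of the site's C-beta, excluding (a) and the site's
#' own backbone and C-beta; (c) partner-side atoms within the shell.
#'
#' @param complex \code{hspred_complex}.
#' @param site One row of the table from \code{\link{find_interface_residues}}
#'   (or any list with \code{chain}, \code{resno}, \code{cbx,cby,cbz}).
#' @param shell_radius Shell radius, Angstrom.
#' @return List with integer atom-row indices \code{a}, \code{b}, \code{c}
#'   and the \code{shell_radius} used.
#' @export
partition_regions <- function(complex, site,
                              shell_radius = energy_config()$shell_radius) {
  stopifnot(inherits(complex, "hspred_complex"), shell_radius > 0)
  at <- complex$atoms
  if (is.null(site$cbx) || !is.finite(site$cbx))
    stop("site has no C-beta coordinates")
  cb <- c(site$cbx, site$cby, site$cbz)
  own <- at$chain == site$chain & at$resno == as.character(site$resno)
  if (!any(own)) stop("residue ", site$chain, " ", site$resno, " not found")
  site_side <- at$side[which(own)[1]]
  a_idx <- which(own & !at$name %in% c("N", "CA", "C", "O", "CB"))
  d2 <- (at$x - cb[1])^2 + (at$y - cb[2])^2 + (at$z - cb[3])^2
  in_shell <- d2 <= shell_radius^2
  b_idx <- which(in_shell & at$side == site_side & !own)
  c_idx <- which(in_shell & at$side != site_side)
  list(a = a_idx, b = b_idx, c = c_idx, shell_radius = shell_radius)
}

#' Pairwise 12-6 Lennard-Jones energy
#'
#' \eqn{E = \epsilon_{ij}[(r_{min,ij}/r)^{12} - 2(r_{min,ij}/r)^6]} with
#' geometric-mean well depth and summed per-atom radii; capped at the
#' clash cap to keep steric overlaps finite.
#'
#' @param i,j Atom records: lists/rows with \code{x,y,z}, \code{vdw_rmin},
#'   \code{vdw_epsilon}.
#' @param config Energy constants, see \code{\link{energy_config}}.
#' @return Energy, kcal/mol.
#' @export
lj_pair <- function(i, j, config = energy_config()) {
  r <- .pair_dist(i, j)
  .lj(r, sqrt(i$vdw_epsilon * j$vdw_epsilon), i$vdw_rmin + j$vdw_rmin,
      config$lj_cap)
}

.lj <- function(r, eps, rmin, cap) {
  q <- (rmin / r)^6
  pmin(eps * (q^2 - 2 * q), cap)
}

#' Pairwise 12-10 hydrogen-bond energy
#'
#' Distance-only 12-10 potential between a donor heavy atom and an
#' acceptor: \eqn{E = \epsilon_{hb}[5(r_0/r)^{12} - 6(r_0/r)^{10}]},
#' active only for \code{hb_rmin < r <= hb_rmax}; zero if the pair is not
#' donor/acceptor in the given orientation.
#'
#' @inheritParams lj_pair
#' @param donor,acceptor Atom records; the donor must carry
#'   \code{is_donor_heavy}, the acceptor \code{is_acceptor}.
#' @return Energy, kcal/mol.
#' @export
hbond_pair <- function(donor, acceptor, config = energy_config()) {
  if (!isTRUE(donor$is_donor_heavy) || !isTRUE(acceptor$is_acceptor))
    return(0)
  r <- .pair_dist(donor, acceptor)
  .hb(r, config)
}

.hb <- function(r, config) {
  out <- numeric(length(r))
  act <- r > config$hb_rmin & r <= config$hb_rmax
  q <- config$hb_r0 / r[act]
  out[act] <- config$hb_eps * (5 * q^12 - 6 * q^10)
  out
}

#' Pairwise Coulomb energy with distance-dependent dielectric
#'
#' \eqn{E = k q_i q_j / (\epsilon(r) r)} with \eqn{\epsilon(r)} linear in
#' r, the usual implicit-screening choice for heavy-atom models.
#'
#' @inheritParams lj_pair
#' @return Energy, kcal/mol.
#' @export
coulomb_pair <- function(i, j, config = energy_config()) {
  r <- .pair_dist(i, j)
  .coul(r, i$partial_charge, j$partial_charge, config)
}

.coul <- function(r, qi, qj, config) {
  config$coulomb_k * qi * qj / (config$dielectric_slope * r * r)
}

#' Pairwise Gaussian solvent-exclusion (desolvation) energy
#'
#' Symmetric EEF1-style term: each atom's solvation free energy density is
#' excluded by the other's volume,
#' \eqn{E = -f(i,j) - f(j,i)} with
#' \eqn{f(i,j) = \frac{\Delta G^{free}_i}{2\pi^{3/2}\lambda_i r^2}
#'   e^{-((r - r_{min,i})/\lambda_i)^2} V_j}; zero beyond the desolvation
#' cutoff.
#'
#' @inheritParams lj_pair
#' @return Energy, kcal/mol.
#' @export
desolv_pair <- function(i, j, config = energy_config()) {
  r <- .pair_dist(i, j)
  .desolv(r, i$solv_dG_free, i$solv_lambda, i$vdw_rmin, j$solv_volume,
          j$solv_dG_free, j$solv_lambda, j$vdw_rmin, i$solv_volume,
          config)
}

.desolv_half <- function(r, dg, lambda, rmin, vol_other) {
  dg / (2 * pi^1.5 * lambda * r^2) * exp(-((r - rmin) / lambda)^2) *
    vol_other
}

.desolv <- function(r, dg_i, lam_i, rmin_i, vol_j,
                    dg_j, lam_j, rmin_j, vol_i, config) {
  out <- numeric(length(r))
  act <- r <= config$desolv_cutoff
  out[act] <- -(.desolv_half(r[act], dg_i[act], lam_i[act], rmin_i[act],
                             vol_j[act]) +
                .desolv_half(r[act], dg_j[act], lam_j[act], rmin_j[act],
                             vol_i[act]))
  out
}

.pair_dist <- function(i, j) {
  r <- sqrt((i$x - j$x)^2 + (i$y - j$y)^2 + (i$z - j$z)^2)
  if (any(r == 0)) stop("zero interatomic distance (duplicate atom)")
  r
}

#' Total cross-pair energy between two atom sets
#'
#' Sums a pair potential over all cross pairs of two disjoint atom sets.
#' For the hydrogen-bond term, both donor-acceptor orientations are summed
#' (A-donor to B-acceptor and B-donor to A-acceptor).
#'
#' @param complex \code{hspred_complex}.
#' @param setA,setB Disjoint integer vectors of atom-row indices.
#' @param term One of \code{"vdw"}, \code{"hbond"}, \code{"coulomb"},
#'   \code{"desolv"}.
#' @param config Energy constants.
#' @return Total energy, kcal/mol (0 when either set is empty).
#' @export
region_energy <- function(complex, setA, setB, term, config = energy_config()) {
  stopifnot(inherits(complex, "hspred_complex"))
  term <- match.arg(term, c("vdw", "hbond", "coulomb", "desolv"))
  if (length(intersect(setA, setB)))
    stop("atom sets overlap; region energies are defined on disjoint sets")
  if (!length(setA) || !length(setB)) return(0)
  at <- complex$atoms
  A <- at[setA, , drop = FALSE]
  B <- at[setB, , drop = FALSE]
  nA <- nrow(A); nB <- nrow(B)
  ii <- rep(seq_len(nA), times = nB)
  jj <- rep(seq_len(nB), each = nA)
  r <- sqrt((A$x[ii] - B$x[jj])^2 + (A$y[ii] - B$y[jj])^2 +
            (A$z[ii] - B$z[jj])^2)
  if (any(r == 0)) stop("zero interatomic distance (duplicate atom)")
  switch(term,
    vdw = sum(.lj(r, sqrt(A$vdw_epsilon[ii] * B$vdw_epsilon[jj]),
                  A$vdw_rmin[ii] + B$vdw_rmin[jj], config$lj_cap)),
    hbond = {
      da <- A$is_donor_heavy[ii] & B$is_acceptor[jj]
      ad <- B$is_donor_heavy[jj] & A$is_acceptor[ii]
      e <- .hb(r, config)
      sum(e[da]) + sum(e[ad])
    },
    coulomb = sum(.coul(r, A$partial_charge[ii], B$partial_charge[jj],
                        config)),
    desolv = sum(.desolv(r, A$solv_dG_free[ii], A$solv_lambda[ii],
                         A$vdw_rmin[ii], B$solv_volume[jj],
                         B$solv_dG_free[jj], B$solv_lambda[jj],
                         B$vdw_rmin[jj], A$solv_volume[ii], config)))
}

#' The 12-component energy feature vector for a candidate residue
#'
#' Evaluates the four energy terms on the three region pairings: side-chain
#' inter-molecular (a x c), environment inter-molecular (b x c, excluding
#' the mutated side chain by construction), and side-chain intra-molecular
#' (a x b).
#'
#' @param complex \code{hspred_complex}.
#' @param site One candidate-site row (see \code{\link{partition_regions}}).
#' @param shell_radius Shell radius, Angstrom.
#' @param config Energy constants.
#' @return Named numeric vector of length 12 in canonical
#'   \code{\link{feature_names}} order.
#' @export
energy_vector <- function(complex, site,
                          shell_radius = energy_config()$shell_radius,
                          config = energy_config()) {
  reg <- partition_regions(complex, site, shell_radius)
  terms <- c("vdw", "hbond", "coulomb", "desolv")
  v <- c(
    vapply(terms, function(t)
      region_energy(complex, reg$a, reg$c, t, config), numeric(1)),
    vapply(terms, function(t)
      region_energy(complex, reg$b, reg$c, t, config), numeric(1)),
    vapply(terms, function(t)
      region_energy(complex, reg$a, reg$b, t, config), numeric(1)))
  names(v) <- feature_names()
  v
}
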