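# Synthetic ground-truth generators: toy two-chain complexes with planted
# interface contacts, and feature tables drawn from a known linear model.
# Everything here is deterministic given the spec's seed, so every stage
# of the pipeline is testable offline, without structure downloads.

#' Specification of a toy two-chain complex
#'
#' Two idealized chains are built from template residue geometries on
#' parallel axes separated by \code{separation} Angstrom. Residues listed
#' in \code{planted1}/\code{planted2} have their side chains oriented
#' across the gap so that their tip atoms come within 4 Angstrom of the
#' partner chain (a guaranteed interface contact); all other side chains
#' point away from the interface. Geometries are idealized, not
#' physically relaxed: bond lengths along planted side chains stretch as
#' needed to bridge the gap.
#'
#' @param seq1,seq2 1-letter residue sequences of chains A and B.
#' @param separation Distance between the chain axes, Angstrom.
#' @param planted1,planted2 Integer residue indices (1-based) whose side
#'   chains are planted across the interface; must be mutable amino acids
#'   (not Ala/Gly/Pro).
#' @param jitter_sd Coordinate jitter standard deviation, Angstrom.
#' @param seed Integer seed.
#' @return List of class \code{toy_complex_spec}.
#' @export
toy_complex_spec <- function(seq1, seq2, separation = 9.5,
                             planted1 = integer(0), planted2 = integer(0),
                             jitter_sd = 0.05, seed = 1L) {
  stopifnot(nchar(seq1) > 0, nchar(seq2) > 0, separation > 0,
            jitter_sd >= 0)
  check_seq <- function(s, planted, nm) {
    aa <- strsplit(s, "")[[1]]
    bad <- is.na(aa_one_to_three(aa))
    if (any(bad)) stop("invalid amino-acid letter(s) in ", nm, ": ",
                       paste(unique(aa[bad]), collapse = ", "))
    if (any(planted < 1 | planted > length(aa)))
      stop("planted index out of range for ", nm)
    npl <- aa[planted]
    if (any(npl %in% c("A", "G", "P")))
      stop("planted residues must be mutable (not Ala/Gly/Pro)")
    aa
  }
  check_seq(seq1, planted1, "seq1")
  check_seq(seq2, planted2, "seq2")
  structure(list(seq1 = seq1, seq2 = seq2, separation = separation,
                 planted1 = as.integer(planted1),
                 planted2 = as.integer(planted2),
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

# build one chain's atoms; nvec is the unit interface normal (toward the
# partner), partner_ca the partner chain's CA coordinates (for aiming
# planted side chains)
.build_chain <- function(aa, chain_id, y0, nvec, planted, partner_ca) {
  rows <- list()
  for (i in seq_along(aa)) {
    res3 <- aa_one_to_three(aa[i])
    ca <- c(3.8 * (i - 1), y0, 0)
    bb <- list(N = ca + c(-1.2, 0, -0.8), CA = ca,
               C = ca + c(1.2, 0, 0.8))
    bb$O <- bb$C + c(0.3, 0, 1.15)
    coords <- bb
    if (res3 != "GLY") {
      is_planted <- i %in% planted
      dvec <- if (is_planted) nvec else .unit(-nvec + c(0, 0, 0.5))
      cb <- ca + 1.53 * dvec
      coords$CB <- cb
      scn <- sidechain_atom_names(res3)
      k <- length(scn)
      if (k > 0) {
        if (is_planted) {
          d2 <- colSums((t(partner_ca) - cb)^2)
          target <- partner_ca[which.min(d2), ]
          u <- .unit(target - cb)
          d <- sqrt(min(d2))
          reach <- d - 3.85
          pvec <- .unit(.perp(u))
          for (j in seq_len(k))
            coords[[scn[j]]] <- cb + u * (reach * j / k) +
              0.35 * (-1)^j * pvec
        } else {
          pvec <- .unit(.perp(dvec))
          for (j in seq_len(k))
            coords[[scn[j]]] <- cb + dvec * 1.5 * j +
              0.4 * (-1)^j * pvec
        }
      }
    }
    for (nm in names(coords))
      rows[[length(rows) + 1]] <- list(name = nm, res3 = res3, resno = i,
                                       chain = chain_id,
                                       xyz = coords[[nm]])
  }
  rows
}

.unit <- function(v) v / sqrt(sum(v^2))
.perp <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v - sum(v * u) * u
}

#' Generate a toy complex as PDB text
#'
#' @param spec \code{\link{toy_complex_spec}}.
#' @return List with \code{pdb} (character vector of PDB lines) and
#'   \code{truth} (data.frame of planted residues: chain, resno, wt).
#' @export
generate_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  aa1 <- strsplit(spec$seq1, "")[[1]]
  aa2 <- strsplit(spec$seq2, "")[[1]]
  ca1 <- t(vapply(seq_along(aa1), function(i) c(3.8 * (i - 1), 0, 0),
                  numeric(3)))
  ca2 <- t(vapply(seq_along(aa2), function(i)
    c(3.8 * (i - 1), spec$separation, 0), numeric(3)))
  rows <- c(.build_chain(aa1, "A", 0, c(0, 1, 0), spec$planted1, ca2),
            .build_chain(aa2, "B", spec$separation, c(0, -1, 0),
                         spec$planted2, ca1))
  xyz <- t(vapply(rows, `[[`, numeric(3), "xyz"))
  if (spec$jitter_sd > 0)
    xyz <- xyz + with_seed(spec$seed,
                           matrix(stats::rnorm(length(xyz),
                                               sd = spec$jitter_sd),
                                  ncol = 3))
  lines <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    el <- substr(gsub("[^A-Z]", "", r$name), 1, 1)
    lines[i] <- sprintf(
      "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, r$name, r$res3, r$chain, r$resno,
      xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, 0.0, el)
  }
  lines <- c(lines, "END")
  truth <- rbind(
    if (length(spec$planted1))
      data.frame(chain = "A", resno = as.character(spec$planted1),
                 wt = aa1[spec$planted1], stringsAsFactors = FALSE),
    if (length(spec$planted2))
      data.frame(chain = "B", resno = as.character(spec$planted2),
                 wt = aa2[spec$planted2], stringsAsFactors = FALSE))
  if (is.null(truth))
    truth <- data.frame(chain = character(0), resno = character(0),
                        wt = character(0))
  list(pdb = lines, truth = truth)
}

#' Specification of a synthetic labelled feature dataset
#'
#' Features are drawn from a seeded multivariate normal; a latent score
#' \eqn{s = w^* \cdot x - b} generates
#' \eqn{\Delta\Delta G = a \, s + \epsilon} on the kcal/mol scale; labels
#' come from the hot-spot threshold and are then flipped at the label
#' noise rate. Rows are dealt round-robin into homology clusters and
#' wild-type amino acids drawn from the composition. The defaults put
#' negative weights on the interaction-energy features (favourable, i.e.
#' more negative, energies mark hot spots) and yield a hot-spot
#' prevalence of roughly 20-25%, the minority-class regime of real
#' alanine-scanning compilations.
#'
#' @param n Number of rows.
#' @param weights Named true weight vector over feature names.
#' @param threshold Latent offset b.
#' @param label_noise Label flip probability, in [0, 0.5).
#' @param ddg_sd ddG noise standard deviation, kcal/mol.
#' @param ddg_scale Slope a mapping latent score to ddG.
#' @param ddg_threshold Hot-spot threshold used for labelling, kcal/mol.
#' @param aa_comp Named probability vector over mutable amino acids.
#' @param n_clusters Number of homology clusters (>= 2).
#' @param aa_weights Optional named list: per-amino-acid weight vectors
#'   overriding \code{weights} for rows of that amino acid (used to plant
#'   amino-acid-specific signal, e.g. a divergent Glu energetics).
#' @param sigma Optional feature covariance matrix (12 x 12); identity by
#'   default. Must be positive definite.
#' @param seed Integer seed.
#' @return List of class \code{synthetic_feature_spec}.
#' @export
synthetic_feature_spec <- function(n = 500L,
                                   weights = c(vdw_sc_inter = -1.6,
                                               hbond_sc_inter = -1.1,
                                               desolv_sc_inter = -0.9,
                                               vdw_env_inter = -0.6,
                                               hbond_env_inter = -0.5,
                                               vdw_sc_intra = -0.4),
                                   threshold = 0.45,
                                   label_noise = 0.05,
                                   ddg_sd = 0.6,
                                   ddg_scale = 1.5,
                                   ddg_threshold = 2.0,
                                   aa_comp = c(R = 0.12, E = 0.12,
                                               K = 0.10, D = 0.10,
                                               N = 0.08, Q = 0.08,
                                               Y = 0.08, W = 0.06,
                                               S = 0.06, T = 0.06,
                                               L = 0.05, I = 0.05,
                                               F = 0.04),
                                   n_clusters = 8L,
                                   aa_weights = NULL,
                                   sigma = NULL,
                                   seed = 1L) {
  stopifnot(n >= 1, label_noise >= 0, label_noise < 0.5, n_clusters >= 2,
            ddg_scale > 0, all(names(weights) %in% feature_names()),
            all(names(aa_comp) %in% mutable_amino_acids()))
  structure(list(n = as.integer(n), weights = weights,
                 threshold = threshold, label_noise = label_noise,
                 ddg_sd = ddg_sd, ddg_scale = ddg_scale,
                 ddg_threshold = ddg_threshold, aa_comp = aa_comp,
                 n_clusters = as.integer(n_clusters),
                 aa_weights = aa_weights, sigma = sigma,
                 seed = as.integer(seed)),
            class = "synthetic_feature_spec")
}

#' Generate a labelled synthetic feature dataset
#'
#' @param spec \code{\link{synthetic_feature_spec}}.
#' @return List with \code{table} (a feature table in the format of
#'   \code{\link{build_feature_table}}) and \code{truth} (the latent
#'   scores and the full true weight vectors used per row).
#' @export
generate_feature_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_feature_spec"))
  fn <- feature_names()
  p <- length(fn)
  sigma <- spec$sigma %||% diag(p)
  ch <- tryCatch(chol(sigma),
                 error = function(e)
                   stop("requested feature covariance is not positive ",
                        "definite"))
  full_w <- function(w) {
    out <- stats::setNames(numeric(p), fn)
    out[names(w)] <- w
    out
  }
  w0 <- full_w(spec$weights)
  res <- with_seed(spec$seed, {
    X <- matrix(stats::rnorm(spec$n * p), spec$n, p) %*% ch
    colnames(X) <- fn
    aa <- sample(names(spec$aa_comp), spec$n, replace = TRUE,
                 prob = spec$aa_comp)
    W <- matrix(rep(w0, each = spec$n), spec$n, p)
    if (!is.null(spec$aa_weights))
      for (a in names(spec$aa_weights)) {
        sel <- aa == a
        W[sel, ] <- matrix(rep(full_w(spec$aa_weights[[a]]),
                               each = sum(sel)), sum(sel), p)
      }
    s <- rowSums(X * W) - spec$threshold
    ddg <- spec$ddg_scale * s + stats::rnorm(spec$n, sd = spec$ddg_sd)
    label <- label_hotspots(ddg, spec$ddg_threshold)
    flip <- stats::runif(spec$n) < spec$label_noise
    label[flip] <- -label[flip]
    list(X = X, aa = aa, s = s, ddg = ddg, label = label, W = W)
  })
  tab <- data.frame(
    complex_id = "synth", chain = "A",
    resnum = as.character(seq_len(spec$n)), wt_aa = res$aa,
    ddg = res$ddg,
    cluster_id = paste0("c",
                        rep_len(seq_len(spec$n_clusters), spec$n)),
    label = res$label, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(res$X))
  list(table = tab,
       truth = list(weights = w0, latent = res$s,
                    per_row_weights = res$W,
                    threshold = spec$threshold))
}
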