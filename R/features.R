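# Labelled per-residue feature tables: joining alanine-scanning mutation
# records to complexes, hot-spot labelling, z-score standardization and
# feature/ddG correlations.

#' Label alanine mutations as hot spots
#'
#' A mutation is a hot spot (+1) when its experimental binding free energy
#' change meets or exceeds the threshold, else a non hot spot (-1). The
#' conventional threshold is 2.0 kcal/mol; the comparison is inclusive.
#'
#' @param ddg Numeric vector of ddG values, kcal/mol.
#' @param ddg_threshold Hot-spot threshold, kcal/mol (> 0).
#' @return Integer vector of +1 / -1 labels.
#' @export
label_hotspots <- function(ddg, ddg_threshold = 2.0) {
  stopifnot(ddg_threshold > 0)
  if (any(!is.finite(ddg)))
    stop("missing or non-finite ddG value(s); labels require measured ddG")
  ifelse(ddg >= ddg_threshold, 1L, -1L)
}

#' Read a tab-separated mutation table
#'
#' Columns: \code{complex_id, chain, resnum, wt_aa, ddg, cluster_id}.
#' \code{resnum} is the PDB residue number with any insertion code
#' appended; \code{wt_aa} the 1-letter wild-type code; \code{ddg} in
#' kcal/mol; \code{cluster_id} the homology-cluster label used to keep
#' related complexes on one side of every cross-validation split.
#'
#' @param path File path.
#' @return data.frame of mutation records.
#' @export
read_mutations <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(resnum = "character"))
  need <- c("complex_id", "chain", "resnum", "wt_aa", "ddg", "cluster_id")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("mutation table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- m$wt_aa %in% c("A", "G", "P")
  if (any(bad)) stop("mutation table contains non-mutable residues ",
                     "(Ala/Gly/Pro) at rows ",
                     paste(which(bad), collapse = ", "))
  m
}

#' @rdname read_mutations
#' @param mutations data.frame of mutation records.
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble a labelled per-residue feature table
#'
#' Joins mutation records to their complexes, computes the 12-component
#' energy vector at each mutated site and attaches hot-spot labels.
#' Mutations at residues that are not at the complex interface are dropped
#' with a warning: only interface mutations are retained. Unresolvable
#' mutations (wrong chain, residue number or wild-type mismatch) are a
#' hard error listing the offenders.
#'
#' @param complexes Named list of \code{hspred_complex} objects, names
#'   matching \code{complex_id} in \code{mutations}.
#' @param mutations Mutation records (see \code{\link{read_mutations}}).
#' @param shell_radius Shell radius for the energy regions, Angstrom.
#' @param contact_cutoff Interface contact distance, Angstrom.
#' @param ddg_threshold Hot-spot threshold, kcal/mol.
#' @param config Energy constants.
#' @return data.frame: mutation columns, \code{label} (+1/-1) and the 12
#'   feature columns of \code{\link{feature_names}}.
#' @export
build_feature_table <- function(complexes, mutations,
                                shell_radius = energy_config()$shell_radius,
                                contact_cutoff = energy_config()$contact_cutoff,
                                ddg_threshold = 2.0,
                                config = energy_config()) {
  if (nrow(mutations) == 0) return(.empty_feature_table())
  key <- paste(mutations$complex_id, mutations$chain, mutations$resnum)
  if (anyDuplicated(key))
    stop("duplicate mutation keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  sites_by_cx <- lapply(complexes, find_interface_residues, contact_cutoff)
  bad <- character(0)
  rows <- vector("list", nrow(mutations))
  dropped <- character(0)
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    cx <- complexes[[m$complex_id]]
    if (is.null(cx)) { bad <- c(bad, paste(key[i], "(no such complex)")); next }
    at <- cx$atoms
    sel <- at$chain == m$chain & at$resno == as.character(m$resnum)
    if (!any(sel)) { bad <- c(bad, paste(key[i], "(residue not found)")); next }
    resname <- at$resname[which(sel)[1]]
    if (!identical(aa_three_to_one(resname), m$wt_aa)) {
      bad <- c(bad, paste0(key[i], " (wild-type mismatch: file has ",
                           resname, ", record says ", m$wt_aa, ")"))
      next
    }
    s <- sites_by_cx[[m$complex_id]]
    hit <- s[s$chain == m$chain & s$resno == as.character(m$resnum), ,
             drop = FALSE]
    if (nrow(hit) == 0) { dropped <- c(dropped, key[i]); next }
    ev <- energy_vector(cx, hit[1, ], shell_radius, config)
    rows[[i]] <- cbind(m, as.data.frame(as.list(ev)))
  }
  if (length(bad))
    stop("unresolvable mutation(s): ", paste(bad, collapse = "; "))
  if (length(dropped))
    warning(length(dropped), " mutation(s) at non-interface residues ",
            "dropped: ", paste(dropped, collapse = "; "))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.empty_feature_table())
  tab <- do.call(rbind, rows)
  tab$label <- label_hotspots(tab$ddg, ddg_threshold)
  rownames(tab) <- NULL
  tab[, c("complex_id", "chain", "resnum", "wt_aa", "ddg", "cluster_id",
          "label", feature_names())]
}

.empty_feature_table <- function() {
  tab <- data.frame(complex_id = character(0), chain = character(0),
                    resnum = character(0), wt_aa = character(0),
                    ddg = numeric(0), cluster_id = character(0),
                    label = integer(0))
  for (f in feature_names()) tab[[f]] <- numeric(0)
  tab
}

#' Z-score standardization of feature columns
#'
#' With \code{stats = "fit"}, per-feature means and standard deviations are
#' estimated on the given table and returned for reuse on held-out data
#' (never re-fit on a test fold). Constant features (sd = 0) are left
#' unscaled with a warning.
#'
#' @param table Feature table.
#' @param stats \code{"fit"} or a list with \code{mean} and \code{sd}
#'   named vectors from a previous fit.
#' @return List with \code{table} (standardized) and \code{stats}.
#' @export
standardize <- function(table, stats = "fit") {
  fn <- intersect(feature_names(), names(table))
  X <- as.matrix(table[, fn, drop = FALSE])
  if (identical(stats, "fit")) {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    if (nrow(X) < 2) sd[] <- NA_real_
    zero <- !is.finite(sd) | sd == 0
    if (any(zero)) {
      warning("constant feature column(s) left unscaled: ",
              paste(fn[zero], collapse = ", "))
      sd[zero] <- 1
      mu[zero] <- 0
    }
    stats <- list(mean = mu, sd = sd)
  }
  X <- sweep(sweep(X, 2, stats$mean[fn]), 2, stats$sd[fn], "/")
  table[, fn] <- X
  list(table = table, stats = stats)
}

#' Absolute Pearson correlation of each feature with observed ddG
#'
#' @param table Labelled feature table with a finite \code{ddg} column.
#' @return Named numeric vector of |r| per feature.
#' @export
feature_ddg_correlation <- function(table) {
  if (nrow(table) < 3)
    stop("need at least 3 rows to estimate correlations")
  fn <- intersect(feature_names(), names(table))
  vapply(fn, function(f) {
    s <- stats::sd(table[[f]])
    if (!is.finite(s) || s == 0) return(0)
    abs(stats::cor(table[[f]], table$ddg))
  }, numeric(1))
}

#' Read/write feature tables
#'
#' Tab-separated, lossless round-trip of the feature table produced by
#' \code{\link{build_feature_table}}.
#'
#' @param table Feature table.
#' @param path File path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(resnum = "character"))
}
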