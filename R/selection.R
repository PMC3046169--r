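# Feature selection: the correlation-filtered baseline set for the general
# model, and the constrained subset-ensemble search that yields the Arg and
# Glu specialist classifiers. Specialist models are trained on ALL
# mutations; the target amino acid enters only when choosing, by inner-CV
# F1 restricted to that amino acid, which member of the candidate ensemble
# to keep.

#' Baseline feature set by correlation filter
#'
#' Keeps the features whose absolute correlation with observed ddG exceeds
#' \code{r_min}, in canonical feature order. This reproduces the design of
#' the general classifier, which retains the informative energy terms and
#' drops the weakly correlated ones.
#'
#' @param corr Named |r| vector over all 12 features
#'   (\code{\link{feature_ddg_correlation}}).
#' @param r_min Correlation floor (strict inequality).
#' @return Character vector of feature names.
#' @export
baseline_feature_set <- function(corr, r_min = 0.2) {
  fn <- feature_names()
  stopifnot(all(fn %in% names(corr)))
  keep <- fn[corr[fn] > r_min]
  if (!length(keep))
    stop("no feature exceeds |r| = ", r_min,
         "; lower r_min or inspect the data")
  keep
}

#' Highly correlated (redundant) feature pairs
#'
#' Unordered pairs of features whose absolute mutual correlation exceeds
#' \code{r_max}; such pairs are excluded from candidate subsets because
#' they carry redundant information.
#'
#' @param corr_matrix Symmetric feature-by-feature absolute correlation
#'   matrix with unit diagonal (named dims).
#' @param r_max Redundancy threshold.
#' @return data.frame with columns \code{f1}, \code{f2} (f1 earlier in
#'   canonical order), possibly empty.
#' @export
redundancy_pairs <- function(corr_matrix, r_max = 0.8) {
  stopifnot(is.matrix(corr_matrix),
            nrow(corr_matrix) == ncol(corr_matrix))
  nm <- rownames(corr_matrix)
  out <- list()
  for (i in seq_len(nrow(corr_matrix) - 1))
    for (j in seq(i + 1, ncol(corr_matrix)))
      if (abs(corr_matrix[i, j]) > r_max)
        out[[length(out) + 1]] <- data.frame(f1 = nm[i], f2 = nm[j],
                                             stringsAsFactors = FALSE)
  if (!length(out))
    return(data.frame(f1 = character(0), f2 = character(0)))
  do.call(rbind, out)
}

#' Enumerate constrained candidate feature subsets
#'
#' All subsets of the base set with the given sizes that contain no
#' excluded (redundant) pair; optionally, each such subset extended by one
#' extra feature outside the base (used to add the intra-molecular Coulomb
#' term to the Arg candidates). Output order is deterministic: by size,
#' then lexicographically by position in the base set, base subsets before
#' their extended variants of equal size.
#'
#' @param base Character vector of base features (canonical order).
#' @param excluded data.frame of excluded pairs
#'   (\code{\link{redundancy_pairs}}).
#' @param sizes Integer subset sizes, default \code{c(3, 4)}.
#' @param extra_feature Optional feature to append to every valid subset;
#'   must not already be in \code{base}.
#' @return List of character vectors.
#' @export
enumerate_candidate_subsets <- function(base, excluded = NULL,
                                        sizes = c(3L, 4L),
                                        extra_feature = NULL) {
  if (!is.null(extra_feature) && extra_feature %in% base)
    stop("extra_feature ", extra_feature, " is already in the base set")
  if (is.null(excluded)) excluded <- data.frame(f1 = character(0),
                                                f2 = character(0))
  ex_keys <- character(0)
  if (nrow(excluded)) {
    a <- pmin(excluded$f1, excluded$f2)
    b <- pmax(excluded$f1, excluded$f2)
    ex_keys <- paste(a, b)
  }
  ok <- function(s) {
    if (length(s) < 2) return(TRUE)
    prs <- utils::combn(sort(s), 2)
    !any(paste(prs[1, ], prs[2, ]) %in% ex_keys)
  }
  out <- list()
  for (k in sort(sizes)) {
    if (k > length(base)) next
    cmb <- utils::combn(base, k, simplify = FALSE)
    cmb <- Filter(ok, cmb)
    out <- c(out, cmb)
    if (!is.null(extra_feature))
      out <- c(out, lapply(cmb, function(s) c(s, extra_feature)))
  }
  # dedupe while preserving first occurrence
  keys <- vapply(out, function(s) paste(sort(s), collapse = "|"),
                 character(1))
  out[!duplicated(keys)]
}

# pooled inner-CV predictions for one feature subset and one (C, cw) pair;
# standardization refit on each inner-train. Returns data.frame(row, truth,
# pred) over all inner-test rows, plus the training row ids it touched.
.inner_cv_predictions <- function(table, feature_ids, C, cw, inner_folds) {
  preds <- list()
  used <- integer(0)
  for (f in inner_folds) {
    tr <- which(table$cluster_id %in% f$train_clusters)
    te <- which(table$cluster_id %in% f$test_clusters)
    if (!length(tr) || !length(te)) next
    if (length(unique(table$label[tr])) < 2) next
    st <- standardize(table[tr, , drop = FALSE], "fit")
    m <- train_linear_svm(st$table, feature_ids, C, cw)
    tes <- standardize(table[te, , drop = FALSE], st$stats)$table
    s <- score(m, tes[, feature_ids, drop = FALSE])
    preds[[length(preds) + 1]] <-
      data.frame(row = te, truth = table$label[te], pred = classify(s),
                 score = s)
    used <- union(used, tr)
  }
  list(pred = do.call(rbind, preds), rows_used = used)
}

.f1_of <- function(truth, pred) {
  precision_recall_f1(confusion_counts(truth, pred))[["f1"]]
}

#' Select the best feature subset for a target amino acid
#'
#' For every candidate subset, hyper-parameters are grid-searched by
#' pooled inner-CV F1 over ALL mutations; the winning hyper-parameters'
#' pooled inner predictions are then restricted to the target amino acid
#' and the candidate with the highest target F1 is returned. Ties break
#' toward the smaller subset, then the earlier candidate in enumeration
#' order (and, within the grid, the smaller C then smaller class weight).
#'
#' @param table Labelled feature table (raw scale; standardization is
#'   refit inside each inner fold).
#' @param candidates List of feature subsets
#'   (\code{\link{enumerate_candidate_subsets}}).
#' @param target_aa 1-letter amino-acid code to optimise for.
#' @param inner_folds List of folds, each with \code{train_clusters} and
#'   \code{test_clusters} (e.g. one outer-train entry of
#'   \code{\link{make_cluster_folds}}).
#' @param config \code{\link{training_config}}.
#' @return List of class \code{hspred_subset}: \code{feature_ids},
#'   \code{f1} (inner-CV target-aa F1), \code{C}, \code{class_weight};
#'   attribute \code{rows_used} records every training row index touched.
#' @export
select_best_subset <- function(table, candidates, target_aa, inner_folds,
                               config = training_config()) {
  if (!any(table$wt_aa == target_aa & table$label == 1) ||
      !any(table$wt_aa == target_aa))
    stop("no usable rows for target amino acid ", target_aa)
  best <- NULL
  rows_used <- integer(0)
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    best_grid <- NULL
    for (C in config$C_grid) for (cw in config$class_weight_grid) {
      icv <- .inner_cv_predictions(table, cand, C, cw, inner_folds)
      rows_used <- union(rows_used, icv$rows_used)
      if (is.null(icv$pred)) next
      f1_all <- .f1_of(icv$pred$truth, icv$pred$pred)
      if (is.null(best_grid) || f1_all > best_grid$f1_all + 1e-12) {
        best_grid <- list(C = C, cw = cw, f1_all = f1_all, pred = icv$pred)
      }
    }
    if (is.null(best_grid)) next
    aa_rows <- best_grid$pred[table$wt_aa[best_grid$pred$row] == target_aa, ,
                              drop = FALSE]
    f1_aa <- if (nrow(aa_rows)) .f1_of(aa_rows$truth, aa_rows$pred) else 0
    better <- is.null(best) ||
      f1_aa > best$f1 + 1e-12 ||
      (abs(f1_aa - best$f1) <= 1e-12 &&
         length(cand) < length(best$feature_ids))
    if (better)
      best <- list(feature_ids = cand, f1 = f1_aa, C = best_grid$C,
                   class_weight = best_grid$cw)
  }
  if (is.null(best)) stop("no candidate could be evaluated")
  attr(best, "rows_used") <- rows_used
  class(best) <- "hspred_subset"
  best
}

#' Detect amino acids the general model handles poorly
#'
#' Scores the general (baseline-feature) model by pooled inner-CV on the
#' training data and flags the amino acids whose per-type F1 falls below
#' \code{floor}. This offers an automatic, cross-validation-compliant way
#' to choose which amino acids deserve specialist classifiers; the shipped
#' default nevertheless hard-codes Arg and Glu, the two types general
#' models are known to handle worst, so ensemble behaviour stays
#' predictable.
#'
#' @param table Labelled feature table (training data only).
#' @param inner_folds Cluster folds over the training data.
#' @param config \code{\link{training_config}}.
#' @param floor F1 floor below which an amino acid is flagged.
#' @param min_n Minimum number of rows (with at least one hot spot) for an
#'   amino acid to be assessed.
#' @param r_min Baseline correlation floor.
#' @return Character vector of flagged 1-letter codes (possibly empty),
#'   with the per-amino-acid F1 table as attribute \code{"per_aa"}.
#' @export
detect_weak_amino_acids <- function(table, inner_folds,
                                    config = training_config(),
                                    floor = 0.35, min_n = 10L,
                                    r_min = 0.2) {
  base <- baseline_feature_set(feature_ddg_correlation(table), r_min)
  gs <- .grid_search(table, base, inner_folds, config)
  icv <- .inner_cv_predictions(table, base, gs$C, gs$class_weight,
                               inner_folds)
  aa_tab <- do.call(rbind, lapply(sort(unique(table$wt_aa)), function(aa) {
    rows <- icv$pred[table$wt_aa[icv$pred$row] == aa, , drop = FALSE]
    data.frame(wt_aa = aa, n = nrow(rows),
               n_hot = sum(rows$truth == 1),
               f1 = if (nrow(rows)) .f1_of(rows$truth, rows$pred) else NA,
               stringsAsFactors = FALSE)
  }))
  weak <- aa_tab$wt_aa[aa_tab$n >= min_n & aa_tab$n_hot >= 1 &
                         aa_tab$f1 < floor]
  attr(weak, "per_aa") <- aa_tab
  weak
}

#' @export
print.hspred_subset <- function(x, ...) {
  cat("Selected subset: {", paste(x$feature_ids, collapse = ", "),
      "}\n  inner-CV target F1 =", round(x$f1, 3),
      " C =", x$C, " class weight =", x$class_weight, "\n")
  invisible(x)
}
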