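# Performance metrics and homology-cluster-aware nested cross-validation.
# Clusters of homologous complexes are never split across train and test,
# in either loop; feature selection and hyper-parameter search run inside
# the inner loop only.

#' Confusion counts from truth and predictions
#'
#' @param truth,pred Integer vectors of +1 / -1.
#' @return Named integer vector \code{c(TP, FP, FN, TN)}.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  c(TP = sum(truth == 1 & pred == 1),
    FP = sum(truth == -1 & pred == 1),
    FN = sum(truth == 1 & pred == -1),
    TN = sum(truth == -1 & pred == -1))
}

#' Precision, recall and F1 score
#'
#' Precision is the fraction of predicted hot spots that are real; recall
#' the fraction of real hot spots recovered; F1 their harmonic mean.
#' Zero-denominator cases return 0, a convention that keeps small
#' per-amino-acid strata well defined.
#'
#' @param counts Named vector with \code{TP, FP, FN} (and optionally TN).
#' @return Named numeric vector \code{c(precision, recall, f1)}.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Matthews correlation coefficient
#'
#' \eqn{(TP \cdot TN - FP \cdot FN) /
#'  \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}; defined as 0 when any factor of
#' the denominator vanishes.
#'
#' @param counts Named vector with \code{TP, FP, FN, TN}.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]]); tn <- as.numeric(counts[["TN"]])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Pearson correlation between decision scores and observed ddG
#'
#' @param scores Numeric decision scores.
#' @param ddg Observed ddG values, kcal/mol.
#' @return Correlation coefficient.
#' @export
score_ddg_correlation <- function(scores, ddg) {
  if (length(scores) < 3) stop("need at least 3 rows")
  stopifnot(length(scores) == length(ddg))
  stats::cor(scores, ddg)
}

#' Build a cluster-respecting nested fold plan
#'
#' Homology clusters are shuffled (by seed) and dealt round-robin into
#' \code{k_outer} outer folds; setting \code{k_outer} to the number of
#' clusters gives leave-one-cluster-out. Within each outer training set,
#' inner folds are built the same way. No cluster ever appears on both
#' sides of any split, and inner folds never contain outer-test clusters.
#'
#' @param cluster_ids Vector of cluster labels (one per row, or the unique
#'   labels themselves).
#' @param k_outer Number of outer folds; \code{NULL} for
#'   leave-one-cluster-out.
#' @param k_inner Number of inner folds (capped at the number of training
#'   clusters in each outer fold).
#' @param seed Integer seed.
#' @return Object of class \code{hspred_folds}: list with \code{outer}
#'   (each element: \code{train_clusters}, \code{test_clusters},
#'   \code{inner} folds of the same shape), \code{k_outer}, \code{k_inner},
#'   \code{seed}.
#' @export
make_cluster_folds <- function(cluster_ids, k_outer = NULL, k_inner = 3L,
                               seed = 1L) {
  clusters <- sort(unique(as.character(cluster_ids)))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  if (is.null(k_outer)) k_outer <- length(clusters)
  if (k_outer > length(clusters))
    stop("k_outer (", k_outer, ") exceeds the number of clusters (",
         length(clusters), ")")
  deal <- function(xs, k, s) {
    xs <- with_seed(s, sample(xs))
    split(xs, rep_len(seq_len(k), length(xs)))
  }
  outer_sets <- deal(clusters, k_outer, seed)
  outer <- lapply(seq_len(k_outer), function(i) {
    test <- outer_sets[[i]]
    train <- setdiff(clusters, test)
    ki <- min(k_inner, length(train))
    inner_sets <- deal(train, ki, seed * 1000L + i)
    inner <- lapply(seq_len(ki), function(j)
      list(train_clusters = setdiff(train, inner_sets[[j]]),
           test_clusters = inner_sets[[j]]))
    list(train_clusters = train, test_clusters = test, inner = inner)
  })
  structure(list(outer = outer, k_outer = k_outer, k_inner = k_inner,
                 seed = as.integer(seed)),
            class = "hspred_folds")
}

#' @export
print.hspred_folds <- function(x, ...) {
  cat("Nested fold plan:", x$k_outer, "outer x", x$k_inner,
      "inner folds (seed", x$seed, ")\n")
  invisible(x)
}

# grid-search (C, cw) for a fixed feature set by pooled inner-CV F1
.grid_search <- function(table, feature_ids, inner_folds, config) {
  best <- NULL
  rows_used <- integer(0)
  for (C in config$C_grid) for (cw in config$class_weight_grid) {
    icv <- .inner_cv_predictions(table, feature_ids, C, cw, inner_folds)
    rows_used <- union(rows_used, icv$rows_used)
    if (is.null(icv$pred)) next
    f1 <- .f1_of(icv$pred$truth, icv$pred$pred)
    if (is.null(best) || f1 > best$f1 + 1e-12)
      best <- list(C = C, class_weight = cw, f1 = f1)
  }
  if (is.null(best)) stop("inner grid search failed on every fold")
  best$rows_used <- rows_used
  best
}

#' Nested cross-validated performance estimate
#'
#' Per outer fold: standardization, the baseline correlation filter, the
#' Arg/Glu subset selection (hspred mode) and the hyper-parameter grid are
#' all fit on the outer-training clusters only, using the inner folds;
#' final models are trained on the full outer-train and scored on the
#' held-out clusters. Outer-test predictions are pooled across folds.
#'
#' @param table Labelled feature table with \code{cluster_id}.
#' @param plan \code{\link{make_cluster_folds}} plan over the same
#'   clusters.
#' @param config \code{\link{training_config}}.
#' @param mode \code{"svm_x"} (general model only) or \code{"hspred"}
#'   (general model plus Arg/Glu specialists with routing).
#' @param specialists Amino acids given specialist models in hspred mode.
#' @param r_min,r_max Correlation filter / redundancy thresholds.
#' @return Object of class \code{hspred_cv}: \code{metrics} (pooled),
#'   \code{per_aa} (per-amino-acid metrics for amino acids present),
#'   \code{predictions} (pooled per-mutation table), \code{counts},
#'   \code{instrumentation} (per fold: training row ids touched and test
#'   row ids, for leakage auditing).
#' @export
nested_cv <- function(table, plan, config = training_config(),
                      mode = c("hspred", "svm_x"),
                      specialists = c("R", "E"),
                      r_min = 0.2, r_max = 0.8) {
  mode <- match.arg(mode)
  if (mode == "svm_x") specialists <- character(0)
  stopifnot(inherits(plan, "hspred_folds"))
  plan_clusters <- sort(unique(unlist(lapply(plan$outer,
                                             `[[`, "test_clusters"))))
  if (!setequal(plan_clusters, unique(as.character(table$cluster_id))))
    stop("fold plan clusters do not match the table's cluster_id values")
  preds <- list()
  instr <- list()
  for (fi in seq_along(plan$outer)) {
    fold <- plan$outer[[fi]]
    tr <- which(table$cluster_id %in% fold$train_clusters)
    te <- which(table$cluster_id %in% fold$test_clusters)
    if (!length(te)) next
    train_tab <- table[tr, , drop = FALSE]
    rows_touched <- integer(0)
    note_rows <- function(r) rows_touched <<- union(rows_touched, tr[r])

    corr <- feature_ddg_correlation(train_tab)
    base <- baseline_feature_set(corr, r_min)
    gs <- .grid_search(train_tab, base, fold$inner, config)
    note_rows(gs$rows_used)
    st <- standardize(train_tab, "fit")
    note_rows(seq_along(tr))
    model_X <- train_linear_svm(st$table, base, gs$C, gs$class_weight,
                                stats = st$stats)
    models <- list(X = model_X)

    for (aa in specialists) {
      if (!any(train_tab$wt_aa == aa & train_tab$label == 1)) next
      fmat <- abs(stats::cor(as.matrix(train_tab[, base, drop = FALSE])))
      excl <- redundancy_pairs(fmat, r_max)
      extra <- if (aa == "R" && !"coulomb_sc_intra" %in% base)
        "coulomb_sc_intra" else NULL
      cands <- enumerate_candidate_subsets(base, excl, c(3L, 4L), extra)
      sel <- tryCatch(
        select_best_subset(train_tab, cands, aa, fold$inner, config),
        error = function(e) NULL)
      if (is.null(sel)) next
      note_rows(attr(sel, "rows_used"))
      models[[aa]] <- train_linear_svm(st$table, sel$feature_ids, sel$C,
                                       sel$class_weight, stats = st$stats)
    }

    test_tab <- table[te, , drop = FALSE]
    s <- numeric(length(te))
    used_model <- character(length(te))
    for (k in seq_along(te)) {
      aa <- test_tab$wt_aa[k]
      m <- if (aa %in% names(models)) models[[aa]] else models$X
      used_model[k] <- if (aa %in% names(models)) aa else "X"
      s[k] <- score(m, test_tab[k, , drop = FALSE])
    }
    preds[[fi]] <- data.frame(
      row = te, complex_id = test_tab$complex_id, chain = test_tab$chain,
      resnum = test_tab$resnum, wt_aa = test_tab$wt_aa,
      cluster_id = test_tab$cluster_id, ddg = test_tab$ddg,
      truth = test_tab$label, score = s, pred = classify(s),
      model = used_model, fold = fi, stringsAsFactors = FALSE)
    instr[[fi]] <- list(train_rows_used = sort(rows_touched),
                        test_rows = sort(te))
  }
  pooled <- do.call(rbind, preds)
  rownames(pooled) <- NULL
  counts <- confusion_counts(pooled$truth, pooled$pred)
  metrics <- c(precision_recall_f1(counts), mcc = mcc(counts),
               score_ddg_cor = if (nrow(pooled) >= 3)
                 score_ddg_correlation(pooled$score, pooled$ddg)
               else NA_real_)
  per_aa <- do.call(rbind, lapply(sort(unique(pooled$wt_aa)), function(aa) {
    sub <- pooled[pooled$wt_aa == aa, , drop = FALSE]
    cts <- confusion_counts(sub$truth, sub$pred)
    data.frame(wt_aa = aa, n = nrow(sub),
               t(precision_recall_f1(cts)), mcc = mcc(cts),
               stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics, per_aa = per_aa, predictions = pooled,
                 counts = counts, instrumentation = instr, mode = mode,
                 plan = plan),
            class = "hspred_cv")
}

#' @export
print.hspred_cv <- function(x, ...) {
  cat("Nested cross-validation (", x$mode, " mode), ",
      nrow(x$predictions), " pooled predictions\n", sep = "")
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f  MCC %.3f\n",
              x$metrics[["precision"]], x$metrics[["recall"]],
              x$metrics[["f1"]], x$metrics[["mcc"]]))
  invisible(x)
}

#' Write a cross-validation report
#'
#' Tab-separated overall and per-amino-acid metrics plus the pooled
#' per-mutation prediction table.
#'
#' @param cv \code{hspred_cv} result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cv_report <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  overall <- data.frame(metric = names(cv$metrics),
                        value = unname(cv$metrics))
  utils::write.table(overall, file.path(dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cv$per_aa, file.path(dir, "metrics_per_aa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cv$predictions, file.path(dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
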