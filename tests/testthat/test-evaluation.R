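test_that("classification metrics match hand-evaluated definitions", {
  prf <- precision_recall_f1(c(TP = 3, FP = 2, FN = 1, TN = 0))
  expect_equal(unname(prf), c(0.6, 0.75, 2 / 3))
  expect_equal(unname(precision_recall_f1(c(TP = 5, FP = 0, FN = 0))),
               c(1, 1, 1))
  expect_equal(unname(precision_recall_f1(c(TP = 0, FP = 0, FN = 4))),
               c(0, 0, 0))
  expect_equal(mcc(c(TP = 5, FP = 0, FN = 0, TN = 5)), 1)
  expect_equal(mcc(c(TP = 3, FP = 2, FN = 1, TN = 4)),
               (3 * 4 - 2 * 1) / sqrt(5 * 4 * 6 * 5))
  expect_equal(mcc(c(TP = 2, FP = 2, FN = 2, TN = 2)), 0)
  expect_equal(mcc(c(TP = 0, FP = 0, FN = 3, TN = 9)), 0)  # degenerate
})

test_that("metrics agree with the confusion oracle on random tuples", {
  set.seed(77)
  for (k in 1:300) {
    cts <- c(TP = rpois(1, 5), FP = rpois(1, 4), FN = rpois(1, 3),
             TN = rpois(1, 8))
    o <- oracle_metrics(cts[1], cts[2], cts[3], cts[4])
    prf <- precision_recall_f1(cts)
    expect_equal(unname(prf), unname(o[1:3]))
    m <- mcc(cts)
    expect_equal(m, unname(o[4]))
    expect_gte(m, -1); expect_lte(m, 1)
    # F1 is the harmonic mean identity
    if (o[1] + o[2] > 0)
      expect_equal(unname(prf["f1"]),
                   2 / (1 / max(o[1], 1e-300) + 1 / max(o[2], 1e-300)),
                   tolerance = 1e-12)
  }
})

test_that("score/ddG correlation behaves as a Pearson estimate", {
  expect_equal(score_ddg_correlation(1:5, 1:5), 1)
  expect_equal(score_ddg_correlation(1:5, -(1:5)), -1)
  expect_error(score_ddg_correlation(1:2, 1:2), "3 rows")
  set.seed(10)
  x <- rnorm(200); r_true <- 0.7
  y <- r_true * x + sqrt(1 - r_true^2) * rnorm(200)
  expect_lt(abs(score_ddg_correlation(x, y) - r_true), 0.1)
})

test_that("cluster folds partition clusters and respect nesting", {
  ids <- paste0("c", 1:6)
  plan <- make_cluster_folds(ids, k_outer = 6, seed = 1)
  expect_equal(plan$k_outer, 6)           # leave-one-cluster-out
  for (f in plan$outer) expect_length(f$test_clusters, 1)
  for (seed in 1:25) {
    plan <- make_cluster_folds(rep(paste0("c", 1:8), 5),
                               k_outer = 4, k_inner = 3, seed = seed)
    tested <- unlist(lapply(plan$outer, `[[`, "test_clusters"))
    expect_setequal(tested, paste0("c", 1:8))
    expect_false(any(duplicated(tested)))
    for (f in plan$outer) {
      expect_length(intersect(f$train_clusters, f$test_clusters), 0)
      for (g in f$inner) {
        expect_length(intersect(g$train_clusters, g$test_clusters), 0)
        expect_length(intersect(g$test_clusters, f$test_clusters), 0)
      }
    }
  }
  expect_error(make_cluster_folds(ids, k_outer = 7), "exceeds")
  expect_error(make_cluster_folds("c1"), "2 clusters")
})

test_that("fold plans are byte-identical across runs at a fixed seed", {
  p1 <- make_cluster_folds(paste0("c", 1:9), k_outer = 4, seed = 123)
  p2 <- make_cluster_folds(paste0("c", 1:9), k_outer = 4, seed = 123)
  expect_identical(p1, p2)
  p3 <- make_cluster_folds(paste0("c", 1:9), k_outer = 4, seed = 124)
  expect_false(identical(p1$outer, p3$outer))
})

test_that("nested CV recovers a clean linear signal", {
  # labels are the exact sign of a linear function of three features
  spec <- synthetic_feature_spec(n = 400, seed = 31, label_noise = 0,
                                 ddg_sd = 0,
                                 weights = c(vdw_sc_inter = -1.6,
                                             hbond_sc_inter = -1.2,
                                             desolv_sc_inter = -1.0))
  ds <- generate_feature_dataset(spec)
  plan <- make_cluster_folds(ds$table$cluster_id, seed = 31)
  cv <- nested_cv(ds$table, plan, small_training_config(31), "svm_x")
  expect_gt(cv$metrics[["f1"]], 0.9)
  # conservation: pooled counts cover the whole table
  expect_equal(sum(cv$counts), nrow(ds$table))
  expect_equal(sort(cv$predictions$row), seq_len(nrow(ds$table)))
})

test_that("permuted labels give chance-level nested-CV performance", {
  ds <- generate_feature_dataset(synthetic_feature_spec(n = 500, seed = 11))
  tab <- ds$table
  set.seed(42)
  tab$label <- sample(tab$label)
  plan <- make_cluster_folds(tab$cluster_id, seed = 11)
  cv <- nested_cv(tab, plan, small_training_config(11), "svm_x")
  expect_lt(abs(cv$metrics[["mcc"]]), 0.15)
})

test_that("a label-leak sentinel is recovered only via outer-test scoring", {
  ds <- generate_feature_dataset(synthetic_feature_spec(n = 300, seed = 17))
  tab <- ds$table
  # plant a feature that IS the label (and aligns with ddg so the
  # correlation filter keeps it)
  tab$vdw_sc_inter <- as.numeric(tab$label)
  tab$ddg <- 2 * tab$label + 0.5
  tab$label <- label_hotspots(tab$ddg)
  plan <- make_cluster_folds(tab$cluster_id, seed = 17)
  cv <- nested_cv(tab, plan, small_training_config(17), "svm_x")
  expect_equal(cv$metrics[["f1"]], 1.0)
  # instrumentation: training never touched an outer-test row
  for (fold in cv$instrumentation)
    expect_length(intersect(fold$train_rows_used, fold$test_rows), 0)
})

test_that("hspred mode without specialists degrades to svm_x exactly", {
  ds <- generate_feature_dataset(synthetic_feature_spec(n = 250, seed = 23))
  plan <- make_cluster_folds(ds$table$cluster_id, seed = 23)
  cfg <- small_training_config(23)
  cv1 <- nested_cv(ds$table, plan, cfg, "svm_x")
  cv2 <- nested_cv(ds$table, plan, cfg, "hspred", specialists = character(0))
  expect_equal(cv1$predictions$score, cv2$predictions$score)
  expect_identical(cv1$predictions$pred, cv2$predictions$pred)
})

test_that("per-amino-acid breakdown sums to the pooled confusion", {
  ds <- generate_feature_dataset(synthetic_feature_spec(n = 250, seed = 29))
  plan <- make_cluster_folds(ds$table$cluster_id, seed = 29)
  cv <- nested_cv(ds$table, plan, small_training_config(29), "svm_x")
  expect_equal(sum(cv$per_aa$n), nrow(ds$table))
  expect_setequal(cv$per_aa$wt_aa, unique(ds$table$wt_aa))
})
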