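test_that("the correlation filter keeps exactly the informative features", {
  corr <- setNames(rep(0.05, 12), feature_names())
  seven <- c("vdw_sc_inter", "hbond_sc_inter", "desolv_sc_inter",
             "vdw_env_inter", "hbond_env_inter", "desolv_env_inter",
             "vdw_sc_intra")
  corr[seven] <- c(0.55, 0.35, 0.4, 0.3, 0.25, 0.22, 0.28)
  expect_equal(baseline_feature_set(corr, 0.2),
               intersect(feature_names(), seven))
  expect_error(baseline_feature_set(setNames(numeric(12), feature_names())),
               "no feature")
  expect_error(baseline_feature_set(corr, 1.0), "no feature")
})

test_that("redundancy_pairs thresholds the correlation matrix", {
  fn <- feature_names()[1:5]
  M <- diag(5); dimnames(M) <- list(fn, fn)
  expect_equal(nrow(redundancy_pairs(M, 0.8)), 0)
  M[1, 3] <- M[3, 1] <- 0.92
  M[2, 5] <- M[5, 2] <- 0.85
  prs <- redundancy_pairs(M, 0.8)
  expect_equal(nrow(prs), 2)
  expect_setequal(paste(prs$f1, prs$f2),
                  c(paste(fn[1], fn[3]), paste(fn[2], fn[5])))
  # r_max = 0 excludes every (non-zero) off-diagonal pair
  M[upper.tri(M)] <- pmax(M[upper.tri(M)], 0.1)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  expect_equal(nrow(redundancy_pairs(M, 0)), choose(5, 2))
})

test_that("subset enumeration matches brute-force powerset filtering", {
  base7 <- feature_names()[c(1, 2, 4, 5, 6, 8, 9)]
  none <- data.frame(f1 = character(0), f2 = character(0))
  subs <- enumerate_candidate_subsets(base7, none)
  expect_length(subs, choose(7, 3) + choose(7, 4))   # 70
  set.seed(21)
  for (trial in 1:20) {
    base <- sample(feature_names(), sample(4:8, 1))
    n_ex <- sample(0:3, 1)
    excl <- if (n_ex > 0) {
      prs <- replicate(n_ex, sort(sample(base, 2)), simplify = FALSE)
      data.frame(f1 = vapply(prs, `[`, "", 1),
                 f2 = vapply(prs, `[`, "", 2))
    } else none
    sizes <- sample(list(3L, c(3L, 4L), 4L), 1)[[1]]
    extra <- if (runif(1) < 0.5) setdiff(feature_names(), base)[1] else NULL
    got <- enumerate_candidate_subsets(base, excl, sizes, extra)
    keys <- vapply(got, function(s) paste(sort(s), collapse = "|"), "")
    expect_false(any(duplicated(keys)))
    expect_setequal(keys, oracle_subsets(base, excl, sizes, extra))
  }
})

test_that("enumeration edge cases behave", {
  b3 <- feature_names()[1:3]
  none <- data.frame(f1 = character(0), f2 = character(0))
  expect_length(enumerate_candidate_subsets(b3, none, 3L), 1)
  expect_error(enumerate_candidate_subsets(b3, none, 3L,
                                           extra_feature = b3[1]),
               "already in the base")
  # excluded pair removes the subsets containing it
  excl <- data.frame(f1 = b3[1], f2 = b3[2])
  expect_length(enumerate_candidate_subsets(b3, excl, 3L), 0)
})

test_that("subset selection recovers planted amino-acid signal", {
  # target-aa labels depend only on three features
  spec <- synthetic_feature_spec(
    n = 400, seed = 13,
    aa_comp = c(E = 0.3, K = 0.2, Y = 0.2, W = 0.15, D = 0.15),
    aa_weights = list(E = c(hbond_sc_inter = -2.2,
                            hbond_env_inter = -1.6,
                            vdw_sc_intra = -1.2)),
    weights = c(vdw_sc_inter = -1.5, hbond_sc_inter = -0.9,
                desolv_sc_inter = -0.8, hbond_env_inter = -0.5,
                vdw_sc_intra = -0.4))
  ds <- generate_feature_dataset(spec)
  folds <- make_cluster_folds(ds$table$cluster_id, k_outer = 3, seed = 13)
  inner <- lapply(folds$outer, function(f)
    list(train_clusters = f$train_clusters,
         test_clusters = f$test_clusters))
  base <- c("vdw_sc_inter", "hbond_sc_inter", "desolv_sc_inter",
            "hbond_env_inter", "vdw_sc_intra")
  cands <- enumerate_candidate_subsets(
    base, data.frame(f1 = character(0), f2 = character(0)), c(3L, 4L))
  sel <- select_best_subset(ds$table, cands, "E", inner,
                            small_training_config(13))
  expect_true(all(c("hbond_sc_inter", "hbond_env_inter") %in%
                    sel$feature_ids))
  # determinism
  sel2 <- select_best_subset(ds$table, cands, "E", inner,
                             small_training_config(13))
  expect_identical(sel$feature_ids, sel2$feature_ids)
  expect_identical(sel$f1, sel2$f1)
})

test_that("weak amino acids are flagged from training-set performance", {
  spec <- synthetic_feature_spec(
    n = 500, seed = 19,
    aa_comp = c(E = 0.25, K = 0.25, Y = 0.25, D = 0.25),
    aa_weights = list(E = c(coulomb_sc_intra = -2.5)))
  ds <- generate_feature_dataset(spec)
  folds <- make_cluster_folds(ds$table$cluster_id, k_outer = 3, seed = 19)
  inner <- lapply(folds$outer, function(f)
    list(train_clusters = f$train_clusters,
         test_clusters = f$test_clusters))
  # Glu ddG here depends on a feature outside the baseline set, so the
  # general model does markedly worse on Glu than on the other types
  weak <- detect_weak_amino_acids(ds$table, inner,
                                  small_training_config(19),
                                  floor = 0.55)
  expect_identical(as.character(weak), "E")
  per_aa <- attr(weak, "per_aa")
  expect_setequal(per_aa$wt_aa, c("D", "E", "K", "Y"))
  expect_lt(per_aa$f1[per_aa$wt_aa == "E"],
            min(per_aa$f1[per_aa$wt_aa != "E"]))
})

test_that("selection ties break to the smaller, earlier subset", {
  ds <- generate_feature_dataset(synthetic_feature_spec(n = 200, seed = 6))
  folds <- make_cluster_folds(ds$table$cluster_id, k_outer = 3, seed = 6)
  inner <- lapply(folds$outer, function(f)
    list(train_clusters = f$train_clusters,
         test_clusters = f$test_clusters))
  one <- list(c("vdw_sc_inter", "hbond_sc_inter", "desolv_sc_inter"))
  sel <- select_best_subset(ds$table, one, "E", inner,
                            small_training_config(6))
  expect_identical(sel$feature_ids, one[[1]])   # single candidate unchanged
  # duplicated candidate list: first occurrence wins, result unchanged
  sel2 <- select_best_subset(ds$table, c(one, one), "E", inner,
                             small_training_config(6))
  expect_identical(sel2$feature_ids, one[[1]])
  expect_error(select_best_subset(ds$table, one, "V", inner,
                                  small_training_config(6)),
               "target amino acid")
})
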