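test_that("folds partition positives near-equally and stay disjoint", {
  RD <- matrix(0, 585, 88)
  RD[withr::with_seed(1, sample(585 * 88, 650))] <- 1
  ds <- association_dataset(RD)
  folds <- make_folds(ds, 5, seed = 0)
  expect_equal(vapply(folds, function(f) nrow(f$test_pos), numeric(1)),
               rep(130, 5))
  key <- function(p) paste(p[, 1], p[, 2])
  all_test <- unlist(lapply(folds, function(f) key(f$test_pos)))
  expect_equal(sort(all_test), sort(key(sslrda:::positive_pairs(RD))))
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in folds) {
    expect_equal(nrow(f$train_neg), nrow(f$train_pos))
    expect_equal(nrow(f$test_neg), round(sum(RD == 0) / 5))
    expect_length(intersect(key(f$train_pos), key(f$test_pos)), 0)
    expect_length(intersect(key(f$train_neg), key(f$test_neg)), 0)
    expect_true(all(RD[f$train_neg] == 0))
    expect_true(all(RD[f$test_neg] == 0))
  }
})

test_that("remainder positives spread over the first folds", {
  RD <- matrix(0, 10, 10)
  RD[withr::with_seed(2, sample(100, 7))] <- 1
  folds <- make_folds(association_dataset(RD), 5, seed = 1)
  expect_equal(vapply(folds, function(f) nrow(f$test_pos), numeric(1)),
               c(2, 2, 1, 1, 1))
  expect_error(make_folds(association_dataset(diag(2)), 5), "fewer positives")
})

test_that("fold-restricted graphs keep every node connected", {
  ds <- tiny_dataset()
  folds <- make_folds(ds, 5, seed = 3)
  for (f in folds) {
    ds_tr <- ds
    ds_tr$RD[f$test_pos] <- 0
    g <- graph_from_dataset(ds_tr, top_k = 1)
    expect_true(all(rowSums(g$A) >= 1))
  }
})

test_that("classification metrics reproduce hand values", {
  expect_equal(classification_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)),
               list(auc = 1, aupr = 1, f1 = 1))
  expect_equal(classification_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))$f1, 1)
  expect_equal(classification_metrics(c(0.9, 0.8, 0.4, 0.2),
                                      c(1, 0, 1, 0))$auc, 0.75)
  expect_error(classification_metrics(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC and AUPR agree with count-based oracles under ties", {
  for (i in 1:25) {
    n <- withr::with_seed(i, sample(6:50, 1))
    scores <- withr::with_seed(i + 100,
                               sample(seq(0, 1, 0.1), n, replace = TRUE))
    labels <- withr::with_seed(i + 200, rbinom(n, 1, 0.5))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    m <- classification_metrics(scores, labels)
    expect_equal(m$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(m$aupr, oracle_aupr(scores, labels), tolerance = 1e-12)
  }
})

test_that("per-positive ranks use the midrank convention", {
  expect_equal(per_positive_ranks(1, c(0.1, 0.2)), 1)
  expect_equal(per_positive_ranks(0, rep(0.5, 4)), 5)
  expect_equal(per_positive_ranks(0.5, c(0.5, 0.5, 0.1, 0.2)), 2)
  for (i in 1:20) {
    pos <- withr::with_seed(i, sample(seq(0, 1, 0.2), 4, replace = TRUE))
    neg <- withr::with_seed(i + 50, sample(seq(0, 1, 0.2), 9, replace = TRUE))
    expect_equal(per_positive_ranks(pos, neg), oracle_ranks(pos, neg))
  }
})

test_that("rank summaries match their definitions", {
  rk <- c(1, 2, 6)
  expect_equal(mean_rank(rk), 3)
  expect_equal(mrr(rk), 5 / 9)
  expect_equal(hits_at_n(c(1, 5, 20), 10), 2 / 3)
  expect_true(hits_at_n(rk, 10) <= hits_at_n(rk, 50))
  expect_gte(mrr(rk), 1 / mean_rank(rk))  # Jensen
})

test_that("local ranking groups by the shared entity", {
  pairs <- rbind(c(1, 1), c(2, 1), c(3, 1), c(4, 1),  # disease 1
                 c(1, 2), c(2, 2))                     # disease 2
  scores <- c(0.9, 0.1, 0.2, 0.3, 0.8, 0.9)
  labels <- c(1, 0, 0, 0, 1, 0)
  out <- local_ranks(pairs, scores, labels, "disease")
  # group 1: positive tops 3 negatives -> rank 1; group 2: rank 2
  expect_equal(sort(out$ranks), c(1, 2))
  expect_equal(out$mr, 1.5)
  # two groups with ranks {1} and {3}
  pairs2 <- rbind(c(1, 1), c(2, 1), c(1, 2), c(2, 2), c(3, 2), c(4, 2))
  out2 <- local_ranks(pairs2, c(1, 0, 0.1, 0.5, 0.6, 0.05),
                      c(1, 0, 1, 0, 0, 0), "disease")
  expect_equal(out2$mr, 2)
  expect_equal(out2$mrr, 2 / 3)
  # a group without negatives contributes rank 1
  out3 <- local_ranks(rbind(c(1, 1)), 0.01, 1, "disease")
  expect_equal(out3$ranks, 1)
})

test_that("cross-validated evaluation is deterministic and well-formed", {
  ds <- tiny_dataset()
  rep1 <- evaluate_cv(ds, "gm_homo", config = fast_gm(), n_folds = 5,
                      seed = 4, n_trees = 30)
  rep2 <- evaluate_cv(ds, "gm_homo", config = fast_gm(), n_folds = 5,
                      seed = 4, n_trees = 30)
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_equal(nrow(rep1$per_fold), 5)
  m <- rep1$mean
  expect_true(m["hits10"] <= m["hits50"] && m["hits50"] <= m["hits100"])
  expect_gte(m["mr"], 1)
  expect_true(m["mrr"] > 0 && m["mrr"] <= 1)
  expect_gte(m["mrr"], 1 / m["mr"])
  expect_true(all(c("mr_l_r", "mr_l_d", "mrr_l_r", "mrr_l_d") %in% names(m)))
  # pooled global ranking mode is exposed and differs in general
  rep3 <- evaluate_cv(ds, "gm_homo", config = fast_gm(), n_folds = 5,
                      seed = 4, n_trees = 30, global_ranking = "pooled")
  expect_equal(rep3$per_fold$auc, rep1$per_fold$auc)
  expect_error(evaluate_cv(ds, "nonsense"), "unknown model")
})
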