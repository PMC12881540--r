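#' Build cross-validation folds
#'
#' Known associations are shuffled (seeded) and partitioned into
#' `n_folds` near-equal parts; each part serves once as test positives while
#' the rest build the training graph and supervise the classifier. Training
#' negatives are an equal-size uniform sample of unknown pairs; test
#' negatives are a uniform sample of `round(|unknown| / n_folds)` unknown
#' pairs disjoint from the training negatives.
#'
#' @param dataset an `association_dataset`.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return list of `fold_split` objects with fields `fold_id`, `train_pos`,
#'   `train_neg`, `test_pos`, `test_neg` (2-column index matrices).
#' @export
make_folds <- function(dataset, n_folds = 5, seed = 0) {
  stopifnot(inherits(dataset, "association_dataset"), n_folds >= 2)
  RD <- dataset$RD
  pos <- positive_pairs(RD)
  npos <- nrow(pos)
  if (npos < n_folds) stop("fewer positives than folds")
  unknown <- which(RD == 0)
  n_test_neg <- round(length(unknown) / n_folds)
  sizes <- rep(npos %/% n_folds, n_folds)
  extra <- npos %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  perm <- withr::with_seed(as.integer(seed), sample.int(npos))
  fold_of <- rep(seq_len(n_folds), times = sizes)
  r <- nrow(RD)
  lapply(seq_len(n_folds), function(f) {
    test_ix <- perm[fold_of == f]
    test_pos <- pos[test_ix, , drop = FALSE]
    train_pos <- pos[-test_ix, , drop = FALSE]
    train_neg <- sample_unknown_pairs(RD, nrow(train_pos),
                                      epoch_seed(seed, f, 21))
    tn_lin <- (train_neg[, 2] - 1) * r + train_neg[, 1]
    test_neg_lin <- withr::with_seed(
      epoch_seed(seed, f, 22),
      sample(setdiff(unknown, tn_lin), n_test_neg))
    test_neg <- cbind(rna = ((test_neg_lin - 1) %% r) + 1,
                      dis = ((test_neg_lin - 1) %/% r) + 1)
    structure(list(fold_id = f, train_pos = train_pos,
                   train_neg = train_neg, test_pos = test_pos,
                   test_neg = test_neg),
              class = "fold_split")
  })
}

#' Classification metrics: AUC, AUPR, F1
#'
#' AUC uses the rank (Wilcoxon) construction with midranks for ties; AUPR
#' is the step-wise integration of the precision-recall curve over distinct
#' score thresholds; F1 is computed at the 0.5 operating point
#' (`score >= 0.5` predicts a link).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (both classes required).
#' @return named list with `auc`, `aupr`, `f1`.
#' @export
classification_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / np
  aupr <- sum(diff(c(0, rec)) * prec)
  pred <- as.integer(scores >= 0.5)
  tp2 <- sum(pred == 1 & labels == 1)
  f1 <- if (tp2 == 0) 0 else {
    p <- tp2 / sum(pred == 1)
    r <- tp2 / np
    2 * p * r / (p + r)
  }
  list(auc = auc, aupr = aupr, f1 = f1)
}

#' Per-positive ranks against a shared negative pool
#'
#' Knowledge-graph convention: every positive is ranked independently
#' against all negatives, `rank_i = 1 + #{neg > pos_i} + 0.5 * #{neg ==
#' pos_i}` (midrank tie handling).
#'
#' @param pos_scores,neg_scores numeric score vectors.
#' @return numeric vector of ranks, each `>= 1`.
#' @export
per_positive_ranks <- function(pos_scores, neg_scores) {
  stopifnot(length(pos_scores) >= 1, length(neg_scores) >= 1)
  vapply(pos_scores, function(p) {
    1 + sum(neg_scores > p) + 0.5 * sum(neg_scores == p)
  }, numeric(1))
}

#' Ranking summary metrics
#'
#' `mean_rank` is the arithmetic mean of the positive ranks; `mrr` the mean
#' reciprocal rank; `hits_at_n` the fraction of positives ranked within the
#' top `N`. By Jensen's inequality `mrr >= 1 / mean_rank`.
#'
#' @param ranks numeric vector of ranks (`>= 1`).
#' @param N cutoff for `hits_at_n`.
#' @return scalar metric value.
#' @export
mean_rank <- function(ranks) {
  stopifnot(length(ranks) >= 1)
  mean(ranks)
}

#' @rdname mean_rank
#' @export
mrr <- function(ranks) {
  stopifnot(length(ranks) >= 1)
  mean(1 / ranks)
}

#' @rdname mean_rank
#' @export
hits_at_n <- function(ranks, N) {
  stopifnot(length(ranks) >= 1)
  mean(ranks <= N)
}

#' Local (per-entity) ranking metrics
#'
#' Test pairs are grouped by shared disease (`group_by = "disease"`: rank
#' the candidate ncRNAs, the `_L_R` metrics) or by shared ncRNA
#' (`group_by = "rna"`: rank the candidate diseases, `_L_D`). Within each
#' group every positive is ranked against that group's negatives only;
#' a group without negatives contributes rank 1 for its positives. Groups
#' without positives are skipped. MR and MRR aggregate over all positives
#' across groups.
#'
#' @param pairs 2-column index matrix of test pairs (rna, disease).
#' @param scores prediction scores aligned with `pairs`.
#' @param labels binary labels aligned with `pairs`.
#' @param group_by `"disease"` or `"rna"`.
#' @return list with `mr`, `mrr` and the vector of local `ranks`.
#' @export
local_ranks <- function(pairs, scores, labels, group_by = c("disease", "rna")) {
  group_by <- match.arg(group_by)
  key <- if (group_by == "disease") pairs[, 2] else pairs[, 1]
  labels <- as.integer(labels)
  ranks <- numeric(0)
  for (g in unique(key)) {
    in_g <- key == g
    ps <- scores[in_g & labels == 1]
    ns <- scores[in_g & labels == 0]
    if (length(ps) == 0) next
    ranks <- c(ranks, if (length(ns) == 0) rep(1, length(ps))
               else per_positive_ranks(ps, ns))
  }
  if (length(ranks) == 0) stop("no positives in any group")
  list(mr = mean_rank(ranks), mrr = mrr(ranks), ranks = ranks)
}

# All metrics for one fold's scored test set.
fold_metrics <- function(pairs, scores, labels,
                         global_ranking = c("per_positive", "pooled")) {
  global_ranking <- match.arg(global_ranking)
  labels <- as.integer(labels)
  cls <- classification_metrics(scores, labels)
  if (global_ranking == "per_positive") {
    ranks <- per_positive_ranks(scores[labels == 1], scores[labels == 0])
  } else {
    allrk <- rank(-scores, ties.method = "average")
    ranks <- allrk[labels == 1]
  }
  lr <- local_ranks(pairs, scores, labels, "disease")
  ld <- local_ranks(pairs, scores, labels, "rna")
  c(cls,
    list(mr = mean_rank(ranks), mrr = mrr(ranks),
         hits10 = hits_at_n(ranks, 10), hits50 = hits_at_n(ranks, 50),
         hits100 = hits_at_n(ranks, 100),
         mr_l_r = lr$mr, mrr_l_r = lr$mrr,
         mr_l_d = ld$mr, mrr_l_d = ld$mrr))
}

#' Train an embedding engine by name
#'
#' Dispatches to [train_gm()], [train_gh()] or [train_ma()] according to the
#' sub-model name `<engine>_<graph>` with engine in `gm`, `gh`, `ma` and
#' graph in `homo`, `hete`.
#'
#' @param dataset an `association_dataset`.
#' @param model sub-model name, e.g. `"gm_homo"`.
#' @param config engine configuration; `NULL` for that engine's defaults.
#' @param train_pairs supervised positive pairs (ignored by the `ma` engine).
#' @param top_k neighbours kept when binarizing similarities.
#' @return an [embedding_set()].
#' @export
train_embeddings <- function(dataset, model, config = NULL,
                             train_pairs = NULL, top_k = 5) {
  parts <- strsplit(model, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("gm", "gh", "ma") ||
      !parts[2] %in% c("homo", "hete")) {
    stop("unknown model '", model,
         "'; expected <gm|gh|ma>_<homo|hete>")
  }
  engine <- parts[1]; variant <- parts[2]
  switch(engine,
    gm = train_gm(dataset, config %||% gm_config(), variant,
                  train_pairs, top_k),
    gh = train_gh(dataset, config %||% gh_config(), variant,
                  train_pairs, top_k),
    ma = train_ma(dataset, config %||% ma_config(), variant, top_k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Five-fold cross-validated evaluation of a sub-model
#'
#' For each fold the training graph is rebuilt from the training positives
#' only (similarity edges are always retained), the selected engine learns
#' embeddings, the predictor is fitted on the fold's labelled training
#' pairs, the test pairs are scored, and classification plus ranking
#' metrics are computed. The engine and predictor seeds are derived from
#' `seed` and the fold id, so the whole run is deterministic.
#'
#' @param dataset an `association_dataset`.
#' @param model sub-model name (see [train_embeddings()]).
#' @param config engine configuration; `NULL` for defaults. The engine seed
#'   is overridden per fold.
#' @param n_folds number of folds.
#' @param seed integer master seed.
#' @param top_k similarity neighbours per row.
#' @param n_trees trees in the predictor ensemble.
#' @param backend predictor backend (see [fit_predictor()]).
#' @param global_ranking `"per_positive"` ranks each test positive against
#'   all test negatives (knowledge-graph corruption convention, the
#'   default); `"pooled"` ranks within a single descending list.
#' @return object of class `metrics_report`: list with `per_fold` (data
#'   frame, one row per fold) and `mean` (named numeric vector).
#' @export
evaluate_cv <- function(dataset, model = "gm_homo", config = NULL,
                        n_folds = 5, seed = 0, top_k = 5, n_trees = 100,
                        backend = "extra_trees",
                        global_ranking = "per_positive") {
  folds <- make_folds(dataset, n_folds, seed)
  rows <- lapply(folds, function(fold) {
    ds_tr <- dataset
    ds_tr$RD[fold$test_pos] <- 0
    cfg <- config %||% switch(substr(model, 1, 2),
                              gm = gm_config(), gh = gh_config(),
                              ma = ma_config())
    cfg$seed <- epoch_seed(seed, fold$fold_id, 31)
    emb <- train_embeddings(ds_tr, model, cfg,
                            train_pairs = fold$train_pos, top_k = top_k)
    tr_pairs <- rbind(fold$train_pos, fold$train_neg)
    tr_labels <- rep(c(1, 0), c(nrow(fold$train_pos), nrow(fold$train_neg)))
    predictor <- fit_predictor(
      pair_features(emb, tr_pairs, tr_labels), n_trees,
      seed = epoch_seed(seed, fold$fold_id, 32), backend = backend)
    te_pairs <- rbind(fold$test_pos, fold$test_neg)
    te_labels <- rep(c(1, 0), c(nrow(fold$test_pos), nrow(fold$test_neg)))
    scores <- score_pairs(predictor, pair_features(emb, te_pairs))
    c(list(fold = fold$fold_id),
      fold_metrics(te_pairs, scores, te_labels, global_ranking))
  })
  per_fold <- do.call(rbind, lapply(rows, as.data.frame))
  means <- colMeans(per_fold[, setdiff(names(per_fold), "fold")])
  structure(list(per_fold = per_fold, mean = means, model = model),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report for %s (%d folds)\n", x$model,
              nrow(x$per_fold)))
  print(round(x$mean, 5))
  invisible(x)
}
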