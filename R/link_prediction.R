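#' Pair feature table
#'
#' The feature row of an ncRNA-disease pair is the concatenation of the two
#' node embeddings, `[Z_rna(i) || Z_dis(j)]`, so its width is twice the
#' embedding dimension.
#'
#' @param embeddings an [embedding_set()].
#' @param pairs 2-column index matrix (rna, disease), 1-based.
#' @param labels optional binary label vector of length `nrow(pairs)`.
#' @return object of class `pair_feature_table` with fields `pairs`,
#'   `features`, `labels`.
#' @export
pair_features <- function(embeddings, pairs, labels = NULL) {
  stopifnot(inherits(embeddings, "embedding_set"))
  pairs <- as.matrix(pairs)
  if (nrow(pairs) > 0) {
    if (min(pairs[, 1]) < 1 || max(pairs[, 1]) > embeddings$r ||
        min(pairs[, 2]) < 1 || max(pairs[, 2]) > embeddings$d) {
      stop("pair index out of range")
    }
  }
  if (!is.null(labels)) stopifnot(length(labels) == nrow(pairs))
  Zr <- rna_embeddings(embeddings)
  Zd <- disease_embeddings(embeddings)
  feat <- cbind(Zr[pairs[, 1], , drop = FALSE],
                Zd[pairs[, 2], , drop = FALSE])
  structure(list(pairs = pairs, features = feat, labels = labels),
            class = "pair_feature_table")
}

#' Fit the association predictor
#'
#' The predictor of record is an ensemble of extremely randomized trees
#' (random split points, no bootstrap, full sample per tree) fitted as a
#' probability forest; a plain logistic regression backend is available for
#' comparison. Both classes must be present. Deterministic given `seed`.
#'
#' @param table a [pair_features()] table with labels.
#' @param n_trees number of trees in the ensemble.
#' @param seed integer seed.
#' @param backend `"extra_trees"` or `"logistic"`.
#' @return object of class `predictor_model`.
#' @export
fit_predictor <- function(table, n_trees = 100, seed = 0,
                          backend = c("extra_trees", "logistic")) {
  backend <- match.arg(backend)
  stopifnot(inherits(table, "pair_feature_table"), !is.null(table$labels))
  y <- as.integer(table$labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- table$features
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (backend == "extra_trees") {
    df <- data.frame(y = factor(y, levels = c(0, 1)), X)
    fit <- ranger::ranger(
      y ~ ., data = df, num.trees = n_trees,
      splitrule = "extratrees", num.random.splits = 1,
      replace = FALSE, sample.fraction = 1,
      probability = TRUE, seed = as.integer(seed), num.threads = 1)
  } else {
    df <- data.frame(y = y, X)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  }
  structure(list(fit = fit, backend = backend, n_features = ncol(X)),
            class = "predictor_model")
}

#' Score ncRNA-disease pairs
#'
#' For the tree ensemble the score is the fraction of trees voting for the
#' positive class; for the logistic backend, the fitted probability. Higher
#' scores mean the pair is more likely to be associated. Scores lie in
#' `[0, 1]`.
#'
#' @param model a [fit_predictor()] model.
#' @param table a [pair_features()] table.
#' @return numeric score vector, one per pair.
#' @export
score_pairs <- function(model, table) {
  stopifnot(inherits(model, "predictor_model"),
            inherits(table, "pair_feature_table"))
  X <- table$features
  if (ncol(X) != model$n_features) {
    stop(sprintf("feature width mismatch: got %d, model expects %d",
                 ncol(X), model$n_features))
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- data.frame(X)
  if (model$backend == "extra_trees") {
    pr <- stats::predict(model$fit, data = df, num.threads = 1)$predictions
    unname(pr[, "1"])
  } else {
    unname(stats::predict(model$fit, newdata = df, type = "response"))
  }
}

#' Rank candidate partners for one entity
#'
#' Case-study mode: all unknown pairs involving the queried disease (or
#' ncRNA) are scored and returned as a descending ranking of candidates.
#'
#' @param model a fitted [fit_predictor()] model.
#' @param embeddings the [embedding_set()] the model was trained on.
#' @param dataset the `association_dataset` (known links are excluded).
#' @param disease_id,rna_id exactly one of the two identifiers.
#' @return data frame with columns `rna_id`, `disease_id`, `score`, sorted
#'   by descending score; zero rows (with a warning) when every pair for the
#'   entity is already known.
#' @export
rank_candidates <- function(model, embeddings, dataset,
                            disease_id = NULL, rna_id = NULL) {
  stopifnot(xor(is.null(disease_id), is.null(rna_id)))
  lookup <- function(id, ids, what) {
    ix <- match(id, ids)
    if (is.na(ix)) {
      near <- utils::head(ids[order(utils::adist(id, ids))], 3)
      stop(sprintf("unknown %s '%s'; nearest labels: %s", what, id,
                   paste(near, collapse = ", ")))
    }
    ix
  }
  if (!is.null(disease_id)) {
    j <- lookup(disease_id, dataset$disease_ids, "disease")
    cand <- which(dataset$RD[, j] == 0)
    pairs <- cbind(rna = cand, dis = rep(j, length(cand)))
  } else {
    i <- lookup(rna_id, dataset$rna_ids, "ncRNA")
    cand <- which(dataset$RD[i, ] == 0)
    pairs <- cbind(rna = rep(i, length(cand)), dis = cand)
  }
  if (nrow(pairs) == 0) {
    warning("all pairs for this entity are already known associations")
    return(data.frame(rna_id = character(), disease_id = character(),
                      score = numeric()))
  }
  sc <- score_pairs(model, pair_features(embeddings, pairs))
  out <- data.frame(rna_id = dataset$rna_ids[pairs[, 1]],
                    disease_id = dataset$disease_ids[pairs[, 2]],
                    score = sc)
  out[order(-out$score), , drop = FALSE]
}
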