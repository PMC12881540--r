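# Contrastive engine "GM": graph-propagated structural features versus MLP
# attribute features. The homogeneous variant trains on the spliced
# similarity/association graph with triplet-margin contrast plus a weakly
# weighted pairwise-margin supervision term; the bipartite variant keeps the
# two node types separate and trains with InfoNCE per type.

# Objective builders return list(value, grads) for the current parameter
# values; the same builders back the finite-difference gradient checks.

gm_homo_objective <- function(params, inputs) {
  cfg <- inputs$config
  eval_objective(params, function(pn) {
    O <- ad_relu(pn$W_o)   # X is one-hot, so X %*% W_o == W_o
    Z <- ad_relu(ad_matmul(inputs$A_hat, O))
    O_nei <- ad_matmul(inputs$M_nei, O)
    O_shf <- lapply(inputs$perms, function(p) ad_permute_rows(O, p))
    L_ctr <- ad_triplet_ctr(O, Z, O_nei, O_shf, cfg$alpha, cfg$beta,
                            cfg$lambda1, cfg$lambda2, cfg$lambda3)
    L_sup <- ad_pairwise_margin(ad_pair_scores(Z, inputs$pos_pairs, inputs$r),
                                ad_pair_scores(Z, inputs$neg_pairs, inputs$r))
    ad_add(ad_scale(L_sup, cfg$lambda4), ad_scale(L_ctr, cfg$lambda5))
  })
}

gm_hete_objective <- function(params, inputs) {
  cfg <- inputs$config
  eval_objective(params, function(pn) {
    O_r <- ad_relu(pn$W_or)
    O_d <- ad_relu(pn$W_od)
    Z_r <- ad_relu(ad_matmul(inputs$P_rna, O_d))
    Z_d <- ad_relu(ad_matmul(inputs$P_dis, O_r))
    ad_add(ad_infonce(O_r, Z_r, cfg$tau), ad_infonce(O_d, Z_d, cfg$tau))
  })
}

gm_homo_inputs <- function(graph, RD, pos_pairs, config, ep) {
  n <- graph$r + graph$d
  list(
    config = config, r = graph$r, A_hat = graph$A_hat,
    M_nei = neighbor_matrix(graph$A, config$n_nei,
                            epoch_seed(config$seed, ep, 1)),
    perms = shuffle_perms(n, config$m, epoch_seed(config$seed, ep, 2)),
    pos_pairs = pos_pairs,
    neg_pairs = sample_unknown_pairs(RD, nrow(pos_pairs),
                                     epoch_seed(config$seed, ep, 3))
  )
}

#' Train the attribute-versus-structure contrastive engine
#'
#' Learns node embeddings by contrasting a one-layer MLP attribute view
#' `O = ReLU(X W_o)` (with one-hot `X`) against the weight-free
#' graph-propagated view `Z = ReLU(A_hat O)`. The homogeneous variant
#' (`"homo"`) works on the spliced similarity/association graph and
#' minimizes `lambda4 * L_sup + lambda5 * L_ctr`, where the contrastive part
#' is the triplet-margin loss over neighborhood and row-shuffled views (see
#' [triplet_contrastive_loss()]) and the supervision part is the
#' pairwise-margin loss on embedding dot products of the training positives
#' against freshly sampled unknown pairs. The bipartite variant (`"hete"`)
#' trains one MLP per node type with cross-type propagation and the summed
#' per-type InfoNCE objective. Optimization is full-graph Adam for
#' `config$epochs` epochs; all sampling is seeded, so results are
#' deterministic given `config$seed`.
#'
#' @param dataset an `association_dataset`; its `RD` defines the training
#'   graph (use the fold-restricted matrix during cross-validation).
#' @param config a [gm_config()].
#' @param variant `"homo"` or `"hete"`.
#' @param train_pairs optional 2-column index matrix (rna, disease) of
#'   supervised positives; defaults to all links of `dataset$RD`.
#' @param top_k neighbours kept per row when binarizing similarities.
#' @return an [embedding_set()] carrying `Z` (structural features) and the
#'   per-epoch loss history.
#' @export
train_gm <- function(dataset, config = gm_config(),
                     variant = c("homo", "hete"),
                     train_pairs = NULL, top_k = 5) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset, "association_dataset"),
            inherits(config, "gm_config"))
  RD <- dataset$RD
  r <- nrow(RD); d <- ncol(RD)
  if (is.null(train_pairs)) train_pairs <- positive_pairs(RD)
  train_pairs <- as.matrix(train_pairs)

  if (variant == "homo") {
    graph <- graph_from_dataset(dataset, top_k)
    params <- withr::with_seed(config$seed, list(
      W_o = glorot_init(r + d, config$n_hidden)))
    fit <- run_training(
      params,
      function(p, ep) gm_homo_objective(
        p, gm_homo_inputs(graph, RD, train_pairs, config, ep)),
      config$epochs, config$lr, config$weight_decay)
    O <- attribute_features(diag(r + d), fit$params$W_o)
    Z <- structure_features(graph$A_hat, O)
  } else {
    het <- build_heterogeneous(RD)
    params <- withr::with_seed(config$seed, list(
      W_or = glorot_init(r, config$n_hidden),
      W_od = glorot_init(d, config$n_hidden)))
    inputs <- list(config = config, P_rna = het$P_rna, P_dis = het$P_dis)
    fit <- run_training(
      params,
      function(p, ep) gm_hete_objective(p, inputs),
      config$epochs, config$lr, config$weight_decay)
    O_r <- attribute_features(diag(r), fit$params$W_or)
    O_d <- attribute_features(diag(d), fit$params$W_od)
    Z <- rbind(structure_features(het$P_rna, O_d),
               structure_features(het$P_dis, O_r))
  }
  embedding_set(Z, r, d, dataset$rna_ids, dataset$disease_ids,
                loss_history = fit$history)
}
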