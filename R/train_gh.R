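# Contrastive engine "GH": local graph-convolution features versus global
# features from a learned parameterized hypergraph. Nodes are softly
# assigned to h hyperedges through H = E W_H; hyperedge features are
# refined by a residual stack F^(i) = ReLU(W^(i-1) F^(i-1)) + F^(i-1) and
# projected back to nodes as O = ReLU(H F^(l)).

# Hypergraph global features on the tape; `Ws` is the list of h x h layer
# matrices (length l).
ad_hypergraph_global <- function(E, W_H, Ws) {
  H <- ad_matmul(E, W_H)
  F_l <- ad_matmul_tn(H, E)
  for (W in Ws) {
    F_l <- ad_add(ad_relu(ad_matmul(W, F_l)), F_l)
  }
  ad_relu(ad_matmul(H, F_l))
}

#' Local graph-convolution features of the hypergraph engine
#'
#' `Z = ReLU(A_hat E)` with a learnable node embedding matrix `E`.
#'
#' @param A_hat normalized adjacency.
#' @param E node embedding matrix (`nodes x e`).
#' @return matrix `nodes x e`.
#' @export
local_features <- function(A_hat, E) {
  pmax(A_hat %*% E, 0)
}

#' Global features through the learned hypergraph stack
#'
#' Computes the node-to-hyperedge assignment `H = E W_H`, initial hyperedge
#' features `F0 = t(H) E`, `l` residual refinement layers
#' `F_i = ReLU(W_i F_{i-1}) + F_{i-1}`, and the node-level global view
#' `O = ReLU(H F_l)`. With all layer matrices zero, the residual path makes
#' `O` independent of `l`.
#'
#' @param E node embedding matrix (`nodes x e`).
#' @param W_H hyperedge assignment matrix (`e x h`).
#' @param layer_weights list of `h x h` layer matrices (length `l`).
#' @return matrix `nodes x e`.
#' @export
hypergraph_global <- function(E, W_H, layer_weights) {
  H <- E %*% W_H
  F_l <- t(H) %*% E
  for (W in layer_weights) {
    F_l <- pmax(W %*% F_l, 0) + F_l
  }
  pmax(H %*% F_l, 0)
}

gh_layer_names <- function(l) paste0("W", seq_len(l) - 1)

gh_homo_objective <- function(params, inputs) {
  cfg <- inputs$config
  eval_objective(params, function(pn) {
    Z <- ad_relu(ad_matmul(inputs$A_hat, pn$E))
    O <- ad_hypergraph_global(pn$E, pn$W_H, pn[gh_layer_names(cfg$l)])
    O_nei <- ad_matmul(inputs$M_nei, O)
    O_shf <- lapply(inputs$perms, function(p) ad_permute_rows(O, p))
    L_ctr <- ad_triplet_ctr(O, Z, O_nei, O_shf, cfg$alpha, cfg$beta,
                            5, 5, 1)
    L_sup <- ad_pairwise_margin(ad_pair_scores(Z, inputs$pos_pairs, inputs$r),
                                ad_pair_scores(Z, inputs$neg_pairs, inputs$r))
    decay <- NULL
    for (p in pn) {
      decay <- if (is.null(decay)) ad_frob2(p) else ad_add(decay, ad_frob2(p))
    }
    ad_add(ad_add(ad_scale(L_sup, cfg$lambda1), ad_scale(L_ctr, cfg$lambda2)),
           ad_scale(decay, cfg$lambda3))
  })
}

gh_hete_objective <- function(params, inputs) {
  cfg <- inputs$config
  ln <- gh_layer_names(cfg$l)
  eval_objective(params, function(pn) {
    Z_r <- ad_relu(ad_matmul(inputs$P_rna, pn$E_d))
    Z_d <- ad_relu(ad_matmul(inputs$P_dis, pn$E_r))
    O_r <- ad_hypergraph_global(pn$E_r, pn$W_H_r, pn[paste0(ln, "_r")])
    O_d <- ad_hypergraph_global(pn$E_d, pn$W_H_d, pn[paste0(ln, "_d")])
    L_ctr <- ad_add(ad_infonce(O_r, Z_r, cfg$tau),
                    ad_infonce(O_d, Z_d, cfg$tau))
    L_sup <- ad_pairwise_margin(
      ad_pair_scores2(Z_r, Z_d, inputs$pos_pairs),
      ad_pair_scores2(Z_r, Z_d, inputs$neg_pairs))
    decay <- NULL
    for (p in pn) {
      decay <- if (is.null(decay)) ad_frob2(p) else ad_add(decay, ad_frob2(p))
    }
    ad_add(ad_add(ad_scale(L_sup, cfg$lambda1), ad_scale(L_ctr, cfg$lambda2)),
           ad_scale(decay, cfg$lambda3))
  })
}

gh_homo_inputs <- function(graph, RD, pos_pairs, config, ep) {
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

#' Train the local-versus-hypergraph contrastive engine
#'
#' Learns a node embedding matrix `E` by contrasting the local
#' graph-convolution view `Z = ReLU(A_hat E)` against a global view `O`
#' computed through a learned parameterized hypergraph
#' ([hypergraph_global()]). The homogeneous variant uses the triplet-margin
#' contrast (shuffling the global view) plus the pairwise-margin supervision
#' on `Z` dot products; the bipartite variant runs per-type hypergraph
#' machinery with cross-type propagation and summed per-type InfoNCE. The
#' total objective is `lambda1 * L_sup + lambda2 * L_ctr + lambda3 *
#' ||Theta||_F^2`, with `Theta` collecting every learnable matrix. The
#' downstream embedding is the local view `Z`. Deterministic given
#' `config$seed`.
#'
#' @inheritParams train_gm
#' @param config a [gh_config()].
#' @return an [embedding_set()] with the per-epoch loss history.
#' @export
train_gh <- function(dataset, config = gh_config(),
                     variant = c("homo", "hete"),
                     train_pairs = NULL, top_k = 5) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset, "association_dataset"),
            inherits(config, "gh_config"))
  RD <- dataset$RD
  r <- nrow(RD); d <- ncol(RD)
  if (is.null(train_pairs)) train_pairs <- positive_pairs(RD)
  train_pairs <- as.matrix(train_pairs)
  ln <- gh_layer_names(config$l)

  if (variant == "homo") {
    graph <- graph_from_dataset(dataset, top_k)
    params <- withr::with_seed(config$seed, {
      p <- list(E = glorot_init(r + d, config$e),
                W_H = glorot_init(config$e, config$h))
      for (nm in ln) p[[nm]] <- glorot_init(config$h, config$h)
      p
    })
    fit <- run_training(
      params,
      function(p, ep) gh_homo_objective(
        p, gh_homo_inputs(graph, RD, train_pairs, config, ep)),
      config$epochs, config$lr)
    Z <- local_features(graph$A_hat, fit$params$E)
  } else {
    het <- build_heterogeneous(RD)
    params <- withr::with_seed(config$seed, {
      p <- list(E_r = glorot_init(r, config$e),
                E_d = glorot_init(d, config$e),
                W_H_r = glorot_init(config$e, config$h),
                W_H_d = glorot_init(config$e, config$h))
      for (nm in ln) {
        p[[paste0(nm, "_r")]] <- glorot_init(config$h, config$h)
        p[[paste0(nm, "_d")]] <- glorot_init(config$h, config$h)
      }
      p
    })
    inputs_fixed <- list(config = config, P_rna = het$P_rna,
                         P_dis = het$P_dis)
    fit <- run_training(
      params,
      function(p, ep) {
        inputs <- inputs_fixed
        inputs$pos_pairs <- train_pairs
        inputs$neg_pairs <- sample_unknown_pairs(
          RD, nrow(train_pairs), epoch_seed(config$seed, ep, 3))
        gh_hete_objective(p, inputs)
      },
      config$epochs, config$lr)
    Z <- rbind(local_features(het$P_rna, fit$params$E_d),
               local_features(het$P_dis, fit$params$E_r))
  }
  embedding_set(Z, r, d, dataset$rna_ids, dataset$disease_ids,
                loss_history = fit$history)
}
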