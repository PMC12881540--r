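# Generative engine "MA": masked node-feature reconstruction. A fraction of
# node rows is replaced by a learnable input mask vector, a 2-layer
# propagation encoder maps to latent space, masked rows are re-masked with a
# learnable latent vector, a 1-layer propagation decoder reconstructs in
# latent space, and an InfoNCE loss over the masked rows aligns each node's
# reconstruction with its own latent row.

#' Propagation encoder of the masked autoencoder
#'
#' Two graph-convolution layers with learnable weights:
#' `Z = ReLU(A_hat ReLU(A_hat X W1) W2)`.
#'
#' @param A_hat normalized adjacency (or any propagation operator).
#' @param X node features.
#' @param W1,W2 weight matrices.
#' @return latent feature matrix.
#' @export
ma_encode <- function(A_hat, X, W1, W2) {
  pmax(A_hat %*% pmax(A_hat %*% X %*% W1, 0) %*% W2, 0)
}

#' Re-mask latent rows with a learnable latent vector
#'
#' @param Z latent features.
#' @param masked masked node indices (empty set returns `Z` unchanged).
#' @param z_prime latent mask vector of length `ncol(Z)`.
#' @return `Z` with the masked rows replaced.
#' @export
ma_remask <- function(Z, masked, z_prime) {
  if (length(masked) == 0) return(Z)
  Z[masked, ] <- matrix(z_prime, length(masked), ncol(Z), byrow = TRUE)
  Z
}

#' Propagation decoder of the masked autoencoder
#'
#' One graph-convolution layer mapping back to the latent width:
#' `M = ReLU(A_hat Z_tilde W3)`.
#'
#' @param A_hat normalized adjacency (or any propagation operator).
#' @param Z_tilde re-masked latent features.
#' @param W3 weight matrix.
#' @return reconstruction matrix with the shape of `Z_tilde`.
#' @export
ma_decode <- function(A_hat, Z_tilde, W3) {
  pmax(A_hat %*% Z_tilde %*% W3, 0)
}

# Per-view masked-reconstruction objective on the tape. `Ah` is the
# (constant) propagation operator, X the constant feature matrix. Returns
# NULL when fewer than 2 nodes are masked (no contrastive signal).
ma_view_loss <- function(pn, suffix, Ah, X, masked, tau) {
  g <- function(nm) pn[[paste0(nm, suffix)]]
  X_hat <- ad_row_replace(X, masked, g("x_prime"))
  H1 <- ad_relu(ad_matmul(ad_matmul(Ah, X_hat), g("W1")))
  Z <- ad_relu(ad_matmul(ad_matmul(Ah, H1), g("W2")))
  Z_tilde <- ad_row_replace(Z, masked, g("z_prime"))
  M <- ad_relu(ad_matmul(ad_matmul(Ah, Z_tilde), g("W3")))
  if (length(masked) < 2) return(NULL)
  ad_infonce(ad_gather_rows(Z, masked), ad_gather_rows(M, masked), tau)
}

ma_homo_objective <- function(params, inputs) {
  cfg <- inputs$config
  eval_objective(params, function(pn) {
    l <- ma_view_loss(pn, "", inputs$A_hat, inputs$X, inputs$masked, cfg$tau)
    if (is.null(l)) stop("fewer than 2 masked nodes: no training signal")
    l
  })
}

ma_hete_objective <- function(params, inputs) {
  cfg <- inputs$config
  eval_objective(params, function(pn) {
    lr_ <- ma_view_loss(pn, "_r", inputs$G_r, inputs$X_r, inputs$masked_r,
                        cfg$tau)
    ld_ <- ma_view_loss(pn, "_d", inputs$G_d, inputs$X_d, inputs$masked_d,
                        cfg$tau)
    if (is.null(lr_) && is.null(ld_)) stop("no masked nodes in either view")
    if (is.null(lr_)) ld_ else if (is.null(ld_)) lr_ else ad_add(lr_, ld_)
  })
}

# Homogeneous feature matrix: similarity rows spliced with associations,
# X = [SR RD; t(RD) SD]. Requires both similarity matrices.
ma_homo_features <- function(dataset) {
  if (is.null(dataset$SR) || is.null(dataset$SD)) {
    stop("the masked-feature engine needs SR and SD similarity matrices")
  }
  rbind(cbind(dataset$SR, dataset$RD), cbind(t(dataset$RD), dataset$SD))
}

ma_mask_indices <- function(n, mask_rate, seed) {
  n_mask <- round(mask_rate * n)
  if (n_mask == 0) stop("nothing to mask: round(mask_rate * n) is 0")
  withr::with_seed(as.integer(seed), sort(sample.int(n, n_mask)))
}

#' Train the masked-feature generative engine
#'
#' Randomly masks `round(mask_rate * n)` node feature rows (replacing them
#' by a learnable vector), encodes with a 2-layer propagation encoder,
#' re-masks the latent rows, decodes with a 1-layer propagation decoder, and
#' minimizes the InfoNCE reconstruction loss over the masked rows (see
#' [reconstruction_infonce()]). The homogeneous variant uses the similarity
#' feature matrix `X = [SR RD; t(RD) SD]` on the spliced graph; the
#' bipartite variant runs a separate encoder/decoder per node type with the
#' two-hop type-internal propagation operators derived from the normalized
#' bipartite adjacency. The mask set is resampled each epoch (seeded). For
#' the downstream embedding the trained encoder is applied to the unmasked
#' features.
#'
#' @inheritParams train_gm
#' @param config an [ma_config()].
#' @return an [embedding_set()] with the per-epoch loss history.
#' @export
train_ma <- function(dataset, config = ma_config(),
                     variant = c("homo", "hete"), top_k = 5) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset, "association_dataset"),
            inherits(config, "ma_config"))
  RD <- dataset$RD
  r <- nrow(RD); d <- ncol(RD)
  k <- config$n_hidden

  if (variant == "homo") {
    graph <- graph_from_dataset(dataset, top_k)
    X <- ma_homo_features(dataset)
    n <- r + d
    params <- withr::with_seed(config$seed, list(
      W1 = glorot_init(n, k), W2 = glorot_init(k, k), W3 = glorot_init(k, k),
      x_prime = matrix(0, 1, n), z_prime = matrix(0, 1, k)))
    fit <- run_training(
      params,
      function(p, ep) ma_homo_objective(p, list(
        config = config, A_hat = graph$A_hat, X = X,
        masked = ma_mask_indices(n, config$mask_rate,
                                 epoch_seed(config$seed, ep)))),
      config$epochs, config$lr)
    Z <- ma_encode(graph$A_hat, X, fit$params$W1, fit$params$W2)
  } else {
    if (is.null(dataset$SR) || is.null(dataset$SD)) {
      stop("the masked-feature engine needs SR and SD similarity matrices")
    }
    het <- build_heterogeneous(RD)
    G_r <- het$P_rna %*% het$P_dis
    G_d <- het$P_dis %*% het$P_rna
    params <- withr::with_seed(config$seed, list(
      W1_r = glorot_init(r, k), W2_r = glorot_init(k, k),
      W3_r = glorot_init(k, k),
      x_prime_r = matrix(0, 1, r), z_prime_r = matrix(0, 1, k),
      W1_d = glorot_init(d, k), W2_d = glorot_init(k, k),
      W3_d = glorot_init(k, k),
      x_prime_d = matrix(0, 1, d), z_prime_d = matrix(0, 1, k)))
    fit <- run_training(
      params,
      function(p, ep) ma_hete_objective(p, list(
        config = config, G_r = G_r, G_d = G_d,
        X_r = dataset$SR, X_d = dataset$SD,
        masked_r = ma_mask_indices(r, config$mask_rate,
                                   epoch_seed(config$seed, ep, 1)),
        masked_d = ma_mask_indices(d, config$mask_rate,
                                   epoch_seed(config$seed, ep, 2)))),
      config$epochs, config$lr)
    Z <- rbind(ma_encode(G_r, dataset$SR, fit$params$W1_r, fit$params$W2_r),
               ma_encode(G_d, dataset$SD, fit$params$W1_d, fit$params$W2_d))
  }
  es <- embedding_set(Z, r, d, dataset$rna_ids, dataset$disease_ids,
                      loss_history = fit$history)
  attr(es, "fit_params") <- fit$params
  es
}
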