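# Feature constructors and self-supervised objectives, in plain numeric
# (vectorized) form. The trainers rebuild the same quantities on the
# autodiff tape; tests check both against explicit-loop oracles.

#' MLP attribute features
#'
#' Single-layer perceptron view of the node attributes: `O = ReLU(X W_o)`.
#'
#' @param X node feature matrix (`nodes x input_dim`).
#' @param W_o weight matrix (`input_dim x n_hidden`).
#' @return matrix `nodes x n_hidden`.
#' @export
attribute_features <- function(X, W_o) {
  pmax(X %*% W_o, 0)
}

#' Graph-propagated structural features
#'
#' Weight-free one-hop propagation of the attribute features through the
#' normalized adjacency, `Z = ReLU(A_hat O)`.
#'
#' @param A_hat normalized adjacency (see [assemble_homogeneous()]).
#' @param O attribute feature matrix.
#' @return matrix with the shape of `O`.
#' @export
structure_features <- function(A_hat, O) {
  pmax(A_hat %*% O, 0)
}

# Row-stochastic neighbor-sampling matrix: row i averages over
# min(n_nei, degree(i)) neighbors sampled without replacement; isolated
# nodes fall back to themselves. Multiplying O by this matrix gives the
# neighborhood view, and it doubles as the constant aggregation operator
# inside the trainers.
neighbor_matrix <- function(A, n_nei = 5, seed = 0) {
  n <- nrow(A)
  M <- matrix(0, n, n)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n)) {
      nb <- which(A[i, ] == 1)
      if (length(nb) == 0) {
        M[i, i] <- 1
      } else {
        take <- min(n_nei, length(nb))
        pick <- if (length(nb) == 1) nb else sample(nb, take)
        M[i, pick] <- 1 / take
      }
    }
  })
  M
}

#' Neighborhood-averaged features
#'
#' For each node, the mean of the attribute rows of up to `n_nei` neighbours
#' sampled uniformly without replacement from its adjacency row; isolated
#' nodes keep their own row.
#'
#' @param A binary adjacency matrix.
#' @param O attribute feature matrix.
#' @param n_nei neighbours sampled per node.
#' @param seed integer seed (sampling is deterministic given the seed).
#' @return matrix with the shape of `O`.
#' @export
neighbor_features <- function(A, O, n_nei = 5, seed = 0) {
  neighbor_matrix(A, n_nei, seed) %*% O
}

# m independent uniformly random row permutations of 1..n.
shuffle_perms <- function(n, m, seed = 0) {
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(m), function(i) sample.int(n))
  })
}

#' Row-shuffled negative views
#'
#' @param O attribute feature matrix.
#' @param m number of shuffled copies.
#' @param seed integer seed.
#' @return list of `m` row permutations of `O`.
#' @export
shuffle_negatives <- function(O, m = 5, seed = 0) {
  perms <- shuffle_perms(nrow(O), m, seed)
  lapply(perms, function(p) O[p, , drop = FALSE])
}

# Mean over nodes of the row-wise Euclidean distance between two matrices —
# the scalar reduction of the matrix-to-matrix distance used by the
# triplet objectives.
mean_row_dist <- function(X, Y) {
  mean(sqrt(rowSums((X - Y)^2)))
}

#' Triplet contrastive loss over attribute, structure, neighborhood and
#' shuffled views
#'
#' Three hinge terms averaged over the `m` shuffled negatives, with
#' `d(X, Y)` the mean row-wise Euclidean distance:
#' `L1 = mean_i max(0, d(O, O_nei) - d(O, O_shf_i) + alpha)` and
#' `L2 = mean_i max(0, d(O, Z) - d(O, O_shf_i) + alpha)` widen the
#' inter-class gap, while
#' `L3 = mean_i max(0, d(O, Z) - d(O, O_shf_i) - alpha - beta)` bounds the
#' intra-class spread. The total is
#' `lambda1 L1 + lambda2 L2 + lambda3 L3`.
#'
#' @param O,Z,O_nei aligned feature matrices (attribute, structure,
#'   neighborhood views).
#' @param O_shf list of shuffled copies of `O` (see [shuffle_negatives()]).
#' @param alpha,beta nonnegative margin parameters.
#' @param lambda1,lambda2,lambda3 term weights.
#' @return nonnegative scalar.
#' @export
triplet_contrastive_loss <- function(O, Z, O_nei, O_shf,
                                     alpha = 0.8, beta = 0.4,
                                     lambda1 = 5, lambda2 = 5, lambda3 = 1) {
  m <- length(O_shf)
  stopifnot(m >= 1)
  d_on <- mean_row_dist(O, O_nei)
  d_oz <- mean_row_dist(O, Z)
  d_os <- vapply(O_shf, function(S) mean_row_dist(O, S), numeric(1))
  L1 <- mean(pmax(0, d_on - d_os + alpha))
  L2 <- mean(pmax(0, d_oz - d_os + alpha))
  L3 <- mean(pmax(0, d_oz - d_os - alpha - beta))
  lambda1 * L1 + lambda2 * L2 + lambda3 * L3
}

#' Pairwise margin (hinge) supervision loss
#'
#' `sum(max(0, 1 - pos + neg))` over aligned positive/negative prediction
#' scores; scores are typically the embedding dot products of sampled
#' training pairs.
#'
#' @param pos_scores,neg_scores numeric vectors or matrices of equal shape.
#' @return nonnegative scalar.
#' @export
pairwise_margin_loss <- function(pos_scores, neg_scores) {
  stopifnot(length(pos_scores) == length(neg_scores))
  sum(pmax(0, 1 - pos_scores + neg_scores))
}

# Row-normalize with zero rows mapped to zero (cosine of a zero vector is
# treated as 0).
normalize_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  inv <- ifelse(nrm > 1e-12, 1 / nrm, 0)
  X * inv
}

#' InfoNCE loss between two aligned views
#'
#' `sum_i -log[ exp(cos(O_i, Z_i)/tau) / sum_j exp(cos(O_i, Z_j)/tau) ]`,
#' the softmax contrastive objective with the matched pair as target.
#' Zero-norm rows contribute cosine 0.
#'
#' @param O,Z row-aligned feature matrices over the same node set.
#' @param tau temperature, `> 0`.
#' @return nonnegative scalar; `n * log(n)` for constant embeddings.
#' @export
infonce_pair_loss <- function(O, Z, tau = 0.5) {
  stopifnot(tau > 0, nrow(O) == nrow(Z))
  S <- normalize_rows(O) %*% t(normalize_rows(Z)) / tau
  mx <- apply(S, 1, max)
  lse <- mx + log(rowSums(exp(S - mx)))
  sum(lse - diag(S))
}

#' Mask node feature rows with a learnable vector
#'
#' Samples `round(mask_rate * n)` node indices uniformly without replacement
#' and replaces their feature rows by the mask vector `x_prime`.
#'
#' @param X feature matrix with at least 2 rows.
#' @param mask_rate fraction of nodes to mask, in `(0, 1)`.
#' @param x_prime mask vector of length `ncol(X)`.
#' @param seed integer seed.
#' @return list with `X_hat` (masked features) and `masked` (index vector).
#' @export
mask_features <- function(X, mask_rate = 0.4, x_prime = NULL, seed = 0) {
  n <- nrow(X)
  stopifnot(n >= 2, mask_rate > 0, mask_rate < 1)
  n_mask <- round(mask_rate * n)
  if (n_mask == 0) stop("nothing to mask: round(mask_rate * n) is 0")
  if (is.null(x_prime)) x_prime <- numeric(ncol(X))
  stopifnot(length(x_prime) == ncol(X))
  masked <- withr::with_seed(as.integer(seed), sort(sample.int(n, n_mask)))
  X_hat <- X
  X_hat[masked, ] <- matrix(x_prime, n_mask, ncol(X), byrow = TRUE)
  list(X_hat = X_hat, masked = masked)
}

#' InfoNCE reconstruction loss over masked nodes
#'
#' Restricted to the masked index set: each masked node's latent row `Z_i`
#' is contrasted with the decoder reconstructions `M_i'` of all masked
#' nodes, with the node's own reconstruction as the positive.
#'
#' @param Z encoder latent features.
#' @param M decoder reconstructions (same shape as `Z`).
#' @param masked masked node indices.
#' @param tau temperature.
#' @return scalar loss; 0 with a warning when only one node is masked.
#' @export
reconstruction_infonce <- function(Z, M, masked, tau = 0.9) {
  stopifnot(length(masked) >= 1)
  if (length(masked) == 1) {
    warning("only one masked node: reconstruction loss is 0")
    return(0)
  }
  infonce_pair_loss(Z[masked, , drop = FALSE], M[masked, , drop = FALSE], tau)
}
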