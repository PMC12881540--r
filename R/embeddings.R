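#' Node embedding set
#'
#' Container for a learned node representation matrix with ncRNA rows first
#' (`1..r`) and disease rows after (`r+1..r+d`), the node order shared by
#' every graph view in the package.
#'
#' @param Z numeric matrix `(r + d) x n_hidden`.
#' @param r,d node counts.
#' @param rna_ids,disease_ids optional identifiers.
#' @param loss_history optional numeric vector of per-epoch training losses.
#' @return object of class `embedding_set`.
#' @export
embedding_set <- function(Z, r, d, rna_ids = NULL, disease_ids = NULL,
                          loss_history = NULL) {
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == r + d)
  structure(list(Z = Z, r = r, d = d, rna_ids = rna_ids,
                 disease_ids = disease_ids, loss_history = loss_history),
            class = "embedding_set")
}

#' @rdname embedding_set
#' @param x an `embedding_set`.
#' @export
rna_embeddings <- function(x) x$Z[seq_len(x$r), , drop = FALSE]

#' @rdname embedding_set
#' @export
disease_embeddings <- function(x) x$Z[x$r + seq_len(x$d), , drop = FALSE]

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("embedding_set: %d ncRNAs + %d diseases, dimension %d\n",
              x$r, x$d, ncol(x$Z)))
  if (!is.null(x$loss_history)) {
    cat(sprintf("  training loss: %.4f -> %.4f over %d epochs\n",
                x$loss_history[1], x$loss_history[length(x$loss_history)],
                length(x$loss_history)))
  }
  invisible(x)
}

#' Engine configurations
#'
#' Defaults follow the grid-searched operating points of the framework:
#' for the attribute-vs-structure contrastive engine (`gm_config`) a hidden
#' width of 128, learning rate 0.005 with weight decay 1e-4, 100 epochs,
#' triplet weights `lambda1 = lambda2 = 5`, `lambda3 = 1`, margins
#' `alpha = 0.8`, `beta = 0.4`, supervised weight `lambda4 = 1e-5` against
#' contrastive weight `lambda5 = 1`; for the local-vs-hypergraph engine
#' (`gh_config`) embedding dimension 128, 50 hyperedges, 2 hyperedge layers
#' and learning rate 1e-3; for the masked-feature autoencoder (`ma_config`)
#' a 2-layer 128-unit encoder, masking rate 0.4, temperature 0.9 and
#' learning rate 0.005. `m` shuffled negatives and `n_nei` sampled
#' neighbours default to 5; the bipartite contrastive variants use
#' temperature `tau`.
#'
#' @param n_hidden,e hidden/embedding width.
#' @param lr learning rate for the Adam optimizer.
#' @param weight_decay L2 penalty added to gradients (gm engine).
#' @param epochs training epochs.
#' @param lambda1,lambda2,lambda3 loss-term weights (triplet terms for the
#'   gm engine; task/contrast/decay weights for the gh engine).
#' @param alpha,beta triplet margins.
#' @param lambda4,lambda5 supervised / contrastive weights (gm engine).
#' @param m number of shuffled negatives.
#' @param n_nei neighbours sampled per node.
#' @param tau InfoNCE temperature.
#' @param h number of hyperedges (gh engine).
#' @param l number of hyperedge layers (gh engine).
#' @param mask_rate fraction of nodes masked (ma engine).
#' @param seed integer seed controlling every random draw in training.
#' @return a classed configuration list.
#' @name engine_config
NULL

#' @rdname engine_config
#' @export
gm_config <- function(n_hidden = 128, lr = 0.005, weight_decay = 1e-4,
                      epochs = 100, lambda1 = 5, lambda2 = 5, lambda3 = 1,
                      alpha = 0.8, beta = 0.4, lambda4 = 1e-5, lambda5 = 1,
                      m = 5, n_nei = 5, tau = 0.5, seed = 0) {
  stopifnot(alpha >= 0, beta >= 0, m >= 1, n_nei >= 1, tau > 0, epochs >= 1)
  structure(as.list(environment()), class = c("gm_config", "engine_config"))
}

#' @rdname engine_config
#' @export
gh_config <- function(e = 128, h = 50, l = 2, lr = 1e-3, epochs = 100,
                      lambda1 = 1, lambda2 = 1, lambda3 = 1e-4,
                      alpha = 0.8, beta = 0.4, m = 5, n_nei = 5, tau = 0.5,
                      seed = 0) {
  stopifnot(e >= 1, h >= 1, l >= 1, epochs >= 1)
  structure(as.list(environment()), class = c("gh_config", "engine_config"))
}

#' @rdname engine_config
#' @export
ma_config <- function(n_hidden = 128, mask_rate = 0.4, tau = 0.9, lr = 0.005,
                      epochs = 100, seed = 0) {
  stopifnot(mask_rate > 0, mask_rate < 1, tau > 0, epochs >= 1)
  structure(as.list(environment()), class = c("ma_config", "engine_config"))
}
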