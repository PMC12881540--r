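#' Top-k binarization of a similarity matrix
#'
#' For each row, the `k` largest off-diagonal entries are set to 1 and all
#' other entries (including the diagonal) to 0, keeping only each node's `k`
#' most similar neighbours so that weakly correlated nodes do not enter the
#' graph. Ties at the k-th value are broken towards the lowest column index.
#' The result is row-wise and therefore not necessarily symmetric.
#'
#' @param S square numeric matrix.
#' @param k number of neighbours to keep per row, `1 <= k < nrow(S)`.
#' @return binary matrix of the same dimension with exactly `k` ones per row.
#' @export
topk_binarize <- function(S, k = 5) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) stop("S must be square")
  if (k < 1 || k >= n) stop(sprintf("k must satisfy 1 <= k < n (k=%d, n=%d)", k, n))
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(-S[i, cand], cand)]
    B[i, ord[seq_len(k)]] <- 1
  }
  B
}

#' Assemble the homogeneous ncRNA-disease graph
#'
#' Splices the (binarized) similarity blocks and the association matrix into
#' the single-node-type adjacency
#' `A = rbind(cbind(SR_b, RD), cbind(t(RD), SD_b))`, with ncRNAs occupying
#' rows/columns `1..r` and diseases `r+1..r+d`. Binarized similarity blocks
#' are symmetrized by logical OR with their transpose (the row-wise top-k
#' selection is inherently asymmetric while the normalization requires a
#' symmetric adjacency) and their diagonal is forced to 0 so self-loops enter
#' exactly once through `A + I`. The propagation operator is the symmetric
#' normalization `A_hat = D^{-1/2} (A + I) D^{-1/2}` with `D` the degree
#' matrix of `A + I`; all its eigenvalues lie in `[-1, 1]`.
#'
#' @param RD binary association matrix `r x d`.
#' @param SR_b,SD_b optional binarized similarity blocks (e.g. from
#'   [topk_binarize()]); `NULL` means no similarity edges.
#' @return an object of class `homogeneous_graph` with fields `A`, `A_hat`,
#'   `r`, `d`.
#' @export
assemble_homogeneous <- function(RD, SR_b = NULL, SD_b = NULL) {
  RD <- as.matrix(RD)
  r <- nrow(RD); d <- ncol(RD)
  sym_block <- function(B, n, what) {
    if (is.null(B)) return(matrix(0, n, n))
    B <- as.matrix(B)
    if (nrow(B) != n || ncol(B) != n) {
      stop(sprintf("%s must be %d x %d", what, n, n))
    }
    B <- (B + t(B)) > 0
    B <- B * 1
    diag(B) <- 0
    B
  }
  A <- rbind(cbind(sym_block(SR_b, r, "SR_b"), RD),
             cbind(t(RD), sym_block(SD_b, d, "SD_b")))
  dimnames(A) <- NULL
  AI <- A + diag(r + d)
  dinv <- 1 / sqrt(rowSums(AI))
  A_hat <- AI * outer(dinv, dinv)
  structure(list(A = A, A_hat = A_hat, r = r, d = d),
            class = "homogeneous_graph")
}

#' One-hot node features
#'
#' @param n node count.
#' @return the `n x n` identity matrix.
#' @export
one_hot_features <- function(n) {
  stopifnot(n >= 1)
  diag(n)
}

#' Build the bipartite (heterogeneous) graph view
#'
#' Keeps ncRNAs and diseases as distinct vertex types with association edges
#' only, and precomputes the degree-normalized cross-type propagation
#' `P = Dr^{-1/2} RD Dd^{-1/2}` (ncRNA side) and its transpose (disease
#' side). Zero degrees are replaced by 1 before inversion, so nodes without
#' links propagate zero vectors rather than NaN.
#'
#' @param RD binary association matrix.
#' @return an object of class `heterogeneous_graph` with fields `RD`,
#'   `P_rna` (`r x d`) and `P_dis` (`d x r`).
#' @export
build_heterogeneous <- function(RD) {
  RD <- as.matrix(RD)
  dr <- rowSums(RD); dd <- colSums(RD)
  dr[dr == 0] <- 1
  dd[dd == 0] <- 1
  P <- RD * outer(1 / sqrt(dr), 1 / sqrt(dd))
  dimnames(P) <- NULL
  structure(list(RD = RD, P_rna = P, P_dis = t(P)),
            class = "heterogeneous_graph")
}

# Homogeneous graph for a dataset: top-k binarized similarities (when
# present) spliced with RD. Shared by the trainers and evaluate_cv.
graph_from_dataset <- function(dataset, top_k = 5) {
  sr_b <- if (!is.null(dataset$SR)) topk_binarize(dataset$SR, top_k) else NULL
  sd_b <- if (!is.null(dataset$SD)) topk_binarize(dataset$SD, top_k) else NULL
  assemble_homogeneous(dataset$RD, sr_b, sd_b)
}
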