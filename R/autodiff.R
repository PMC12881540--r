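# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every training objective in the package is assembled from the operations
# below on a fresh tape per evaluation; ad_backward() then yields exact
# analytic gradients for all parameter nodes. Nodes are environments so
# gradient accumulation mutates in place; constants are passed as plain
# matrices and receive no gradient. The tape is append-only, so reverse
# creation order is a valid topological order for backpropagation.

.AD_EPS <- 1e-12

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

is_ad <- function(x) inherits(x, "ad_node")

ad_value <- function(x) if (is_ad(x)) x$value else x

.ad_make <- function(tape, value, inputs = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$inputs <- inputs
  nd$backfn <- backfn
  nd$tape <- tape
  class(nd) <- "ad_node"
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_param <- function(tape, value) {
  .ad_make(tape, as.matrix(value))
}

.ad_tape_of <- function(...) {
  for (x in list(...)) if (is_ad(x)) return(x$tape)
  stop("at least one input must be an ad_node")
}

.ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# Backpropagate from a scalar node; afterwards every reachable parameter
# node carries its gradient in $grad (NULL means identically zero).
ad_backward <- function(root) {
  stopifnot(is_ad(root), length(root$value) == 1L)
  root$grad <- matrix(1, 1, 1)
  nodes <- root$tape$nodes
  for (i in seq(root$id, 1L)) {
    nd <- nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$inputs)) {
      if (is_ad(nd$inputs[[j]]) && !is.null(gs[[j]])) {
        .ad_accum(nd$inputs[[j]], gs[[j]])
      }
    }
  }
  invisible(root)
}

ad_grad <- function(node) {
  if (is.null(node$grad)) matrix(0, nrow(node$value), ncol(node$value)) else node$grad
}

## ---- primitive operations ----

ad_matmul <- function(x, y) {
  tp <- .ad_tape_of(x, y)
  vx <- ad_value(x); vy <- ad_value(y)
  .ad_make(tp, vx %*% vy, list(x, y), function(g) {
    list(if (is_ad(x)) g %*% t(vy) else NULL,
         if (is_ad(y)) t(vx) %*% g else NULL)
  })
}

# x %*% t(y)
ad_matmul_nt <- function(x, y) {
  tp <- .ad_tape_of(x, y)
  vx <- ad_value(x); vy <- ad_value(y)
  .ad_make(tp, vx %*% t(vy), list(x, y), function(g) {
    list(if (is_ad(x)) g %*% vy else NULL,
         if (is_ad(y)) t(g) %*% vx else NULL)
  })
}

# t(x) %*% y
ad_matmul_tn <- function(x, y) {
  tp <- .ad_tape_of(x, y)
  vx <- ad_value(x); vy <- ad_value(y)
  .ad_make(tp, t(vx) %*% vy, list(x, y), function(g) {
    list(if (is_ad(x)) vy %*% t(g) else NULL,
         if (is_ad(y)) vx %*% g else NULL)
  })
}

ad_relu <- function(x) {
  tp <- .ad_tape_of(x)
  vx <- ad_value(x)
  mask <- vx > 0
  .ad_make(tp, vx * mask, list(x), function(g) list(g * mask))
}

ad_add <- function(x, y) {
  tp <- .ad_tape_of(x, y)
  .ad_make(tp, ad_value(x) + ad_value(y), list(x, y), function(g) list(g, g))
}

ad_sub <- function(x, y) {
  tp <- .ad_tape_of(x, y)
  .ad_make(tp, ad_value(x) - ad_value(y), list(x, y), function(g) list(g, -g))
}

ad_scale <- function(x, a) {
  tp <- .ad_tape_of(x)
  .ad_make(tp, ad_value(x) * a, list(x), function(g) list(g * a))
}

ad_add_const <- function(x, c) {
  tp <- .ad_tape_of(x)
  .ad_make(tp, ad_value(x) + c, list(x), function(g) list(g))
}

ad_sum <- function(x) {
  tp <- .ad_tape_of(x)
  vx <- ad_value(x)
  .ad_make(tp, matrix(sum(vx), 1, 1), list(x), function(g) {
    list(matrix(g[1], nrow(vx), ncol(vx)))
  })
}

ad_frob2 <- function(x) {
  tp <- .ad_tape_of(x)
  vx <- ad_value(x)
  .ad_make(tp, matrix(sum(vx^2), 1, 1), list(x), function(g) list(2 * g[1] * vx))
}

# Mean over rows of the Euclidean distance between paired rows of x and y.
ad_mean_row_l2 <- function(x, y) {
  tp <- .ad_tape_of(x, y)
  vx <- ad_value(x); vy <- ad_value(y)
  D <- vx - vy
  nrm <- sqrt(rowSums(D^2))
  n <- nrow(D)
  .ad_make(tp, matrix(mean(nrm), 1, 1), list(x, y), function(g) {
    scale <- ifelse(nrm > .AD_EPS, 1 / (n * nrm), 0)
    gx <- g[1] * D * scale
    list(gx, -gx)
  })
}

ad_gather_rows <- function(x, idx) {
  tp <- .ad_tape_of(x)
  vx <- ad_value(x)
  .ad_make(tp, vx[idx, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(vx), ncol(vx))
    agg <- rowsum(g, group = idx)
    rows <- as.integer(rownames(agg))
    gx[rows, ] <- gx[rows, ] + agg
    list(gx)
  })
}

ad_permute_rows <- function(x, perm) {
  tp <- .ad_tape_of(x)
  vx <- ad_value(x)
  .ad_make(tp, vx[perm, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(vx), ncol(vx))
    gx[perm, ] <- g
    list(gx)
  })
}

# Replace rows idx of x by the (learnable) row vector v (1 x k node).
ad_row_replace <- function(x, idx, v) {
  tp <- .ad_tape_of(x, v)
  vx <- ad_value(x)
  vv <- matrix(ad_value(v), nrow = 1)
  out <- vx
  out[idx, ] <- matrix(vv, nrow = length(idx), ncol = ncol(vx), byrow = TRUE)
  .ad_make(tp, out, list(x, v), function(g) {
    gx <- g
    gx[idx, ] <- 0
    gv <- matrix(colSums(g[idx, , drop = FALSE]), nrow = 1)
    list(gx, gv)
  })
}

ad_rowdot <- function(x, y) {
  tp <- .ad_tape_of(x, y)
  vx <- ad_value(x); vy <- ad_value(y)
  .ad_make(tp, matrix(rowSums(vx * vy), ncol = 1), list(x, y), function(g) {
    gcol <- as.vector(g)
    list(gcol * vy, gcol * vx)
  })
}

# Row-wise L2 normalization; all-zero rows map to zero rows (cosine treated
# as 0 downstream) and propagate no gradient.
ad_normalize_rows <- function(x) {
  tp <- .ad_tape_of(x)
  vx <- ad_value(x)
  nrm <- sqrt(rowSums(vx^2))
  ok <- nrm > .AD_EPS
  inv <- ifelse(ok, 1 / nrm, 0)
  N <- vx * inv
  .ad_make(tp, N, list(x), function(g) {
    dots <- rowSums(vx * g)
    gx <- g * inv - vx * (dots * inv^3)
    gx[!ok, ] <- 0
    list(gx)
  })
}

# For a square score matrix S, sum_i [logsumexp(S[i,]) - S[i,i]]:
# the diagonal-target softmax cross entropy used by the InfoNCE losses.
ad_softmax_ce_diag <- function(x) {
  tp <- .ad_tape_of(x)
  S <- ad_value(x)
  stopifnot(nrow(S) == ncol(S))
  mx <- apply(S, 1, max)
  lse <- mx + log(rowSums(exp(S - mx)))
  val <- sum(lse - diag(S))
  P <- exp(S - lse)  # row-softmax
  .ad_make(tp, matrix(val, 1, 1), list(x), function(g) {
    gx <- P
    diag(gx) <- diag(gx) - 1
    list(g[1] * gx)
  })
}

## ---- composite objectives shared by the trainers ----

# Triplet (hinge) contrast of Eqs.-style multiple losses: first view O,
# second view Z, neighborhood view O_nei, shuffled negatives O_shf (list).
ad_triplet_ctr <- function(O, Z, O_nei, O_shf, alpha, beta,
                           lambda1, lambda2, lambda3) {
  m <- length(O_shf)
  d_on <- ad_mean_row_l2(O, O_nei)
  d_oz <- ad_mean_row_l2(O, Z)
  L1 <- NULL; L2 <- NULL; L3 <- NULL
  for (i in seq_len(m)) {
    d_os <- ad_mean_row_l2(O, O_shf[[i]])
    h1 <- ad_relu(ad_add_const(ad_sub(d_on, d_os), alpha))
    h2 <- ad_relu(ad_add_const(ad_sub(d_oz, d_os), alpha))
    h3 <- ad_relu(ad_add_const(ad_sub(d_oz, d_os), -alpha - beta))
    L1 <- if (is.null(L1)) h1 else ad_add(L1, h1)
    L2 <- if (is.null(L2)) h2 else ad_add(L2, h2)
    L3 <- if (is.null(L3)) h3 else ad_add(L3, h3)
  }
  ad_add(ad_add(ad_scale(L1, lambda1 / m), ad_scale(L2, lambda2 / m)),
         ad_scale(L3, lambda3 / m))
}

ad_infonce <- function(O, Z, tau) {
  S <- ad_scale(ad_matmul_nt(ad_normalize_rows(O), ad_normalize_rows(Z)),
                1 / tau)
  ad_softmax_ce_diag(S)
}

# sum max(0, 1 - pos + neg) over aligned score vectors.
ad_pairwise_margin <- function(pos, neg) {
  ad_sum(ad_relu(ad_add_const(ad_sub(neg, pos), 1)))
}

## ---- Adam optimizer ----

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in seq_along(params)) {
    g <- grads[[k]]
    if (weight_decay > 0) g <- g + weight_decay * params[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
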