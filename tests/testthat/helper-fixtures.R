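# Shared fixtures: everything is generated in code at test time.

# Small block dataset for fast engine runs.
tiny_dataset <- function(r = 30, d = 20, seed = 1) {
  generate_synthetic(synthetic_spec(r = r, d = d, n_blocks = 2,
                                    p_intra = 0.3, p_inter = 0.02,
                                    sim_noise = 0.05, seed = seed))
}

# 6-node dataset used by the gradient checks (4 ncRNAs + 3 diseases keeps
# every top-k call valid and leaves unknown pairs to sample).
grad_dataset <- function() {
  generate_synthetic(synthetic_spec(r = 4, d = 3, n_blocks = 2,
                                    p_intra = 0.5, p_inter = 0.1,
                                    sim_noise = 0.05, seed = 3))
}

fast_gm <- function(epochs = 3, seed = 0) {
  gm_config(n_hidden = 8, epochs = epochs, m = 2, n_nei = 2, seed = seed)
}

fast_gh <- function(epochs = 3, seed = 0) {
  gh_config(e = 8, h = 4, l = 2, epochs = epochs, m = 2, n_nei = 2,
            seed = seed)
}

fast_ma <- function(epochs = 3, seed = 0) {
  ma_config(n_hidden = 8, epochs = epochs, seed = seed)
}

# Central finite-difference check of an objective's analytic gradients.
# Returns the worst relative error over all parameter entries.
fd_gradient_error <- function(params, objfun, h = 1e-4) {
  out <- objfun(params)
  worst <- 0
  for (nm in names(params)) {
    ga <- out$grads[[nm]]
    for (ix in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][ix] <- pp[[nm]][ix] + h
      pm <- params; pm[[nm]][ix] <- pm[[nm]][ix] - h
      gn <- (objfun(pp)$value - objfun(pm)$value) / (2 * h)
      denom <- max(1e-6, abs(ga[ix]) + abs(gn))
      worst <- max(worst, abs(ga[ix] - gn) / denom)
    }
  }
  worst
}

grad_norm2 <- function(grads) sum(vapply(grads, function(g) sum(g^2),
                                         numeric(1)))

# Explicit-loop oracles (deliberately unvectorized re-implementations).

oracle_mean_row_dist <- function(X, Y) {
  acc <- 0
  for (i in seq_len(nrow(X))) {
    s <- 0
    for (j in seq_len(ncol(X))) s <- s + (X[i, j] - Y[i, j])^2
    acc <- acc + sqrt(s)
  }
  acc / nrow(X)
}

oracle_triplet <- function(O, Z, O_nei, O_shf, alpha, beta, l1, l2, l3) {
  m <- length(O_shf)
  L1 <- 0; L2 <- 0; L3 <- 0
  for (i in seq_len(m)) {
    don <- oracle_mean_row_dist(O, O_nei)
    doz <- oracle_mean_row_dist(O, Z)
    dos <- oracle_mean_row_dist(O, O_shf[[i]])
    L1 <- L1 + max(0, don - dos + alpha)
    L2 <- L2 + max(0, doz - dos + alpha)
    L3 <- L3 + max(0, doz - dos - alpha - beta)
  }
  l1 * L1 / m + l2 * L2 / m + l3 * L3 / m
}

oracle_margin <- function(pos, neg) {
  s <- 0
  for (i in seq_along(pos)) s <- s + max(0, 1 - pos[i] + neg[i])
  s
}

oracle_cos <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) return(0)
  sum(a * b) / (na * nb)
}

oracle_infonce <- function(O, Z, tau) {
  n <- nrow(O)
  total <- 0
  for (i in seq_len(n)) {
    denom <- 0
    for (j in seq_len(n)) denom <- denom + exp(oracle_cos(O[i, ], Z[j, ]) / tau)
    total <- total - log(exp(oracle_cos(O[i, ], Z[i, ]) / tau) / denom)
  }
  total
}

oracle_auc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  acc <- 0
  for (p in ps) for (q in ns) {
    acc <- acc + (p > q) + 0.5 * (p == q)
  }
  acc / (length(ps) * length(ns))
}

oracle_aupr <- function(scores, labels) {
  np <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  acc <- 0; prev_rec <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / np
    acc <- acc + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  acc
}

oracle_ranks <- function(pos, neg) {
  out <- numeric(length(pos))
  for (i in seq_along(pos)) {
    rk <- 1
    for (q in neg) {
      if (q > pos[i]) rk <- rk + 1
      if (q == pos[i]) rk <- rk + 0.5
    }
    out[i] <- rk
  }
  out
}
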