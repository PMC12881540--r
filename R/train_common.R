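# Shared training infrastructure: parameter initialization, pair sampling,
# the Adam loop, and the tape evaluation wrapper used by every engine.

# Deterministic per-epoch seed below 2^31, derived from the run seed.
epoch_seed <- function(seed, epoch, salt = 0) {
  as.integer((as.numeric(seed) * 1009 + epoch * 7919 + salt * 104729) %%
               2147483563)
}

glorot_init <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# All (i, j) index pairs with RD[i, j] == 1, as a 2-column matrix.
positive_pairs <- function(RD) {
  w <- which(RD == 1)
  r <- nrow(RD)
  cbind(rna = ((w - 1) %% r) + 1, dis = ((w - 1) %/% r) + 1)
}

# Uniform sample of n unknown (zero) pairs of RD.
sample_unknown_pairs <- function(RD, n, seed, exclude = NULL) {
  z <- which(RD == 0)
  if (!is.null(exclude)) z <- setdiff(z, exclude)
  if (length(z) < n) stop("not enough unknown pairs to sample from")
  r <- nrow(RD)
  w <- withr::with_seed(as.integer(seed), sample(z, n))
  cbind(rna = ((w - 1) %% r) + 1, dis = ((w - 1) %/% r) + 1)
}

# Evaluate an objective: params (named list of matrices) -> loss value and
# gradient list. `build` receives the list of parameter nodes and must
# return a scalar node.
eval_objective <- function(params, build) {
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_param(tape, p))
  loss <- build(pn)
  ad_backward(loss)
  list(value = loss$value[1, 1], grads = lapply(pn, ad_grad))
}

# Adam training loop. `objective(params, epoch)` returns
# list(value, grads); aborts on non-finite loss.
run_training <- function(params, objective, epochs, lr, weight_decay = 0) {
  state <- adam_state(params)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    out <- objective(params, ep)
    if (!is.finite(out$value)) {
      stop(sprintf("non-finite training loss (%s) at epoch %d", out$value, ep))
    }
    history[ep] <- out$value
    step <- adam_step(params, out$grads, state, lr, weight_decay)
    params <- step$params
    state <- step$state
  }
  list(params = params, history = history)
}

# Dot-product scores of embedding pairs on the tape: Z is the stacked
# (ncRNA-first) embedding node, pairs an index matrix (rna, dis).
ad_pair_scores <- function(Z, pairs, r) {
  ad_rowdot(ad_gather_rows(Z, pairs[, 1]),
            ad_gather_rows(Z, r + pairs[, 2]))
}

# Same with per-type embedding nodes.
ad_pair_scores2 <- function(Z_rna, Z_dis, pairs) {
  ad_rowdot(ad_gather_rows(Z_rna, pairs[, 1]),
            ad_gather_rows(Z_dis, pairs[, 2]))
}
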