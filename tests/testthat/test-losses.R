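test_that("attribute and structure features apply ReLU propagation", {
  expect_equal(attribute_features(diag(2), matrix(1, 2, 2)),
               matrix(1, 2, 2))
  expect_equal(attribute_features(diag(2), matrix(-1, 2, 2)),
               matrix(0, 2, 2))
  expect_equal(attribute_features(matrix(c(1, 0), 1, 2),
                                  rbind(c(2, -1), c(0, 3))),
               matrix(c(2, 0), 1, 2))
  O <- rbind(c(2, 0), c(0, 2))
  expect_equal(structure_features(matrix(0.5, 2, 2), O), matrix(1, 2, 2))
  expect_equal(structure_features(diag(2), O), O)
  expect_equal(dim(structure_features(matrix(0.5, 2, 2), O)), dim(O))
})

test_that("neighborhood features average sampled neighbors with fallbacks", {
  A <- rbind(c(0, 1, 0, 0),
             c(1, 0, 1, 1),
             c(0, 1, 0, 0),
             c(0, 0, 0, 0))  # node 4 isolated
  O <- matrix(1:8, 4, 2)
  On <- neighbor_features(A, O, n_nei = 3, seed = 1)
  expect_equal(On[1, ], O[2, ])                      # single neighbor
  expect_equal(On[2, ], colMeans(O[c(1, 3, 4), ]))   # all 3 neighbors
  expect_equal(On[4, ], O[4, ])                      # isolated fallback
  expect_identical(neighbor_features(A, O, 2, seed = 9),
                   neighbor_features(A, O, 2, seed = 9))
})

test_that("shuffled negatives are seeded row permutations", {
  O <- matrix(rnorm(20), 5, 4)
  shf <- shuffle_negatives(O, m = 3, seed = 2)
  expect_length(shf, 3)
  for (S in shf) {
    expect_equal(S[do.call(order, as.data.frame(S)), ],
                 O[do.call(order, as.data.frame(O)), ])
    expect_equal(colMeans(S), colMeans(O))
  }
  expect_identical(shuffle_negatives(O, 3, seed = 2), shf)
})

test_that("triplet loss reproduces hand-worked hinge values", {
  # 1x1 matrices make d() the absolute difference
  O <- matrix(0); O_nei <- matrix(0.2); Z <- matrix(1.5)
  O_shf <- list(matrix(0.5))
  expect_equal(triplet_contrastive_loss(O, Z, O_nei, O_shf,
                                        lambda1 = 1, lambda2 = 0,
                                        lambda3 = 0),
               0.5)  # max(0, 0.2 - 0.5 + 0.8)
  expect_equal(triplet_contrastive_loss(O, Z, O_nei, O_shf,
                                        lambda1 = 0, lambda2 = 0,
                                        lambda3 = 1),
               0)    # max(0, 1.5 - 0.5 - 1.2)
  # all views identical: L1 = L2 = alpha, L3 = 0
  I2 <- diag(2)
  expect_equal(triplet_contrastive_loss(I2, I2, I2, list(I2)),
               5 * 0.8 + 5 * 0.8)
})

test_that("triplet and margin losses match explicit-loop oracles", {
  for (i in 1:5) {
    O <- withr::with_seed(i, matrix(rnorm(15), 5, 3))
    Z <- withr::with_seed(i + 5, matrix(rnorm(15), 5, 3))
    On <- withr::with_seed(i + 10, matrix(rnorm(15), 5, 3))
    shf <- shuffle_negatives(O, 3, seed = i)
    expect_equal(triplet_contrastive_loss(O, Z, On, shf),
                 oracle_triplet(O, Z, On, shf, 0.8, 0.4, 5, 5, 1),
                 tolerance = 1e-6)
    pos <- withr::with_seed(i + 20, rnorm(7))
    neg <- withr::with_seed(i + 30, rnorm(7))
    expect_equal(pairwise_margin_loss(pos, neg), oracle_margin(pos, neg),
                 tolerance = 1e-6)
  }
  expect_equal(pairwise_margin_loss(2, 0), 0)
  expect_equal(pairwise_margin_loss(0, 0), 1)
  expect_equal(pairwise_margin_loss(c(0.5, 0.2), c(0.1, 0.4)), 1.8)
})

test_that("InfoNCE has its closed-form values and loop equivalence", {
  expect_equal(infonce_pair_loss(matrix(1, 1, 2), matrix(1, 1, 2), tau = 1), 0)
  expect_equal(infonce_pair_loss(diag(2), diag(2), tau = 1),
               2 * log(1 + exp(-1)))
  O <- matrix(1, 4, 3)
  expect_equal(infonce_pair_loss(O, O, tau = 0.7), 4 * log(4))
  for (i in 1:5) {
    A <- withr::with_seed(i, matrix(rnorm(15), 5, 3))
    B <- withr::with_seed(i + 50, matrix(rnorm(15), 5, 3))
    B[2, ] <- 0  # zero-norm row handled as cosine 0
    expect_equal(infonce_pair_loss(A, B, 0.5), oracle_infonce(A, B, 0.5),
                 tolerance = 1e-6)
  }
})

test_that("masking selects the exact count and leaves other rows intact", {
  X <- matrix(rnorm(40), 10, 4)
  mk <- mask_features(X, 0.4, x_prime = rep(9, 4), seed = 3)
  expect_length(mk$masked, 4)
  expect_true(all(mk$X_hat[mk$masked, ] == 9))
  expect_identical(mk$X_hat[-mk$masked, ], X[-mk$masked, ])
  expect_identical(mask_features(X, 0.4, seed = 3)$masked, mk$masked)
  expect_error(mask_features(matrix(0, 10, 2), 0.04), "nothing to mask")
})

test_that("masked-reconstruction InfoNCE restricts to the masked set", {
  Z <- matrix(rnorm(20), 5, 4)
  M <- matrix(rnorm(20), 5, 4)
  expect_warning(l1 <- reconstruction_infonce(Z, M, masked = 2), "one masked")
  expect_equal(l1, 0)
  l <- reconstruction_infonce(Z, M, masked = c(1, 3), tau = 1)
  expect_equal(l, oracle_infonce(Z[c(1, 3), ], M[c(1, 3), ], 1),
               tolerance = 1e-6)
  # simultaneous reordering of the masked rows leaves the loss unchanged
  Z2 <- Z; M2 <- M
  Z2[c(1, 3), ] <- Z[c(3, 1), ]; M2[c(1, 3), ] <- M[c(3, 1), ]
  expect_equal(reconstruction_infonce(Z2, M2, c(1, 3), 0.9),
               reconstruction_infonce(Z, M, c(1, 3), 0.9))
})

test_that("closed-form masked InfoNCE on two orthogonal reconstructions", {
  Z <- rbind(c(1, 0), c(0, 1), c(5, 5))
  M <- rbind(c(1, 0), c(0, 1), c(-3, 2))
  expect_equal(reconstruction_infonce(Z, M, masked = c(1, 2), tau = 1),
               2 * log(1 + exp(-1)))
})
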