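test_that("edge-list reader builds RD in first-appearance order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("R1\tD1", "R2\tD1"), f)
  ds <- read_association(f, "edge_list")
  expect_equal(ds$rna_ids, c("R1", "R2"))
  expect_equal(ds$disease_ids, "D1")
  expect_equal(unname(ds$RD), matrix(c(1, 1), 2, 1))
})

test_that("edge-list reader deduplicates with a warning and rejects empties", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("R1\tD1", "R1\tD1", "R2\tD2"), f)
  expect_warning(ds <- read_association(f, "edge_list"), "duplicate")
  expect_equal(sum(ds$RD), 2)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f2)
  expect_error(read_association(f2, "edge_list"), "no associations")
})

test_that("matrix reader recovers a benchmark-sized association table", {
  r <- 585; d <- 88; links <- 650
  RD <- matrix(0, r, d, dimnames = list(paste0("R", 1:r), paste0("D", 1:d)))
  RD[withr::with_seed(1, sample(r * d, links))] <- 1
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(id = rownames(RD), RD, check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_association(f, "matrix")
  expect_equal(dim(ds$RD), c(r, d))
  expect_equal(sum(ds$RD), links)
  expect_equal(dataset_density(ds), links / (r * d))
})

test_that("similarity reader repairs noisy input and rejects non-square", {
  f <- withr::local_tempfile(fileext = ".tsv")
  M <- diag(3); dimnames(M) <- list(paste0("R", 1:3), paste0("R", 1:3))
  utils::write.table(data.frame(id = rownames(M), M, check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unname(read_similarity(f)), diag(3), ignore_attr = TRUE)

  M2 <- diag(3); M2[1, 2] <- M2[2, 1] <- 1.0000001
  dimnames(M2) <- dimnames(M)
  utils::write.table(data.frame(id = rownames(M2), M2, check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(S <- read_similarity(f), "clipped")
  expect_equal(S[1, 2], 1)

  M3 <- diag(3); M3[1, 2] <- 0.6; M3[2, 1] <- 0.4
  dimnames(M3) <- dimnames(M)
  utils::write.table(data.frame(id = rownames(M3), M3, check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(S3 <- read_similarity(f), "symmetrized")
  expect_equal(S3[1, 2], 0.5)
  expect_equal(S3[2, 1], 0.5)

  M4 <- matrix(runif(6), 2, 3,
               dimnames = list(c("a", "b"), c("a", "b", "c")))
  utils::write.table(data.frame(id = rownames(M4), M4, check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_similarity(f), "not square")
})

test_that("similarity labels must match the association labels", {
  fa <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("R1\tD1", "R2\tD1"), fa)
  fs <- withr::local_tempfile(fileext = ".tsv")
  M <- diag(2); dimnames(M) <- list(c("R1", "RX"), c("R1", "RX"))
  utils::write.table(data.frame(id = rownames(M), M, check.names = FALSE),
                     fs, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_association(fa, "edge_list", sr_path = fs), "RX")
})

test_that("dataset invariants are enforced", {
  expect_error(association_dataset(matrix(2, 1, 1)), "0 or 1")
  expect_error(association_dataset(matrix(1, 2, 1),
                                   rna_ids = c("a", "a"),
                                   disease_ids = "d"), "duplicate")
  S <- matrix(c(1, 0.3, 0.7, 1), 2, 2)
  expect_error(association_dataset(diag(2), SR = S), "symmetric")
  expect_error(association_dataset(diag(2), SR = diag(3)), "must be 2 x 2")
})

test_that("synthetic generator honours forced probabilities and reseeds", {
  ds <- generate_synthetic(synthetic_spec(r = 50, d = 50, n_blocks = 1,
                                          p_intra = 1, p_inter = 0,
                                          sim_noise = 0, seed = 0))
  expect_true(all(ds$RD == 1))
  expect_true(all(ds$SR == 1))
  expect_error(
    generate_synthetic(synthetic_spec(r = 10, d = 10, n_blocks = 2,
                                      p_intra = 0, p_inter = 0,
                                      sim_noise = 0, seed = 0)),
    "zero associations")
})

test_that("synthetic density matches its binomial expectation", {
  # expectation p_intra/K + p_inter (K-1)/K under uniform group assignment
  for (case in list(list(r = 200, d = 100, seed = 1),
                    list(r = 500, d = 500, seed = 2))) {
    spec <- synthetic_spec(r = case$r, d = case$d, n_blocks = 4,
                           p_intra = 0.2, p_inter = 0.005, sim_noise = 0.1,
                           seed = case$seed)
    ds <- generate_synthetic(spec)
    expected <- 0.2 / 4 + 0.005 * 3 / 4
    se <- sqrt(expected * (1 - expected) / (case$r * case$d))
    expect_lt(abs(dataset_density(ds) - expected), 3 * se)
  }
})

test_that("synthetic generation is bit-reproducible and validates", {
  s <- synthetic_spec(r = 40, d = 30, seed = 7)
  a <- generate_synthetic(s); b <- generate_synthetic(s)
  expect_identical(a, b)
  expect_equal(max(abs(a$SR - t(a$SR))), 0)
  expect_equal(unname(diag(a$SR)), rep(1, 40))
  expect_true(all(a$SR >= 0 & a$SR <= 1))
  expect_error(synthetic_spec(p_intra = 0.1, p_inter = 0.5), "p_inter")
})

test_that("shuffled associations keep the link count but lose structure", {
  ds <- tiny_dataset()
  sh <- shuffle_associations(ds, seed = 3)
  expect_equal(sum(sh$RD), sum(ds$RD))
  expect_false(identical(sh$RD, ds$RD))
})

test_that("score files round-trip sorted and metrics round-trip exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  pairs <- data.frame(rna_id = c("a", "b", "c"), disease_id = c("x", "y", "z"),
                      score = c(0.5, 0.9, 0.123456789012345))
  write_scores(pairs, f)
  back <- read_scores(f)
  expect_equal(back$score, c(0.9, 0.5, 0.123456789012345), tolerance = 1e-12)
  expect_equal(back$rna_id, c("b", "a", "c"))

  write_scores(pairs[0, ], f)
  expect_equal(nrow(read_scores(f)), 0)

  fm <- withr::local_tempfile(fileext = ".json")
  rep <- list(auc = 0.987654321012345, mr = 12.5)
  write_metrics(rep, fm)
  expect_equal(read_metrics(fm), rep, tolerance = 1e-14)
})
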