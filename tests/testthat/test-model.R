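test_that("hand-worked k=1 model from AACG has the expected costs", {
  m <- build_model("AACG", k = 1, missing_cost = 10,
                   strand_policy = "forward")
  expect_equal(m$costs[["AA"]], -log(0.5), tolerance = 1e-12)
  expect_equal(m$costs[["AC"]], -log(0.5), tolerance = 1e-12)
  expect_equal(m$costs[["CG"]], 0)
  other <- setdiff(names(m$costs), c("AA", "AC", "CG"))
  expect_true(all(m$costs[other] == 10))
  expect_equal(m$n_transitions_trained, 3)
})

test_that("single observed transition per context has probability 1", {
  m <- build_model("AAAA", k = 1, missing_cost = 10,
                   strand_policy = "forward")
  expect_equal(m$costs[["AA"]], 0)
  expect_true(all(m$costs[setdiff(names(m$costs), "AA")] == 10))
})

test_that("model costs match the independent oracle on random genomes", {
  set.seed(202)
  for (k in c(1L, 3L)) {
    for (policy in c("forward", "both")) {
      seqs <- replicate(2, random_dna(400))
      m <- build_model(seqs, k = k, strand_policy = policy)
      expect_equal(unname(m$costs),
                   unname(oracle_costs(seqs, k, 10, policy)),
                   tolerance = 1e-12,
                   info = sprintf("k=%d policy=%s", k, policy))
    }
  }
})

test_that("observed transition probabilities normalize per context", {
  set.seed(303)
  for (k in c(1L, 3L, 5L)) {
    m <- build_model(random_dna(5000), k = k)
    p <- matrix(exp(-m$costs), ncol = 4L, byrow = TRUE)
    obs <- matrix(m$costs != m$missing_cost, ncol = 4L, byrow = TRUE)
    trained <- rowSums(obs) > 0
    sums <- rowSums(p * obs)[trained]
    expect_true(all(abs(sums - 1) <= 1e-9), info = paste("k =", k))
  }
})

test_that("costs are scale-invariant and non-negative", {
  set.seed(404)
  s <- random_dna(600)
  m1 <- build_model(s, k = 3)
  m2 <- build_model(c(s, s, s), k = 3)   # duplicated training data
  expect_equal(m1$costs, m2$costs, tolerance = 1e-12)
  expect_true(all(m1$costs >= 0))
})

test_that("strand_policy=both is symmetric under reverse complement", {
  set.seed(505)
  s <- random_dna(500)
  m_fwd_in <- build_model(s, k = 2, strand_policy = "both")
  m_rc_in <- build_model(oracle_revcomp(s), k = 2, strand_policy = "both")
  expect_identical(m_fwd_in$costs, m_rc_in$costs)
  # a palindromic input under "both" equals training on it twice forward
  m1 <- build_model("ACGT", k = 1, strand_policy = "both")
  m2 <- build_model(c("ACGT", "ACGT"), k = 1, strand_policy = "forward")
  expect_identical(m1$costs, m2$costs)
})

test_that("degenerate training input is refused", {
  expect_error(build_model("NNNNNN", k = 2), "model-degenerate")
  expect_error(build_model(character(0), k = 2), "at least one")
})

test_that("database assembly preserves input order and genome identity", {
  set.seed(606)
  seqs <- setNames(replicate(3, random_dna(800)), c("gA", "gB", "gC"))
  tax <- make_lineage_table(names(seqs),
                            phylum = c("P1", "P1", "P2"),
                            genus = c("Ga", "Gb", "Gc"))
  db <- build_database(as.list(seqs), k = 5, taxonomy = tax)
  expect_equal(dim(db$matrix), c(3L, 4096L))
  expect_identical(rownames(db$matrix), c("gA", "gB", "gC"))
  # permuted input order gives a row-permutation of the same models
  db2 <- build_database(as.list(seqs[c(3, 1, 2)]), k = 5, taxonomy = tax)
  expect_identical(db2$matrix[rownames(db$matrix), ], db$matrix)
  # rows match independently built single models (at float32 precision)
  m_gB <- build_model(seqs[["gB"]], k = 5, genome_id = "gB")
  expect_lt(max(abs(db$matrix["gB", ] - m_gB$costs)), 1e-6)
})

test_that("database construction validates its inputs", {
  expect_error(build_database(list(), k = 2), "non-empty")
  expect_error(
    build_database(list(a = "ACGTACGT", a = "ACGTACGT"), k = 2,
                   allow_missing_taxonomy = TRUE),
    "duplicate genome_id"
  )
  tax <- make_lineage_table("other")
  expect_error(
    build_database(list(a = "ACGTACGT"), k = 2, taxonomy = tax),
    "no taxonomy entry"
  )
  db <- build_database(list(a = "ACGTACGT"), k = 2, taxonomy = tax,
                       allow_missing_taxonomy = TRUE)
  expect_equal(db$genomes$phylum, "NA")
})

test_that("incremental add equals a from-scratch rebuild bit-exactly", {
  set.seed(707)
  seqs <- setNames(as.list(replicate(10, random_dna(600))),
                   sprintf("g%02d", 1:10))
  tax <- make_lineage_table(names(seqs),
                            phylum = sprintf("P%d", rep(1:2, 5)))
  db9 <- build_database(seqs[1:9], k = 4, taxonomy = tax,
                        allow_missing_taxonomy = TRUE)
  db10_inc <- add_genome(db9, "g10", seqs[["g10"]],
                         lineage = tax[tax$genome_id == "g10", ])
  db10_full <- build_database(seqs, k = 4, taxonomy = tax)
  expect_identical(db10_inc$matrix, db10_full$matrix)
  expect_identical(db10_inc$genomes, db10_full$genomes)
  expect_equal(nrow(db10_inc$matrix), 10L)
  expect_error(add_genome(db9, "g03", "ACGTACGT"), "duplicate")
})
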