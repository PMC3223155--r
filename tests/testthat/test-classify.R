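make_toy_db <- function(seqs, k, strand_policy = "forward") {
  build_database(as.list(seqs), k = k, strand_policy = strand_policy,
                 allow_missing_taxonomy = TRUE)
}

test_that("read vectorization follows the window-counting convention", {
  rv <- vectorize_reads(c(r1 = "AAC"), k = 1)
  expect_equal(rv$counts[1, "AA"], c(AA = 1))
  expect_equal(rv$counts[1, "AC"], c(AC = 1))
  expect_equal(rv$n_valid_transitions, 2L)

  # l <= k: no countable transition, kept as unclassifiable
  rv2 <- vectorize_reads(c(r2 = "AC"), k = 5)
  expect_equal(rv2$n_valid_transitions, 0L)

  # homopolymer: l - k identical transitions
  rv3 <- vectorize_reads(c(r3 = strrep("A", 101)), k = 1)
  expect_equal(unname(rv3$counts[1, "AA"]), 100)
  expect_equal(rv3$n_valid_transitions, 100L)
})

test_that("scores equal the hand-worked transition sums", {
  db <- make_toy_db(c(g1 = "AACG"), k = 1)
  s <- score_all(vectorize_reads(c(r = "AAC"), 1), db)
  expect_equal(s[1, 1], 2 * log(2), tolerance = 1e-6)
  s2 <- score_all(vectorize_reads(c(r = "AAT"), 1), db)
  expect_equal(s2[1, 1], log(2) + 10, tolerance = 1e-6)
  # all transitions observed with probability 1: score exactly 0
  db_poly <- make_toy_db(c(gA = strrep("A", 50)), k = 1)
  s3 <- score_all(vectorize_reads(c(r = strrep("A", 30)), 1), db_poly)
  expect_identical(s3[1, 1], 0)
})

test_that("matrix scoring agrees with the per-transition oracle", {
  set.seed(808)
  for (k in c(1L, 2L, 3L, 5L)) {
    seqs <- setNames(replicate(4, random_dna(1500)), paste0("g", 1:4))
    db <- make_toy_db(seqs, k = k, strand_policy = "both")
    reads <- setNames(
      vapply(sample(50:300, 8), random_dna, character(1)),
      paste0("r", 1:8)
    )
    rv <- vectorize_reads(reads, k)
    sc <- score_all(rv, db, backend = "vectorized")
    for (r in seq_along(reads)) {
      for (g in seq_len(nrow(db$matrix))) {
        exp_s <- oracle_score(reads[r], db$matrix[g, ], k)
        expect_equal(sc[r, g], exp_s,
                     tolerance = 1e-4 / max(1, abs(exp_s)),
                     info = sprintf("k=%d read=%d genome=%d", k, r, g))
      }
    }
  }
})

test_that("reference and vectorized backends agree", {
  set.seed(909)
  db <- make_toy_db(setNames(replicate(3, random_dna(1000)),
                             paste0("g", 1:3)), k = 3)
  rv <- vectorize_reads(setNames(replicate(6, random_dna(120)),
                                 paste0("r", 1:6)), 3)
  s_ref <- score_all(rv, db, backend = "reference")
  s_vec <- score_all(rv, db, backend = "vectorized")
  s_acc <- score_all(rv, db, backend = "accelerated")
  expect_equal(s_ref, s_vec, tolerance = 1e-10)
  expect_identical(s_vec, s_acc)
})

test_that("a read all of whose transitions are unseen scores n * missing_cost", {
  # model trained on A/C only; read walks G/T contexts exclusively
  db <- make_toy_db(c(g = "ACACACACAC"), k = 1)
  read <- c(r = "GTGTGTGTG")
  rv <- vectorize_reads(read, 1)
  s <- score_all(rv, db)
  expect_identical(s[1, 1], rv$n_valid_transitions * 10)
})

test_that("assignment picks the minimum score with deterministic ties", {
  db <- make_toy_db(c(g1 = "AACGTT", g2 = "AACGTT", g3 = "GGGCCC"), k = 1)
  # identical rows g1/g2: lowest row index must win
  res <- classify_reads(c(r = "AACG"), db)
  expect_equal(res$genome_id, "g1")
  expect_equal(res$rank_of_best, 1L)
  # scores [3.2, 1.1, 7.0] -> row 2
  sc <- matrix(c(3.2, 1.1, 7.0), nrow = 1,
               dimnames = list("r", c("g1", "g2", "g3")))
  a <- assign_reads(sc, db, n_valid_transitions = 3L)
  expect_equal(a$genome_id, "g2")
  expect_equal(a$score, 1.1)
})

test_that("reads sampled from a genome are assigned to that genome", {
  set.seed(111)
  g_src <- random_dna(5000)
  g_bg <- random_dna(5000)
  db <- make_toy_db(c(src = g_src, bg = g_bg), k = 3,
                    strand_policy = "both")
  starts <- sample(4500, 20)
  reads <- setNames(substring(g_src, starts, starts + 499),
                    paste0("r", 1:20))
  res <- classify_reads(reads, db)
  # verify per read with the brute-force oracle, then check the argmin
  for (i in 1:20) {
    s_src <- oracle_score(reads[i], db$matrix["src", ], 3)
    s_bg <- oracle_score(reads[i], db$matrix["bg", ], 3)
    expect_lt(s_src, s_bg)
  }
  expect_true(all(res$genome_id == "src"))
})

test_that("unclassifiable reads get the sentinel assignment", {
  db <- make_toy_db(c(g = "ACGTACGTAC"), k = 5)
  res <- classify_reads(c(ok = "ACGTACGTAC", short = "ACG",
                          gappy = "NNNNNNNNNN"), db)
  expect_equal(res$genome_id, c("g", "UNCLASSIFIED", "UNCLASSIFIED"))
  expect_true(all(is.na(res$score[2:3])))
  expect_equal(res$phylum[2], "UNCLASSIFIED")
})

test_that("batched classification is invariant to batch size and backend", {
  set.seed(222)
  db <- make_toy_db(setNames(replicate(4, random_dna(2000)),
                             paste0("g", 1:4)), k = 3)
  reads <- setNames(vapply(rep(80, 100), random_dna, character(1)),
                    sprintf("r%03d", 1:100))
  one_shot <- classify_reads(reads, db)
  expect_identical(classify_stream(reads, db, batch_size = 1L), one_shot)
  expect_identical(classify_stream(reads, db, batch_size = 7L), one_shot)
  expect_identical(classify_stream(reads, db, batch_size = 100L), one_shot)
  by_ref <- classify_stream(reads, db, batch_size = 33L,
                            backend = "reference")
  expect_equal(by_ref, one_shot, tolerance = 1e-10)
  # empty query set: empty result, same columns
  empty <- classify_stream(character(0), db)
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty), names(one_shot))
})

test_that("k mismatch and empty databases are rejected", {
  db <- make_toy_db(c(g = "ACGTACGTACGT"), k = 3)
  rv <- vectorize_reads(c(r = "ACGTACGT"), k = 2)
  expect_error(score_all(rv, db), "order mismatch")
})

test_that("top-N reporting orders hits by score and keeps lineages", {
  set.seed(333)
  db <- make_toy_db(setNames(replicate(5, random_dna(1000)),
                             paste0("g", 1:5)), k = 2)
  read <- c(r1 = random_dna(200))
  res <- classify_reads(read, db, top = 3)
  expect_equal(nrow(res), 3L)
  expect_equal(res$hit_rank, 1:3)
  expect_false(is.unsorted(res$score))
  # hit 1 must equal the plain argmin assignment
  plain <- classify_reads(read, db)
  expect_equal(res$genome_id[1], plain$genome_id)
  expect_equal(res$score[1], plain$score)
  expect_true(all(TAXONOMY_RANKS %in% names(res)))
})
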