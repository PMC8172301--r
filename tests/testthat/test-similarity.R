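measures <- all_measures()

test_that("encoding flattens itemsets in canonical order", {
  expect_equal(seq_tokens(new_pattern(list(c("R07", "I21"), "I20"))),
               c("I21", "R07", "I20"))
  expect_equal(seq_tokens(new_pattern("I50")), "I50")
  # order-preserving on single-item sequences: distinct sequences stay distinct
  a <- new_pattern(c("A", "B", "C"))
  b <- new_pattern(c("B", "A", "C"))
  expect_false(identical(seq_tokens(a), seq_tokens(b)))
})

test_that("every measure is zero at identity and one at identical similarity", {
  withr::with_seed(11, {
    for (m in measures) {
      for (i in 1:20) {
        x <- random_tokens(LETTERS[1:6], 8, min_len = 1)
        expect_equal(token_distance(x, x, m), 0)
        expect_equal(token_similarity(x, x, m), 1)
      }
      expect_equal(token_similarity(character(0), character(0), m), 1)
    }
  })
})

test_that("hand-checked distance values match their definitions", {
  lev <- measures$levenshtein
  expect_equal(token_distance("A", "B", lev), 1)
  expect_equal(token_similarity("A", "B", lev), 0)
  # one substitution + one insertion over tokens
  expect_equal(token_distance(c("I21", "R07", "I20"), c("I21", "I50"), lev), 2)
  # transposition: one operation for osa/dl, two for levenshtein
  a <- c("R07", "I20"); b <- c("I20", "R07")
  expect_equal(token_distance(a, b, lev), 2)
  expect_equal(token_distance(a, b, measures$osa), 1)
  expect_equal(token_distance(a, b, measures$damerau_levenshtein), 1)
  # unrestricted transposition beats osa when the pair is separated
  a2 <- c("C", "A"); b2 <- c("A", "B", "C")
  expect_equal(token_distance(a2, b2, measures$damerau_levenshtein), 2)
  expect_equal(token_distance(a2, b2, measures$osa), 3)
  # longest common substring: |a|+|b|-2*run
  expect_equal(token_distance(c("A", "B", "C"), c("B", "C", "D"),
                              measures$lcs), 2)
  # q-gram degenerate cases: texts shorter than q
  qg <- measures$qgram
  expect_equal(token_similarity("A", "A", qg), 1)   # both profiles empty
  expect_equal(token_similarity("A", c("A", "B"), qg), 0)  # one empty
  expect_equal(token_similarity(character(0), c("A", "B"), measures$jaccard), 0)
})

test_that("all nine measures agree with reference implementations on random pairs", {
  withr::with_seed(2024, {
    vocab <- LETTERS[1:6]
    for (i in 1:500) {
      a <- random_tokens(vocab, 8)
      b <- random_tokens(vocab, 8)
      expect_identical(token_distance(a, b, measures$levenshtein),
                       ref_levenshtein(a, b))
      expect_identical(as.integer(token_distance(a, b, measures$osa)),
                       as.integer(ref_osa(a, b)))
      expect_identical(as.integer(token_distance(a, b,
                                                 measures$damerau_levenshtein)),
                       as.integer(ref_dl(a, b)))
      expect_identical(as.integer(token_distance(a, b, measures$lcs)),
                       as.integer(length(a) + length(b) - 2 * ref_lcstr(a, b)))
      expect_identical(as.integer(token_distance(a, b, measures$qgram)),
                       as.integer(ref_qgram_dist(a, b)))
      expect_equal(token_similarity(a, b, measures$jaccard),
                   ref_jaccard_sim(a, b), tolerance = 1e-12)
      expect_equal(token_similarity(a, b, measures$cosine),
                   ref_cosine_sim(a, b), tolerance = 1e-12)
      expect_equal(token_similarity(a, b, measures$jaro),
                   ref_jaro_sim(a, b), tolerance = 1e-12)
      expect_equal(token_similarity(a, b, measures$jaro_winkler),
                   ref_jw_sim(a, b), tolerance = 1e-12)
    }
  })
})

test_that("distances are symmetric, bounded and obey the edit-family dominance chain", {
  withr::with_seed(7, {
    vocab <- LETTERS[1:5]
    for (i in 1:200) {
      a <- random_tokens(vocab, 7)
      b <- random_tokens(vocab, 7)
      for (m in measures) {
        expect_equal(token_distance(a, b, m), token_distance(b, a, m))
        s <- token_similarity(a, b, m)
        expect_gte(s, 0)
        expect_lte(s, 1)
      }
      dl <- token_distance(a, b, measures$damerau_levenshtein)
      osa <- token_distance(a, b, measures$osa)
      lev <- token_distance(a, b, measures$levenshtein)
      expect_lte(dl, osa)
      expect_lte(osa, lev)
    }
  })
})

test_that("appending a foreign token never raises q-gram-family similarity", {
  withr::with_seed(13, {
    qfam <- measures[c("qgram", "jaccard", "cosine")]
    for (i in 1:100) {
      a <- random_tokens(LETTERS[1:5], 6, min_len = 2)
      b <- random_tokens(LETTERS[1:5], 6, min_len = 2)
      b2 <- c(b, "ZZ")  # token absent from a
      for (m in qfam) {
        expect_lte(token_similarity(a, b2, m), token_similarity(a, b, m) + 1e-12)
      }
    }
  })
})

test_that("similarity vectors align with the context's pattern list", {
  db <- table1_db()
  pats <- filter_maximal(mine_frequent(db, table1_ids(db, ">65"),
                                       mining_config(2 / 3)))
  m <- measures$levenshtein
  v <- similarity_vector(db$sequence[[1]], pats, m)
  expect_length(v, nrow(pats))
  expect_equal(v, vapply(pats$pattern, function(p) {
    token_similarity(seq_tokens(db$sequence[[1]]), seq_tokens(p), m)
  }, 0))
  # a trajectory identical to a pattern scores 1 on that element
  v2 <- similarity_vector(pats$pattern[[1]], pats, m)
  expect_equal(v2[1], 1)
  expect_warning(v3 <- similarity_vector(db$sequence[[1]],
                                         pats[0, ], m), "no patterns")
  expect_length(v3, 0)
})

test_that("similarity discretization uses the 0.4 and 0.6 cuts", {
  expect_equal(as.character(discretize_similarity(c(0, 0.39, 0.4, 0.59, 0.6, 1))),
               c("low", "low", "medium", "medium", "strong", "strong"))
  expect_error(discretize_similarity(1.2), class = "careseq_domain_error")
  expect_error(discretize_similarity(0.5, low_cut = 0.7, strong_cut = 0.6),
               class = "careseq_config_error")
})
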