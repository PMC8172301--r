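test_that("subsequence embedding respects order and itemset containment", {
  p1 <- table1_db()$sequence[[1]]  # <(I21 R07)(I20)>
  expect_true(is_subsequence(new_pattern(c("R07", "I20")), p1))
  expect_true(is_subsequence(list(), p1))
  expect_false(is_subsequence(new_pattern(c("I20", "R07")),
                              new_pattern(c("R07", "I20"))))
  # itemset containment: (R07 I21) must sit inside one itemset
  expect_true(is_subsequence(new_pattern(list(c("R07", "I21"))), p1))
  expect_false(is_subsequence(new_pattern(list(c("R07", "I20"))), p1))
  # greedy scan agrees with the recursive definition on random cases
  withr::with_seed(42, {
    for (i in 1:200) {
      s <- random_micro_db(1, letters[1:4], 6)$sequence[[1]]
      p <- new_pattern(random_tokens(letters[1:4], 3, min_len = 1))
      expect_equal(is_subsequence(p, s), ref_embed(p, s))
    }
  })
})

test_that("support counts supporting patients as a fraction of the context", {
  db <- table1_db()
  p <- new_pattern(c("R07", "I20"))
  expect_equal(pattern_support(p, db, table1_ids(db, "45-65")), 1 / 6)
  expect_equal(pattern_support(p, db, table1_ids(db, ">65")), 7 / 8)
  expect_equal(pattern_support(list(), db), 1)
  expect_equal(pattern_support(new_pattern("X99"), db), 0)
  expect_error(pattern_support(p, db, character(0)),
               class = "careseq_domain_error")
  # invariant to permuting patient order
  perm <- withr::with_seed(7, db[sample.int(nrow(db)), ])
  expect_equal(pattern_support(p, new_seq_db(perm), table1_ids(db, ">65")),
               7 / 8)
})

test_that("frequency decisions at the minimum-support boundary are exact", {
  db <- table1_db()
  cfg <- mining_config(min_support = 2 / 3)
  over65 <- mine_frequent(db, table1_ids(db, ">65"), cfg)
  young <- mine_frequent(db, table1_ids(db, "45-65"), cfg)
  expect_true("<(R07) (I20)>" %in% over65$pattern_str)
  expect_false("<(R07) (I20)>" %in% young$pattern_str)
  expect_true(all(over65$support >= 2 / 3))

  # identical single-item sequences at min_support 1
  uni <- tibble::tibble(patient_id = c("a", "b", "c"),
                        sequence = rep(list(new_pattern("I21")), 3))
  expect_equal(mine_frequent(uni, config = mining_config(1))$pattern_str,
               "<(I21)>")
})

test_that("mined outputs satisfy prefix anti-monotonicity", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      db <- random_micro_db(10, c("I20", "I21", "I25", "R07"), 5)
      res <- mine_frequent(db, config = mining_config(0.2))
      for (i in seq_len(nrow(res))) {
        pat <- res$pattern[[i]]
        if (length(pat) > 1) {
          prefix_sup <- pattern_support(pat[-length(pat)], db)
          expect_gte(prefix_sup, res$support[i])
        }
      }
    }
  })
})

test_that("itemset growth finds multi-code patterns when enabled", {
  db <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    sequence = list(new_pattern(list("R07", c("I20", "I25"))),
                    new_pattern(list(c("I20", "I25", "I48"))),
                    new_pattern(list("I10", c("I20", "I25"), "I50")))
  )
  multi <- mine_frequent(db, config = mining_config(1, allow_multi_item = TRUE))
  expect_true("<(I20 I25)>" %in% multi$pattern_str)
  single <- mine_frequent(db, config = mining_config(1))
  expect_false(any(grepl(" ", gsub(") (", ")(", single$pattern_str, fixed = TRUE))))
})

test_that("maximal filtering removes embedded patterns and is idempotent", {
  f <- lapply(list("I20", c("I20", "I21", "I25"), c("I20", "I21"),
                   c("I21", "I25"), c("I21", "I20"), c("I20", "I21", "I24")),
              new_pattern)
  fp <- filter_maximal(f)
  expect_setequal(vapply(fp, pattern_to_string, ""),
                  c("<(I20) (I21) (I25)>", "<(I21) (I20)>",
                    "<(I20) (I21) (I24)>"))
  expect_equal(filter_maximal(fp), fp)
  # pairwise incomparable
  for (i in seq_along(fp)) for (j in seq_along(fp)) {
    if (i != j) expect_false(is_subsequence(fp[[i]], fp[[j]]))
  }
  # nested chain collapses to its longest element; singleton is kept
  chain <- lapply(list("I20", c("I20", "I21"), c("I20", "I21", "I25")),
                  new_pattern)
  expect_equal(vapply(filter_maximal(chain), pattern_to_string, ""),
               "<(I20) (I21) (I25)>")
  expect_equal(filter_maximal(chain[1]), chain[1])
})

test_that("contextual mining composes mining and maximal filtering per context", {
  db <- table1_db()
  ctx <- enumerate_contexts(db, min_patients = 3, min_events_per_class = 1)
  one <- ctx[which(is.na(ctx$sex) & ctx$age_class == ">65" &
                     is.na(ctx$stay_class)), ]
  cfg <- mining_config(2 / 3)
  combined <- mine_contextual_maximal(db, one, cfg)
  manual <- filter_maximal(mine_frequent(db, one, cfg))
  expect_setequal(combined$pattern_str, manual$pattern_str)
  expect_true(all(combined$support >= 2 / 3))
  # canonical ordering: support descending, then pattern string
  expect_false(is.unsorted(rev(combined$support)))
})

test_that("a pattern frequent in one context only is reported there only", {
  # plant a three-code pattern at 40% in men and 2% in women
  rp <- tibble::tibble(
    sex = c("man", "woman"), age_class = NA_character_,
    stay_class = NA_character_,
    pattern = rep(list(new_pattern(c("R07", "I20", "I21"))), 2),
    prob = c(0.4, 0.02)
  )
  coh <- generate_cohort(cohort_config(n_patients = 600, risk_patterns = rp,
                                       outcome_coef = 0,
                                       outcome_intercept = qlogis(0.14),
                                       seed = 5))
  db <- discretize_covariates(coh$db)
  ctx <- enumerate_contexts(db, min_patients = 10, min_events_per_class = 0)
  men <- ctx[which(ctx$sex == "man" & is.na(ctx$age_class) &
                     is.na(ctx$stay_class)), ]
  women <- ctx[which(ctx$sex == "woman" & is.na(ctx$age_class) &
                       is.na(ctx$stay_class)), ]
  cfg <- mining_config(0.1)
  in_men <- mine_frequent(db, men, cfg)
  in_women <- mine_frequent(db, women, cfg)
  target <- "<(R07) (I20) (I21)>"
  expect_true(target %in% in_men$pattern_str)
  expect_false(target %in% in_women$pattern_str)
})

test_that("the resource cap trips instead of flooding", {
  db <- random_micro_db(6, letters[1:4], 5)
  expect_error(mine_frequent(db, config = mining_config(0.01, max_patterns = 5L)),
               class = "careseq_resource_error")
})
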