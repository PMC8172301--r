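test_that("stay records ingest, reject incomplete rows, and round-trip the worked example", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(table1_records(), path)
  recs <- read_stay_records(path)
  expect_equal(length(unique(recs$patient_id)), 14)

  # a missing code is rejected, the other rows kept
  bad <- table1_records()
  bad$code[3] <- NA
  readr::write_csv(bad, path)
  expect_message(recs2 <- read_stay_records(path), "Rejected 1")
  expect_equal(nrow(recs2), nrow(bad) - 1)

  expect_error(read_stay_records(file.path(tempdir(), "absent.csv")),
               class = "careseq_input_error")
  bad$code_system <- "SNOMED"
  readr::write_csv(bad, path)
  expect_error(read_stay_records(path), class = "careseq_config_error")
})

test_that("stay filtering keeps exactly prefix-matched codes and preserves order", {
  recs <- tibble::tibble(patient_id = c("a", "a", "a", "b"),
                         order_index = c(1, 2, 3, 1),
                         code = c("I21", "J44", "R07", "J44"))
  expect_message(kept <- filter_relevant_stays(recs, c("I2", "R07", "I50")),
                 "lost all stays")
  expect_equal(kept$code, c("I21", "R07"))
  expect_false("b" %in% kept$patient_id)

  # prefixes covering all codes: identity
  all_kept <- filter_relevant_stays(recs, c("I", "J", "R"))
  expect_equal(all_kept, tibble::as_tibble(recs))

  # every worked-example code starts with I or R
  expect_equal(length(unique(filter_relevant_stays(table1_records(),
                                                   c("I", "R"))$patient_id)),
               14)
})

test_that("trajectory building groups codes by order index and ignores row order", {
  recs <- tibble::tibble(
    patient_id = "P1",
    order_index = c(2, 2, 4),
    code = c("R07", "I21", "I20")
  )
  db <- build_trajectories(recs)
  expect_equal(db$sequence[[1]], new_pattern(list(c("I21", "R07"), "I20")),
               ignore_attr = TRUE)
  expect_equal(db$n_stays, 2L)

  shuffled <- recs[c(3, 1, 2), ]
  expect_equal(build_trajectories(shuffled), db)

  dup <- recs[c(1, 1, 2, 3), ]
  expect_warning(db2 <- build_trajectories(dup), "Deduplicated")
  expect_equal(db2, db)

  single <- build_trajectories(tibble::tibble(patient_id = "q",
                                              order_index = 7, code = "I50"))
  expect_equal(single$sequence[[1]], new_pattern("I50"), ignore_attr = TRUE)
})

test_that("covariate discretization uses left-inclusive boundaries and the inclusion age", {
  db <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"),
    sequence = rep(list(new_pattern("I21")), 4),
    sex = c("woman", "man", "man", "man"),
    age = c(66, 65, 50, 44),
    n_stays = c(7L, 5L, 6L, 3L),
    outcome = "alive"
  )
  expect_message(out <- discretize_covariates(db), "inclusion age")
  expect_equal(nrow(out), 3)  # the 44-year-old is excluded
  expect_equal(out$age_class, c(">65", "45-65", "45-65"))
  expect_equal(out$stay_class, c(">5", "<=5", ">5"))
})

test_that("context enumeration yields the 27-cell hierarchy with refinement and screening", {
  db <- table1_db()
  ctx <- enumerate_contexts(db, min_patients = 3, min_events_per_class = 1)
  expect_equal(nrow(ctx), 27)
  general <- ctx[ctx$label == "general", ]
  expect_setequal(general$member_ids[[1]], db$patient_id)

  # child members are a subset of every parent context's members
  parent <- ctx[!is.na(ctx$sex) & is.na(ctx$age_class) & is.na(ctx$stay_class), ]
  child <- ctx[!is.na(ctx$sex) & !is.na(ctx$age_class) & !is.na(ctx$stay_class), ]
  for (i in seq_len(nrow(child))) {
    par <- parent$member_ids[[which(parent$sex == child$sex[i])]]
    expect_true(all(child$member_ids[[i]] %in% par))
  }

  # membership = exactly the patients satisfying the constraints
  row <- ctx[which(ctx$sex == "man" & ctx$age_class == ">65" &
                     is.na(ctx$stay_class)), ]
  expect_setequal(row$member_ids[[1]],
                  db$patient_id[db$sex == "man" & db$age_class == ">65"])

  # all-identical covariates: non-matching contexts are empty and flagged
  uni <- db
  uni$sex <- "man"; uni$age_class <- ">65"; uni$stay_class <- "<=5"
  ctx2 <- enumerate_contexts(uni, min_patients = 1, min_events_per_class = 0)
  woman_ctx <- ctx2[which(ctx2$sex == "woman" & is.na(ctx2$age_class) &
                            is.na(ctx2$stay_class)), ]
  expect_equal(woman_ctx$n_patients, 0L)
  expect_true(woman_ctx$excluded)

  # a sparse cell fails the minimum-size screen but is still listed
  ctx3 <- enumerate_contexts(db, min_patients = 4, min_events_per_class = 1)
  sparse <- ctx3[which(ctx3$sex == "woman" & ctx3$age_class == "45-65" &
                         !is.na(ctx3$stay_class)), ]
  expect_true(all(sparse$excluded))
  expect_equal(nrow(ctx3), 27)
})

test_that("a sequential database round-trips through JSON and stay-record CSV", {
  db <- table1_db()
  json <- withr::local_tempfile(fileext = ".json")
  write_seq_db_json(db, json)
  back <- read_seq_db_json(json)
  expect_equal(back$patient_id, db$patient_id)
  expect_equal(back$sequence, db$sequence, ignore_attr = TRUE)
  expect_equal(back$outcome, db$outcome)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_stay_records(db, csv)
  rebuilt <- build_trajectories(read_stay_records(csv))
  ord <- match(db$patient_id, rebuilt$patient_id)
  expect_equal(rebuilt$sequence[ord], db$sequence, ignore_attr = TRUE)
  expect_equal(rebuilt$outcome[ord], db$outcome)
})
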