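# The 14-patient worked-example database: per-patient month-grouped ICD-10
# itemsets, eight patients aged >65 and six aged 45-65.
table1_sequences <- function() {
  list(
    P1  = list(c("R07", "I21"), "I20"),
    P2  = list(c("R07", "I50"), "I20"),
    P3  = list("R07", "R07", "I20"),
    P4  = list("I25", "R07", c("I20", "I25")),
    P5  = list("I21", c("R07", "I25"), c("I20", "I25", "I21")),
    P6  = list("I20", "R07"),
    P7  = list("R07", "I20", "R07"),
    P8  = list("I21", "R07", c("I20", "I25")),
    P9  = list("R07", "R07", c("I20", "I21")),
    P10 = list(c("I20", "I25", "I21")),
    P11 = list(c("I20", "I21"), "R07"),
    P12 = list("I50", c("I20", "I25", "I21"), "R07"),
    P13 = list(c("I20", "I21", "I50")),
    P14 = list("I20", "R07", "I50")
  )
}

table1_db <- function() {
  seqs <- table1_sequences()
  sex <- c("man", "man", "man", "man", "man", "woman", "woman", "woman",
           "man", "man", "man", "woman", "woman", "woman")
  age <- c(rep(70, 8), rep(50, 6))
  db <- tibble::tibble(
    patient_id = names(seqs),
    sequence = lapply(seqs, new_pattern),
    sex = sex, age = age,
    n_stays = lengths(seqs),
    outcome = rep(c("alive", "dead"), 7)
  )
  discretize_covariates(db)
}

table1_ids <- function(db, age_class) db$patient_id[db$age_class == age_class]

# stay-record rows for the same database (one row per code per stay)
table1_records <- function() {
  db <- table1_db()
  tibble::as_tibble(do.call(rbind, lapply(seq_len(nrow(db)), function(i) {
    s <- db$sequence[[i]]
    data.frame(patient_id = db$patient_id[i],
               order_index = rep(seq_along(s), lengths(s)),
               code = unlist(s), code_system = "ICD10",
               sex = db$sex[i], age = db$age[i], outcome = db$outcome[i])
  })))
}

# random micro-database of single-item-itemset sequences
random_micro_db <- function(n_patients, vocab, max_len) {
  tibble::tibble(
    patient_id = sprintf("p%02d", seq_len(n_patients)),
    sequence = lapply(seq_len(n_patients), function(i) {
      new_pattern(sample(vocab, sample.int(max_len, 1), replace = TRUE))
    })
  )
}

random_tokens <- function(vocab, max_len, min_len = 0) {
  n <- sample(min_len:max_len, 1)
  if (n == 0) character(0) else sample(vocab, n, replace = TRUE)
}
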