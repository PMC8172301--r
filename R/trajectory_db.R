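# Stay-level records -> per-patient trajectories, covariate classes and the
# context hierarchy.

#' Read stay-level records from a delimited file
#'
#' Expects one row per code per stay with header
#' `patient_id,order_index,code,code_system,sex,age,outcome`. Rows missing a
#' patient id or an event code are rejected; the number of rejected rows is
#' reported with a message.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default comma).
#' @return A tibble of stay records with the columns above. Covariate and
#'   outcome columns absent from the file are allowed and filled with `NA`.
#' @export
read_stay_records <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(sprintf("Stay-record file not found: %s", path),
          class = "careseq_input_error")
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!all(c("patient_id", "order_index", "code") %in% names(raw))) {
    abort("Stay-record file must contain patient_id, order_index and code columns.",
          class = "careseq_input_error")
  }
  for (col in c("code_system", "sex", "age", "outcome")) {
    if (!col %in% names(raw)) raw[[col]] <- NA
  }
  if (any(!is.na(raw$code_system) &
          !raw$code_system %in% c("ICD10", "DRG"))) {
    abort("code_system must be ICD10 or DRG.",
          class = "careseq_config_error")
  }
  raw <- mutate(raw,
                patient_id = as.character(.data$patient_id),
                code = as.character(.data$code))
  bad <- is.na(raw$patient_id) | !nzchar(raw$patient_id) |
    is.na(raw$code) | !nzchar(raw$code)
  if (any(bad)) {
    inform(sprintf("Rejected %d record(s) with missing patient_id or code.",
                   sum(bad)))
  }
  as_tibble(raw[!bad, c("patient_id", "order_index", "code", "code_system",
                        "sex", "age", "outcome")])
}

#' Keep only stays whose code matches a relevant prefix
#'
#' Filters stay records to those whose event code starts with one of the
#' supplied prefixes (e.g. the code families that define a disease area).
#' Relative order within each patient is preserved. Patients whose every stay
#' is removed disappear from the output; a message reports how many.
#'
#' @param records A stay-record tibble (see [read_stay_records()]).
#' @param keep_prefixes Non-empty character vector of code prefixes.
#' @return The filtered stay-record tibble.
#' @examples
#' recs <- tibble::tibble(patient_id = "P1", order_index = 1:2,
#'                        code = c("I21", "J44"))
#' filter_relevant_stays(recs, c("I2", "R07", "I50"))
#' @export
filter_relevant_stays <- function(records, keep_prefixes) {
  if (length(keep_prefixes) == 0) {
    abort("keep_prefixes must be non-empty.", class = "careseq_config_error")
  }
  rx <- paste0("^(", paste(escape_regex(keep_prefixes), collapse = "|"), ")")
  kept <- records[grepl(rx, records$code), , drop = FALSE]
  lost <- setdiff(unique(records$patient_id), unique(kept$patient_id))
  if (length(lost) > 0) {
    inform(sprintf("%d patient(s) lost all stays under filtering and were dropped.",
                   length(lost)))
  }
  as_tibble(kept)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Build per-patient trajectories from stay records
#'
#' Codes sharing a patient's `order_index` form one itemset; itemsets are
#' ordered by `order_index`. Duplicate (patient, order_index, code) triples
#' are deduplicated with a warning. Covariates and outcome, when present in
#' the records, are carried over (one value per patient).
#'
#' @param records A stay-record tibble.
#' @return A sequential database: a tibble with one row per patient and
#'   columns `patient_id`, `sequence` (list column of itemset lists), `sex`,
#'   `age`, `n_stays` (number of itemsets, i.e. distinct stay positions) and
#'   `outcome`, classed `careseq_db`.
#' @export
build_trajectories <- function(records) {
  for (col in c("sex", "age", "outcome")) {
    if (!col %in% names(records)) records[[col]] <- NA
  }
  dup <- duplicated(records[c("patient_id", "order_index", "code")])
  if (any(dup)) {
    warn(sprintf("Deduplicated %d repeated (patient, order_index, code) record(s).",
                 sum(dup)))
    records <- records[!dup, , drop = FALSE]
  }
  records <- arrange(records, .data$patient_id, .data$order_index)
  per_patient <- function(df) {
    its <- split(df$code, factor(df$order_index, levels = unique(df$order_index)))
    seqs <- new_pattern(unname(its))
    tibble(
      sequence = list(seqs),
      sex = first_non_na(df$sex),
      age = first_non_na(df$age),
      n_stays = length(seqs),
      outcome = first_non_na(df$outcome)
    )
  }
  db <- records |>
    group_by(.data$patient_id) |>
    dplyr::group_modify(~ per_patient(.x)) |>
    ungroup()
  new_seq_db(db)
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA else x[[1]]
}

new_seq_db <- function(df) {
  stopifnot(all(c("patient_id", "sequence") %in% names(df)))
  class(df) <- unique(c("careseq_db", class(as_tibble(df))))
  df
}

#' @export
print.careseq_db <- function(x, ...) {
  cat(sprintf("A sequential database of %d patient trajectories\n", nrow(x)))
  NextMethod()
}

#' Discretize patient covariates into context classes
#'
#' Adds `age_class` (`"45-65"` when age is at most `age_cut`, `">65"` above)
#' and `stay_class` (`"<=5"` when the stay count is at most `stay_cut`, `">5"`
#' above). Ages at or below `age_min` violate the cohort inclusion rule and
#' are dropped with a message.
#'
#' @param db A sequential database (see [build_trajectories()]).
#' @param age_cut Age boundary in years; the boundary value falls in the lower
#'   class (default 65).
#' @param stay_cut Stay-count boundary; the boundary value falls in the lower
#'   class (default 5).
#' @param age_min Exclusive lower inclusion bound on age (default 45).
#' @return The database with `age_class` and `stay_class` columns added.
#' @examples
#' db <- tibble::tibble(patient_id = "P1",
#'                      sequence = list(new_pattern("I21")),
#'                      sex = "man", age = 66, n_stays = 7, outcome = "alive")
#' discretize_covariates(db)
#' @export
discretize_covariates <- function(db, age_cut = 65, stay_cut = 5, age_min = 45) {
  too_young <- !is.na(db$age) & db$age <= age_min
  if (any(too_young)) {
    inform(sprintf("Excluded %d patient(s) at or below the inclusion age of %g.",
                   sum(too_young), age_min))
    db <- db[!too_young, , drop = FALSE]
  }
  db <- mutate(db,
    age_class = ifelse(.data$age <= age_cut, "45-65", ">65"),
    stay_class = ifelse(.data$n_stays <= stay_cut, "<=5", ">5")
  )
  new_seq_db(db)
}

context_attrs <- c("sex", "age_class", "stay_class")

#' Enumerate the context hierarchy
#'
#' Forms every conjunction over sex, age class and stay class with each
#' attribute either fixed to one of its observed two levels or left free:
#' 3 x 3 x 3 = 27 candidate contexts including the fully free "general"
#' context. Contexts below the minimum patient count, or with fewer than
#' `min_events_per_class` patients in either outcome class, are flagged
#' `excluded` but still listed.
#'
#' @param db A sequential database with discretized covariates and outcomes.
#' @param min_patients Minimum context size to be usable for modeling.
#' @param min_events_per_class Minimum number of patients per outcome class.
#' @return A tibble with one row per context: the three constraint columns
#'   (`NA` = free), `label`, `member_ids` (list column), `n_patients`,
#'   `n_deaths` and `excluded`.
#' @export
enumerate_contexts <- function(db, min_patients = 30, min_events_per_class = 5) {
  if (!all(context_attrs %in% names(db))) {
    abort("Covariates must be discretized before enumerating contexts.",
          class = "careseq_config_error")
  }
  levels_of <- list(sex = c(NA, "man", "woman"),
                    age_class = c(NA, "45-65", ">65"),
                    stay_class = c(NA, "<=5", ">5"))
  grid <- tidyr::expand_grid(sex = levels_of$sex,
                             age_class = levels_of$age_class,
                             stay_class = levels_of$stay_class)
  rows <- pmap(grid, function(sex, age_class, stay_class) {
    keep <- rep(TRUE, nrow(db))
    if (!is.na(sex)) keep <- keep & db$sex == sex
    if (!is.na(age_class)) keep <- keep & db$age_class == age_class
    if (!is.na(stay_class)) keep <- keep & db$stay_class == stay_class
    ids <- db$patient_id[keep & !is.na(keep)]
    deaths <- sum(db$outcome[db$patient_id %in% ids] == "dead", na.rm = TRUE)
    tibble(sex = sex, age_class = age_class, stay_class = stay_class,
           label = context_label(sex, age_class, stay_class),
           member_ids = list(ids),
           n_patients = length(ids),
           n_deaths = deaths)
  })
  out <- bind_rows(rows)
  out$excluded <- out$n_patients < min_patients |
    out$n_deaths < min_events_per_class |
    (out$n_patients - out$n_deaths) < min_events_per_class
  out
}

context_label <- function(sex, age_class, stay_class) {
  parts <- c(
    if (!is.na(sex)) sex,
    if (!is.na(age_class)) paste0(age_class, " years"),
    if (!is.na(stay_class)) paste0(stay_class, " stays")
  )
  if (length(parts) == 0) "general" else paste(parts, collapse = " and ")
}

#' Restrict a database to the members of one context
#'
#' @param db A sequential database.
#' @param context A one-row slice of the tibble returned by
#'   [enumerate_contexts()], or a character vector of patient ids.
#' @return The database rows for the context members.
#' @export
context_members <- function(db, context) {
  ids <- if (is.character(context)) context else context$member_ids[[1]]
  new_seq_db(db[db$patient_id %in% ids, , drop = FALSE])
}

#' Write a sequential database as stay-level records
#'
#' Emits the delimited format [read_stay_records()] consumes: one row per
#' code per stay, with `order_index` equal to the itemset position.
#'
#' @param db A sequential database.
#' @param path Output CSV path.
#' @param code_system Code system tag written on every row.
#' @return `path`, invisibly.
#' @export
write_stay_records <- function(db, path, code_system = "ICD10") {
  rows <- map(seq_len(nrow(db)), function(i) {
    s <- db$sequence[[i]]
    tibble(patient_id = db$patient_id[[i]],
           order_index = rep(seq_along(s), lengths(s)),
           code = unlist(s, use.names = FALSE),
           code_system = code_system,
           sex = db$sex[[i]], age = db$age[[i]], outcome = db$outcome[[i]])
  })
  readr::write_csv(bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

#' Serialize a sequential database to JSON
#'
#' Writes patients, itemset sequences, covariates and outcomes to a JSON file
#' that [read_seq_db_json()] restores exactly.
#'
#' @param db A sequential database.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_seq_db_json <- function(db, path) {
  payload <- list(patients = lapply(seq_len(nrow(db)), function(i) {
    list(patient_id = db$patient_id[[i]],
         sequence = lapply(db$sequence[[i]], as.character),
         sex = db$sex[[i]], age = db$age[[i]],
         n_stays = db$n_stays[[i]], outcome = db$outcome[[i]])
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a sequential database from JSON
#'
#' @param path A file written by [write_seq_db_json()].
#' @return A sequential database tibble.
#' @export
read_seq_db_json <- function(path) {
  payload <- jsonlite::read_json(path)
  rows <- map(payload$patients, function(p) {
    tibble(patient_id = p$patient_id,
           sequence = list(new_pattern(lapply(p$sequence, unlist))),
           sex = p$sex %||% NA_character_,
           age = p$age %||% NA_real_,
           n_stays = p$n_stays,
           outcome = p$outcome %||% NA_character_)
  })
  db <- bind_rows(rows)
  db$age <- as.numeric(db$age)
  db$n_stays <- as.integer(db$n_stays)
  new_seq_db(db)
}
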