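# Synthetic cohort generator with planted patterns and known ground truth.
#
# Emulates the structure of an administrative discharge cohort: per-patient
# ordered sequences of coded stays, sex/age/stay-count covariates, risk
# patterns planted with context-specific probabilities, and a binary
# in-hospital death whose probability follows a logistic model in the
# trajectory's maximal similarity to the risk patterns. Because the outcome
# works through similarity rather than raw pattern presence, the
# featurization step sits on the causal path and its correctness is
# detectable end to end.

default_vocabulary <- c("R07", "I20", "I21", "I50", "I10", "I25", "I48",
                        "E11", "E78", "J44", "K21", "N18", "M54", "R55",
                        "Z51", "I63")

#' Synthetic cohort configuration
#'
#' Defaults sketch a mid-2010s cardiovascular discharge cohort: about 5,000
#' patients, 45% aged 45-65 and 55% over 65, a mean of roughly five stays per
#' patient (range 4-10), a 16-code vocabulary, one chest-pain-to-heart-failure
#' risk trajectory planted in 30% of the cohort, and a steep logistic outcome
#' model giving a death prevalence under 20%.
#'
#' @param n_patients Number of patients.
#' @param p_man Probability of sex `"man"`.
#' @param p_age_young Probability of the 45-65 age class; ages are uniform
#'   within the class ranges.
#' @param stay_min,stay_lambda,stay_max Stay counts are
#'   `stay_min + min(Poisson(stay_lambda), stay_max - stay_min)`.
#' @param vocabulary Character vector of event codes; filler codes are drawn
#'   uniformly from it.
#' @param risk_patterns A tibble with columns `sex`, `age_class`,
#'   `stay_class` (constraints, `NA` = free), `pattern` (list column) and
#'   `prob` (planting probability). Each patient uses the first row whose
#'   constraints they satisfy. Default: one global four-code risk trajectory
#'   planted with probability 0.3.
#' @param noise_rate Per-planted-position probability that the pattern code
#'   is corrupted into a random code (default 0: noise enters only through
#'   the interleaved filler codes).
#' @param outcome_intercept,outcome_coef Logistic outcome model:
#'   `P(death) = plogis(intercept + coef * max similarity to the applicable
#'   risk patterns)`. The defaults (-9, 12) encode a strong signal; a null
#'   cohort uses `outcome_coef = 0` with `outcome_intercept = qlogis(0.14)`.
#' @param outcome_measure Similarity measure name the outcome model uses
#'   (default `"levenshtein"`).
#' @param seed Integer seed.
#' @return A list of class `careseq_cohort_config`.
#' @export
cohort_config <- function(n_patients = 5000L,
                          p_man = 0.6,
                          p_age_young = 0.45,
                          stay_min = 4L, stay_lambda = 1.2, stay_max = 10L,
                          vocabulary = default_vocabulary,
                          risk_patterns = NULL,
                          noise_rate = 0,
                          outcome_intercept = -9,
                          outcome_coef = 12,
                          outcome_measure = "levenshtein",
                          seed = 1L) {
  if (length(vocabulary) == 0) {
    abort("vocabulary must be non-empty.", class = "careseq_config_error")
  }
  if (is.null(risk_patterns)) {
    risk_patterns <- tibble(
      sex = NA_character_, age_class = NA_character_,
      stay_class = NA_character_,
      pattern = list(new_pattern(c("R07", "I20", "I21", "I50"))),
      prob = 0.3
    )
  }
  probs <- c(p_man, p_age_young, noise_rate, risk_patterns$prob)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].", class = "careseq_config_error")
  }
  if (any(vapply(risk_patterns$pattern, pattern_length, 0L) > stay_max)) {
    abort("A risk pattern is longer than the maximum sequence length.",
          class = "careseq_config_error")
  }
  structure(list(n_patients = as.integer(n_patients), p_man = p_man,
                 p_age_young = p_age_young, stay_min = as.integer(stay_min),
                 stay_lambda = stay_lambda, stay_max = as.integer(stay_max),
                 vocabulary = vocabulary, risk_patterns = risk_patterns,
                 noise_rate = noise_rate,
                 outcome_intercept = outcome_intercept,
                 outcome_coef = outcome_coef,
                 outcome_measure = outcome_measure, seed = as.integer(seed)),
            class = "careseq_cohort_config")
}

#' Generate a synthetic cohort with ground truth
#'
#' Per patient: draw covariates; draw a sequence length; with the applicable
#' context's planting probability, embed that context's risk pattern in order
#' at random positions (each planted code corrupted with probability
#' `noise_rate`), filling the remaining positions with uniform filler codes;
#' then draw death from the logistic outcome model in the realised maximal
#' similarity to the applicable risk patterns.
#'
#' @param config A [cohort_config()].
#' @return A list of class `careseq_cohort`: `db` (a sequential database with
#'   `sex`, `age`, `n_stays`, `outcome`) and `truth` (a tibble with the
#'   planted flag, the applicable pattern, the realised similarity and the
#'   true death probability per patient), plus the generating `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "careseq_cohort_config"))
  measure <- similarity_measure(config$outcome_measure)
  rp <- config$risk_patterns
  withr::with_seed(config$seed, {
    n <- config$n_patients
    sex <- ifelse(runif(n) < config$p_man, "man", "woman")
    young <- runif(n) < config$p_age_young
    age <- ifelse(young, runif(n, 45.001, 65), runif(n, 65.001, 90))
    n_stays <- config$stay_min +
      pmin(rpois(n, config$stay_lambda), config$stay_max - config$stay_min)
    age_class <- ifelse(age <= 65, "45-65", ">65")
    stay_class <- ifelse(n_stays <= 5, "<=5", ">5")

    rows <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      ridx <- match_risk_row(rp, sex[i], age_class[i], stay_class[i])
      planted <- !is.na(ridx) && runif(1) < rp$prob[ridx]
      len <- n_stays[i]
      codes <- sample(config$vocabulary, len, replace = TRUE)
      if (planted) {
        pat <- seq_tokens(rp$pattern[[ridx]])
        pos <- sort(sample.int(len, length(pat)))
        keep <- runif(length(pat)) >= config$noise_rate
        codes[pos[keep]] <- pat[keep]
      }
      sim <- if (is.na(ridx)) 0 else
        max(vapply(rp$pattern[!is.na(match_rows(rp, sex[i], age_class[i],
                                                stay_class[i]))],
                   function(p) token_similarity(codes, seq_tokens(p), measure),
                   0))
      p_death <- plogis(config$outcome_intercept + config$outcome_coef * sim)
      rows[[i]] <- list(sequence = new_pattern(as.list(codes)))
      truth[[i]] <- tibble(planted = planted,
                           pattern_row = ifelse(is.na(ridx), NA_integer_, ridx),
                           true_similarity = sim, true_prob = p_death)
    }
    dead <- runif(n) < map_dbl(truth, ~ .x$true_prob)
    db <- tibble(
      patient_id = sprintf("S%05d", seq_len(n)),
      sequence = map(rows, "sequence"),
      sex = sex, age = age, n_stays = as.integer(n_stays),
      outcome = ifelse(dead, "dead", "alive")
    )
    truth_tbl <- dplyr::bind_cols(tibble(patient_id = db$patient_id),
                                  bind_rows(truth))
    structure(list(db = new_seq_db(db), truth = truth_tbl, config = config),
              class = "careseq_cohort")
  })
}

# first risk row whose constraints the patient satisfies (NA when none).
match_risk_row <- function(rp, sex, age_class, stay_class) {
  hits <- match_rows(rp, sex, age_class, stay_class)
  hits <- which(!is.na(hits))
  if (length(hits) == 0) NA_integer_ else hits[1]
}

match_rows <- function(rp, sex, age_class, stay_class) {
  ok <- (is.na(rp$sex) | rp$sex == sex) &
    (is.na(rp$age_class) | rp$age_class == age_class) &
    (is.na(rp$stay_class) | rp$stay_class == stay_class)
  ifelse(ok, seq_len(nrow(rp)), NA_integer_)
}

#' @export
print.careseq_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %.1f%% deaths, %d planted\n",
              nrow(x$db), 100 * mean(x$db$outcome == "dead"),
              sum(x$truth$planted)))
  invisible(x)
}

#' Ground-truth bookkeeping for a synthetic cohort
#'
#' @param cohort A `careseq_cohort`.
#' @return A tibble with one row per risk-pattern row of the generating
#'   configuration: the configured planting probability, the realised planted
#'   fraction among eligible patients, the fraction of eligible trajectories
#'   actually embedding the pattern (planted or by chance), the mean true
#'   death probability and the realised death prevalence.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "careseq_cohort"))
  rp <- cohort$config$risk_patterns
  db <- cohort$db
  truth <- cohort$truth
  rows <- map(seq_len(nrow(rp)), function(r) {
    eligible <- which(truth$pattern_row == r)
    embeds <- map_lgl(db$sequence[eligible],
                      ~ is_subsequence(rp$pattern[[r]], .x))
    tibble(
      pattern_str = pattern_to_string(rp$pattern[[r]]),
      configured_prob = rp$prob[r],
      n_eligible = length(eligible),
      planted_fraction = mean(truth$planted[eligible]),
      embedded_fraction = mean(embeds),
      mean_true_prob = mean(truth$true_prob[eligible]),
      death_prevalence = mean(db$outcome[eligible] == "dead")
    )
  })
  bind_rows(rows)
}
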