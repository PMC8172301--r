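# Discrimination and accuracy metrics, Pareto (maximal-vector) selection and
# external validation.

#' Confusion-matrix metrics for binary predictions
#'
#' Computes accuracy, sensitivity, specificity, error rate, precision and
#' F-measure, with the death class as positive. A ratio with zero denominator
#' is reported as 0 and flagged in the `degenerate` column.
#'
#' @param labels Factor or character vector with values `alive`/`dead`.
#' @param predicted Hard predictions on the same coding.
#' @return A one-row tibble of metrics.
#' @export
confusion_metrics <- function(labels, predicted) {
  labels <- as.character(labels); predicted <- as.character(predicted)
  if (length(labels) != length(predicted)) {
    abort("labels and predictions differ in length.", class = "careseq_domain_error")
  }
  if (!all(c(labels, predicted) %in% c("alive", "dead"))) {
    abort("Labels must be binary alive/dead.", class = "careseq_domain_error")
  }
  tp <- sum(labels == "dead" & predicted == "dead")
  tn <- sum(labels == "alive" & predicted == "alive")
  fp <- sum(labels == "alive" & predicted == "dead")
  fn <- sum(labels == "dead" & predicted == "alive")
  n <- tp + tn + fp + fn
  safe <- function(num, den) if (den == 0) 0 else num / den
  accuracy <- safe(tp + tn, n)
  sensitivity <- safe(tp, tp + fn)
  specificity <- safe(tn, tn + fp)
  precision <- safe(tp, tp + fp)
  f_measure <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  tibble(accuracy = accuracy, sensitivity = sensitivity,
         specificity = specificity, error_rate = 1 - accuracy,
         precision = precision, f_measure = f_measure,
         degenerate = (tp + fn == 0) || (tn + fp == 0) || (tp + fp == 0))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation, equivalent to the trapezoidal area under
#' the ROC curve with ties counted half.
#'
#' @param labels Binary labels (`alive`/`dead`, or 0/1 with 1 = death).
#' @param scores Numeric scores, larger meaning more death-like.
#' @return The AURC in \[0, 1\]; `NA` with a warning when only one class is
#'   present.
#' @export
aurc <- function(labels, scores) {
  y <- as_binary_outcome(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) {
    warn("AURC undefined: only one outcome class present.")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

as_binary_outcome <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      abort("Numeric labels must be 0/1.", class = "careseq_domain_error")
    }
    return(labels)
  }
  as.integer(as.character(labels) == "dead")
}

#' Brier score
#'
#' Mean squared difference between the predicted death probability and the
#' binary outcome.
#'
#' @param labels Binary labels (`alive`/`dead` or 0/1).
#' @param probabilities Predicted death probabilities in \[0, 1\].
#' @return The Brier score in \[0, 1\].
#' @export
brier_score <- function(labels, probabilities) {
  if (any(probabilities < 0 | probabilities > 1)) {
    abort("Probabilities must lie in [0, 1].", class = "careseq_domain_error")
  }
  y <- as_binary_outcome(labels)
  mean((probabilities - y)^2)
}

#' Pareto (maximal-vector) selection of configurations
#'
#' Keeps the records not dominated on all criteria simultaneously: a record
#' is dropped when some other record is at least as good on every criterion
#' and strictly better on at least one. The surviving set is returned in a
#' deterministic order (lexicographic by the criteria, best first, ties by
#' configuration name), so its first row is the nominated single best
#' combination when one is required.
#'
#' @param records A tibble of evaluation records.
#' @param criteria Named character vector mapping metric columns to
#'   orientation (`"max"` or `"min"`). Default: AURC and F-measure maximised,
#'   error rate minimised.
#' @param name_cols Columns identifying a configuration, used for the final
#'   tie-break.
#' @return The non-dominated subset of `records`, ordered as described.
#' @export
pareto_select <- function(records,
                          criteria = c(aurc = "max", f_measure = "max",
                                       error_rate = "min"),
                          name_cols = intersect(c("family", "measure",
                                                  "encoding", "context_label"),
                                                names(records))) {
  if (nrow(records) == 0) return(records)
  if (!all(names(criteria) %in% names(records))) {
    abort("All criteria columns must be present in the records.",
          class = "careseq_config_error")
  }
  # orient every criterion so larger is better
  m <- vapply(names(criteria), function(cn) {
    v <- records[[cn]]
    if (criteria[[cn]] == "min") -v else v
  }, numeric(nrow(records)))
  m <- matrix(m, nrow = nrow(records))
  dominated <- vapply(seq_len(nrow(m)), function(i) {
    any(vapply(seq_len(nrow(m)), function(j) {
      j != i && all(m[j, ] >= m[i, ]) && any(m[j, ] > m[i, ])
    }, TRUE))
  }, TRUE)
  out <- records[!dominated, , drop = FALSE]
  ord_cols <- c(lapply(names(criteria), function(cn) {
    if (criteria[[cn]] == "min") out[[cn]] else -out[[cn]]
  }), lapply(name_cols, function(cn) out[[cn]]))
  out[do.call(order, ord_cols), , drop = FALSE]
}

#' Rank classifier families within each context
#'
#' For each context, families are ordered by their best record under the
#' Pareto criteria (lexicographic: AURC down, F-measure down, error rate up),
#' and the table reports the percentage of contexts in which each family
#' lands at rank 1, 2 and 3.
#'
#' @param records Evaluation records with `context_label`, `family` and the
#'   criteria columns.
#' @param criteria As in [pareto_select()].
#' @param top_n Number of ranks to report (default 3).
#' @return A tibble: `rank`, one column per family, values in percent
#'   (each rank row sums to 100 up to rounding).
#' @export
rank_model_families <- function(records,
                                criteria = c(aurc = "max", f_measure = "max",
                                             error_rate = "min"),
                                top_n = 3L) {
  stopifnot(all(c("context_label", "family") %in% names(records)))
  fams <- sort(unique(records$family))
  ctxs <- unique(records$context_label)
  hits <- matrix(0, nrow = top_n, ncol = length(fams),
                 dimnames = list(NULL, fams))
  # lexicographic order on the oriented criteria: a linear extension of
  # Pareto dominance, so a dominating family always outranks a dominated one.
  lex_order <- function(df) {
    cols <- c(lapply(names(criteria), function(cn) {
      if (criteria[[cn]] == "min") df[[cn]] else -df[[cn]]
    }), list(df$family))
    df[do.call(order, cols), , drop = FALSE]
  }
  for (ctx in ctxs) {
    sub <- records[records$context_label == ctx, , drop = FALSE]
    best <- bind_rows(lapply(split(sub, sub$family),
                             function(d) head(lex_order(d), 1)))
    best <- lex_order(best)
    for (r in seq_len(min(top_n, nrow(best)))) {
      hits[r, best$family[r]] <- hits[r, best$family[r]] + 1
    }
  }
  pct <- 100 * hits / length(ctxs)
  dplyr::bind_cols(tibble(rank = seq_len(top_n)), as_tibble(pct))
}

#' External validation of a trained scorer
#'
#' Applies the scorer once to the untouched external split (unbalanced, as
#' observed) and reports discrimination (AURC) and overall accuracy (Brier
#' score).
#'
#' @param scorer A `careseq_scorer` fitted on internal data only.
#' @param x External predictor tibble.
#' @param labels External outcome labels.
#' @return A one-row tibble with `external_aurc` and `brier`.
#' @export
validate_external <- function(scorer, x, labels) {
  pr <- predict(scorer, x)
  tibble(external_aurc = aurc(labels, pr),
         brier = brier_score(labels, pr))
}
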