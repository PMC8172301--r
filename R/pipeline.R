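# End-to-end study pipeline: mine patterns per context on internal data,
# featurize, train every (model, similarity, encoding) configuration with
# repeated holdout, select by Pareto dominance, and validate externally.

#' Evaluate one (model, similarity, encoding) configuration
#'
#' Internal validation by repeated stratified holdout: in each round the
#' internal feature table is split into training and test parts, the training
#' part is balanced by undersampling, the model is fitted, and hard
#' predictions at the 0.5 threshold are scored on the (unbalanced) test part.
#' Metrics are averaged over rounds; `predicted_deaths` is the mean count of
#' predicted-death test cases, `observed_deaths` the mean observed count.
#' Finally the model is refitted on the whole balanced internal table and
#' applied once to the external table.
#'
#' @param features_internal,features_external Feature tables from
#'   [similarity_features()] for the internal and external parts of one
#'   context.
#' @param family Classifier family name (see [model_config()]).
#' @param encoding `"continuous"` or `"discretized"`.
#' @param repeats Number of holdout rounds (default 5).
#' @param train_fraction Fraction of internal rows used for training in each
#'   round (default 2/3, mirroring a 2163/1082 style split).
#' @param seed Integer seed; round r uses seed + r.
#' @return A one-row tibble of internal metrics, external AURC and Brier
#'   score.
#' @export
evaluate_configuration <- function(features_internal, features_external,
                                   family, encoding = "continuous",
                                   repeats = 5L, train_fraction = 2 / 3,
                                   seed = 1L) {
  af <- assemble_features(features_internal, encoding)
  mc <- model_config(family)
  n <- nrow(af$x)
  rounds <- map(seq_len(repeats), function(r) {
    rs <- seed + r
    idx <- withr::with_seed(rs, stratified_sample(af$y, train_fraction))
    train_x <- af$x[idx, , drop = FALSE]
    train_y <- af$y[idx]
    bal <- balance_classes(tibble(.row = seq_along(train_y),
                                  outcome = as.character(train_y)), seed = rs)
    fit <- train_classifier(train_x[bal$.row, , drop = FALSE],
                            droplevels(train_y[bal$.row]),
                            mc, seed = rs)
    test_x <- af$x[-idx, , drop = FALSE]
    test_y <- af$y[-idx]
    pr <- predict(fit, test_x)
    hard <- ifelse(pr >= 0.5, "dead", "alive")
    cm <- confusion_metrics(test_y, hard)
    mutate(cm, aurc = aurc(test_y, pr),
           predicted_deaths = sum(hard == "dead"),
           observed_deaths = sum(test_y == "dead"))
  })
  internal <- bind_rows(rounds) |>
    summarise(across(c("accuracy", "sensitivity", "specificity", "error_rate",
                       "precision", "f_measure", "aurc", "predicted_deaths",
                       "observed_deaths"), mean))
  bal_all <- balance_classes(tibble(.row = seq_len(n),
                                    outcome = as.character(af$y)), seed = seed)
  final_fit <- train_classifier(af$x[bal_all$.row, , drop = FALSE],
                                droplevels(af$y[bal_all$.row]), mc, seed = seed)
  ext <- assemble_external(features_external, encoding, af$x)
  external <- validate_external(final_fit, ext$x, ext$y)
  dplyr::bind_cols(internal, external)
}

# indices of a stratified training sample preserving class proportions.
stratified_sample <- function(y, fraction) {
  unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    sample(idx, max(1L, round(fraction * length(idx))))
  }), use.names = FALSE)
}

# external features under the same encoding and column set as training.
assemble_external <- function(features_external, encoding, train_x) {
  y <- factor(features_external$outcome, levels = c("alive", "dead"))
  sim_cols <- grep("^sim_", names(features_external), value = TRUE)
  x <- features_external[sim_cols]
  if (encoding == "discretized") {
    x <- as_tibble(lapply(x, discretize_similarity))
  }
  for (cov in c("sex", "age_class")) {
    if (cov %in% names(features_external)) {
      x[[cov]] <- factor(features_external[[cov]])
    }
  }
  list(x = as_tibble(x)[intersect(names(train_x), names(x))], y = y)
}

#' Run the full study pipeline on a sequential database
#'
#' Splits patients into internal and external parts, enumerates the context
#' hierarchy, mines maximal frequent patterns per context on internal
#' patients only, computes similarity features per measure, evaluates every
#' (family, measure, encoding) configuration per context, and returns the
#' evaluation records with the Pareto-selected combinations.
#'
#' @param db A sequential database with covariates and outcomes (discretized
#'   covariates are added when absent).
#' @param families,measures,encodings Configuration axes (defaults: all six
#'   families, all nine measures, both encodings).
#' @param contexts Optional pre-built context tibble; by default contexts are
#'   enumerated from the internal part and screened for minimum size.
#' @param mining A [mining_config()].
#' @param internal_fraction,train_fraction,repeats,seed Split and holdout
#'   parameters (see [split_dataset()] and [evaluate_configuration()]).
#' @param min_patients,min_events_per_class Context screening thresholds.
#' @param general_only Evaluate only the general (whole-cohort) context; the
#'   default for quick studies.
#' @return An object of class `careseq_study`: a list with `records` (one
#'   evaluation record per configuration and context), `selected` (the
#'   Pareto-optimal records per context), `patterns`, `contexts` and the call
#'   parameters.
#' @export
run_study <- function(db,
                      families = names(all_model_families()),
                      measures = names(measure_families),
                      encodings = c("continuous", "discretized"),
                      contexts = NULL,
                      mining = mining_config(min_support = 0.05),
                      internal_fraction = 2 / 3, train_fraction = 2 / 3,
                      repeats = 5L, seed = 1L,
                      min_patients = 30L, min_events_per_class = 5L,
                      general_only = FALSE) {
  if (!all(context_attrs %in% names(db))) {
    db <- discretize_covariates(db)
  }
  parts <- split_dataset(db, internal_fraction, seed = seed)
  internal <- parts$internal
  external <- parts$external
  if (is.null(contexts)) {
    contexts <- enumerate_contexts(internal, min_patients, min_events_per_class)
  }
  if (general_only) {
    contexts <- contexts[contexts$label == "general", , drop = FALSE]
  }
  use <- contexts[!contexts$excluded, , drop = FALSE]
  patterns <- mine_contextual_maximal(internal, use, mining)

  records <- list()
  for (ci in seq_len(nrow(use))) {
    ctx <- use[ci, ]
    pats <- patterns[patterns$context_label == ctx$label, , drop = FALSE]
    if (nrow(pats) == 0) next
    int_db <- context_restrict(internal, ctx)
    ext_db <- context_restrict(external, ctx)
    if (nrow(ext_db) == 0) next
    for (ms in measures) {
      m <- similarity_measure(ms)
      fi <- similarity_features(int_db, pats, m)
      fe <- similarity_features(ext_db, pats, m)
      for (enc in encodings) {
        for (fam in families) {
          rec <- evaluate_configuration(fi, fe, fam, enc,
                                        repeats = repeats,
                                        train_fraction = train_fraction,
                                        seed = seed)
          rec$context_label <- ctx$label
          rec$family <- fam
          rec$measure <- ms
          rec$measure_family <- measure_families[[ms]]
          rec$encoding <- enc
          records[[length(records) + 1L]] <- rec
        }
      }
    }
  }
  records <- bind_rows(records) |>
    relocate("context_label", "family", "measure", "measure_family", "encoding")
  selected <- records |>
    group_by(.data$context_label) |>
    dplyr::group_split() |>
    map(pareto_select) |>
    bind_rows()
  structure(list(records = records, selected = selected,
                 patterns = patterns, contexts = contexts,
                 params = list(families = families, measures = measures,
                               encodings = encodings, repeats = repeats,
                               seed = seed)),
            class = "careseq_study")
}

# membership by the context's own constraints, so a context row enumerated on
# one part of the split applies to the other part too.
context_restrict <- function(db, ctx) {
  keep <- rep(TRUE, nrow(db))
  for (at in context_attrs) {
    if (!is.na(ctx[[at]])) keep <- keep & db[[at]] == ctx[[at]]
  }
  new_seq_db(db[keep & !is.na(keep), , drop = FALSE])
}

#' @export
print.careseq_study <- function(x, ...) {
  cat(sprintf("careseq study: %d configuration(s) over %d context(s)\n",
              nrow(x$records), length(unique(x$records$context_label))))
  cat("Pareto-selected best combination(s):\n")
  print(head(as_tibble(x$selected)[c("context_label", "family", "measure",
                                     "encoding", "aurc", "f_measure",
                                     "error_rate", "external_aurc", "brier")],
             10))
  invisible(x)
}

#' Tidy a study's evaluation records
#'
#' @param x A `careseq_study`.
#' @param ... Unused.
#' @return The per-configuration evaluation records as a tibble.
#' @method tidy careseq_study
#' @export
tidy.careseq_study <- function(x, ...) as_tibble(x$records)

#' One-row study summary
#'
#' @param x A `careseq_study`.
#' @param ... Unused.
#' @return A one-row tibble: configuration count, context count, the
#'   nominated best combination and its internal AURC, external AURC and
#'   Brier score.
#' @method glance careseq_study
#' @export
glance.careseq_study <- function(x, ...) {
  best <- head(x$selected, 1)
  tibble(n_configurations = nrow(x$records),
         n_contexts = length(unique(x$records$context_label)),
         best_family = best$family, best_measure = best$measure,
         best_encoding = best$encoding, best_aurc = best$aurc,
         best_external_aurc = best$external_aurc, best_brier = best$brier)
}

#' Plot internal discrimination by family and similarity measure
#'
#' @param object A `careseq_study`.
#' @param metric Metric column to plot (default `"aurc"`).
#' @param ... Unused.
#' @return A ggplot of the metric by classifier family, coloured by measure
#'   family, faceted by encoding.
#' @method autoplot careseq_study
#' @export
autoplot.careseq_study <- function(object, metric = "aurc", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data[[metric]],
                                   colour = .data$measure_family)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.15,
                                                            height = 0)) +
    ggplot2::facet_wrap(~encoding) +
    ggplot2::labs(x = "classifier family", y = metric,
                  colour = "similarity family")
}
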