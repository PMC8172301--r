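# Dataset splitting, class balancing, feature assembly and the six
# classifier families.
#
# The model families themselves are standard fits (e1071, rpart, nnet,
# class, stats::glm); this module wraps them behind one scorer interface
# that always returns a death probability, so every (model, similarity,
# encoding) configuration is interchangeable downstream.

#' Split a database into internal and external validation parts
#'
#' Patient-level random split: the internal part is used for training and
#' internal validation, the external part is never touched until final
#' validation. Reproducible under a fixed seed.
#'
#' @param db A sequential database with outcomes.
#' @param internal_fraction Fraction of patients assigned to the internal
#'   part (default 2/3, mirroring a 3245/1626 style split).
#' @param seed Integer seed.
#' @return A list with elements `internal` and `external`, both sequential
#'   databases with disjoint patients.
#' @export
split_dataset <- function(db, internal_fraction = 2 / 3, seed = 1L) {
  if (internal_fraction <= 0 || internal_fraction >= 1) {
    abort("internal_fraction must lie in (0, 1).", class = "careseq_config_error")
  }
  counts <- table(db$outcome)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("Need at least 2 patients in each outcome class to split.",
          class = "careseq_split_error")
  }
  n <- nrow(db)
  n_int <- round(internal_fraction * n)
  idx <- withr::with_seed(seed, sample.int(n, n_int))
  list(internal = new_seq_db(db[idx, , drop = FALSE]),
       external = new_seq_db(db[-idx, , drop = FALSE]))
}

#' Balance outcome classes by undersampling
#'
#' Uniformly subsamples the majority class down to the minority class size;
#' every minority record is kept.
#'
#' @param df A data frame with an `outcome` column coded `"alive"`/`"dead"`.
#' @param seed Integer seed.
#' @return The balanced data frame.
#' @export
balance_classes <- function(df, seed = 1L) {
  counts <- table(df$outcome)
  if (length(counts) < 2 || any(counts == 0)) {
    abort("Both outcome classes must be present to balance.",
          class = "careseq_balance_error")
  }
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(names(counts), minority)
  min_idx <- which(df$outcome == minority)
  maj_idx <- which(df$outcome %in% majority)
  keep_maj <- withr::with_seed(seed, sample(maj_idx, length(min_idx)))
  df[sort(c(min_idx, keep_maj)), , drop = FALSE]
}

#' Assemble a model matrix from a similarity feature table
#'
#' Builds predictors from sex, age class and the similarity columns.
#' Covariates constant within the context (e.g. sex inside a single-sex
#' context) are dropped. Under the discretized encoding each similarity
#' column becomes a three-level factor (low/medium/strong).
#'
#' @param features Output of [similarity_features()].
#' @param encoding `"continuous"` or `"discretized"`.
#' @return A list: `x` (a tibble of predictors: factors for sex/age class and
#'   discretized similarities, numerics otherwise) and `y` (outcome factor
#'   with levels `alive`, `dead`).
#' @export
assemble_features <- function(features, encoding = c("continuous", "discretized")) {
  encoding <- match.arg(encoding)
  y <- factor(features$outcome, levels = c("alive", "dead"))
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("Outcome is constant; cannot model this context.",
          class = "careseq_model_error")
  }
  sim_cols <- grep("^sim_", names(features), value = TRUE)
  x <- features[sim_cols]
  if (encoding == "discretized") {
    x <- as_tibble(lapply(x, discretize_similarity))
  }
  for (cov in c("sex", "age_class")) {
    if (cov %in% names(features) && length(unique(features[[cov]])) > 1) {
      x[[cov]] <- factor(features[[cov]])
    }
  }
  # drop zero-variance columns (constant similarity or single-level factor)
  keep <- vapply(x, function(col) length(unique(col)) > 1, TRUE)
  list(x = as_tibble(x[keep]), y = y)
}

#' Model configuration for one classifier family
#'
#' @param family One of `"NB"` (naive Bayes), `"KNN"` (k-nearest neighbours),
#'   `"Tree"` (classification tree), `"LR"` (logistic regression), `"SVM"`
#'   (support vector machine) or `"ANN"` (single-hidden-layer neural net).
#' @param ... Family-specific hyperparameters overriding the defaults:
#'   `k` (KNN, default 5); `cost` and `gamma` (SVM, radial kernel, default
#'   cost 1); `size`, `decay`, `maxit` (ANN, defaults max(3, p) units, 0.01,
#'   200); `cp` (Tree, default 0.01). Logistic regression is unpenalized and
#'   naive Bayes is Gaussian on numeric and categorical on factor predictors.
#' @return A list of class `careseq_model_config`.
#' @export
model_config <- function(family = c("NB", "KNN", "Tree", "LR", "SVM", "ANN"),
                         ...) {
  family <- match.arg(family)
  structure(list(family = family, params = list(...)),
            class = "careseq_model_config")
}

#' The six classifier families
#'
#' @return A named list of default [model_config()] objects.
#' @export
all_model_families <- function() {
  fams <- c("NB", "KNN", "Tree", "LR", "SVM", "ANN")
  setNames(lapply(fams, model_config), fams)
}

# numeric design matrix (dummy-coded factors) for families that need one.
design_matrix <- function(x) {
  mm <- stats::model.matrix(~ ., data = x)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

#' Train one classifier configuration
#'
#' Fits the requested family on assembled features and returns a scorer whose
#' [predict()] method maps new feature rows to death probabilities. All
#' stochastic fits (neural net initialisation, k-nearest-neighbour tie
#' breaking, the SVM's internal probability calibration) run under the given
#' seed, so refitting on the same data reproduces the same scorer. SVM
#' decision values are converted to probabilities by the fit's built-in
#' Platt-style sigmoid calibration.
#'
#' @param x Predictor tibble from [assemble_features()].
#' @param y Outcome factor (`alive`/`dead`).
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `careseq_scorer`.
#' @export
train_classifier <- function(x, y, config = model_config("LR"), seed = 1L) {
  stopifnot(inherits(config, "careseq_model_config"))
  if (any(is.na(y)) || anyNA(x)) {
    abort("Missing values are not allowed in features or labels.",
          class = "careseq_model_error")
  }
  p <- config$params
  fit <- withr::with_seed(seed, switch(config$family,
    NB = e1071::naiveBayes(x = as.data.frame(x), y = y),
    KNN = list(train = design_matrix(x), labels = y,
               k = p$k %||% 5L),
    Tree = rpart::rpart(y ~ ., data = cbind(as.data.frame(x), y = y),
                        method = "class",
                        control = rpart::rpart.control(cp = p$cp %||% 0.01)),
    LR = suppressWarnings(
      glm(y ~ ., data = cbind(as.data.frame(x), y = y), family = binomial())),
    SVM = {
      args <- list(x = design_matrix(x), y = y, kernel = "radial",
                   cost = p$cost %||% 1, probability = TRUE, scale = FALSE)
      if (!is.null(p$gamma)) args$gamma <- p$gamma
      do.call(e1071::svm, args)
    },
    ANN = nnet::nnet(x = design_matrix(x), y = as.numeric(y == "dead"),
                     size = p$size %||% max(3L, ncol(design_matrix(x))),
                     decay = p$decay %||% 0.01, maxit = p$maxit %||% 200L,
                     entropy = TRUE, trace = FALSE)
  ))
  structure(list(family = config$family, fit = fit, seed = seed,
                 feature_names = names(x),
                 factor_levels = lapply(keep(x, is.factor), levels)),
            class = "careseq_scorer")
}

#' Predict death probabilities from a trained scorer
#'
#' @param object A `careseq_scorer`.
#' @param newdata A predictor tibble with the training columns.
#' @param ... Unused.
#' @return A numeric vector of probabilities of the `dead` class.
#' @export
predict.careseq_scorer <- function(object, newdata, ...) {
  x <- as_tibble(newdata)[object$feature_names]
  for (nm in names(object$factor_levels)) {
    x[[nm]] <- factor(x[[nm]], levels = object$factor_levels[[nm]])
  }
  pr <- switch(object$family,
    NB = predict(object$fit, as.data.frame(x), type = "raw")[, "dead"],
    KNN = {
      pred <- withr::with_seed(object$seed,
        class::knn(object$fit$train, design_matrix(x), object$fit$labels,
                   k = object$fit$k, prob = TRUE))
      votes <- attr(pred, "prob")
      ifelse(pred == "dead", votes, 1 - votes)
    },
    Tree = predict(object$fit, as.data.frame(x), type = "prob")[, "dead"],
    LR = unname(predict(object$fit, as.data.frame(x), type = "response")),
    SVM = {
      pr <- predict(object$fit, design_matrix(x), probability = TRUE)
      attr(pr, "probabilities")[, "dead"]
    },
    ANN = as.numeric(predict(object$fit, design_matrix(x)))
  )
  pr <- pmin(pmax(as.numeric(pr), 0), 1)
  unname(pr)
}

#' @export
print.careseq_scorer <- function(x, ...) {
  cat(sprintf("careseq scorer: %s on %d feature(s)\n",
              x$family, length(x$feature_names)))
  invisible(x)
}

#' Enumerate (model, similarity, encoding) configurations
#'
#' The full cross-product of classifier families, similarity measures and
#' encodings, optionally repeated per context. Six families, nine measures
#' and two encodings give the canonical 108 configurations.
#'
#' @param families Character vector of family names (default all six).
#' @param measures Character vector of measure names (default all nine).
#' @param encodings Character vector among `"continuous"`, `"discretized"`.
#' @param contexts Optional character vector of context labels; when given,
#'   the cross-product is replicated per context.
#' @return A tibble with one row per configuration.
#' @examples
#' nrow(enumerate_configurations())  # 108
#' @export
enumerate_configurations <- function(families = names(all_model_families()),
                                     measures = names(measure_families),
                                     encodings = c("continuous", "discretized"),
                                     contexts = NULL) {
  if (length(families) == 0 || length(measures) == 0 || length(encodings) == 0) {
    abort("families, measures and encodings must be non-empty.",
          class = "careseq_config_error")
  }
  grid <- tidyr::expand_grid(family = families, measure = measures,
                             encoding = encodings)
  if (!is.null(contexts)) {
    grid <- tidyr::expand_grid(context_label = contexts, grid)
  }
  grid
}
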