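# Contextual frequent sequential pattern mining (PrefixSpan-style prefix
# projection) and maximal-pattern filtering.

#' Mining configuration
#'
#' @param min_support Minimum support as a proportion of a context's patients,
#'   in (0, 1]. Default 0.01: supports are explored down to 1% so that long,
#'   informative patterns survive in short, variable trajectories.
#' @param max_pattern_length Maximum total item count per pattern
#'   (`Inf` = unbounded).
#' @param allow_multi_item Allow itemsets with more than one code in mined
#'   patterns. Off by default: discharge trajectories are effectively one
#'   code per stay position, and single-item growth keeps the search small.
#'   The engine handles multi-item growth when enabled.
#' @param max_patterns Resource cap on the number of frequent patterns a
#'   single mining call may produce before failing with guidance.
#' @return A list of class `careseq_mining_config`.
#' @export
mining_config <- function(min_support = 0.01, max_pattern_length = Inf,
                          allow_multi_item = FALSE, max_patterns = 100000L) {
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    abort("min_support must lie in (0, 1].", class = "careseq_config_error")
  }
  if (max_pattern_length < 1) {
    abort("max_pattern_length must be at least 1.", class = "careseq_config_error")
  }
  structure(list(min_support = min_support,
                 max_pattern_length = max_pattern_length,
                 allow_multi_item = isTRUE(allow_multi_item),
                 max_patterns = max_patterns),
            class = "careseq_mining_config")
}

# Patient count needed for support >= min_support, guarding the comparison at
# rational boundaries such as 2/3 against floating-point error.
support_count_needed <- function(min_support, n) {
  x <- min_support * n
  r <- round(x)
  if (abs(x - r) < 1e-9) as.integer(r) else as.integer(ceiling(x))
}

#' Support of a pattern in a context
#'
#' The fraction of the context's patients whose trajectory embeds the pattern
#' (document frequency: each patient counts once however often the pattern
#' occurs).
#'
#' @param pattern A pattern (list of itemsets); the empty pattern has support 1.
#' @param db A sequential database.
#' @param context Optional context row or patient-id vector; default is the
#'   whole database (the general context).
#' @return A proportion in \[0, 1\].
#' @export
pattern_support <- function(pattern, db, context = NULL) {
  if (!is.null(context)) db <- context_members(db, context)
  if (nrow(db) == 0) {
    abort("Support is undefined in an empty context.",
          class = "careseq_domain_error")
  }
  mean(map_lgl(db$sequence, ~ is_subsequence(pattern, .x)))
}

#' Mine frequent sequential patterns in one context
#'
#' Recursive prefix-projection search: each frequent prefix projects the
#' database onto its suffixes, and the prefix is grown by appending a new
#' single-item itemset (sequence extension) or, when multi-item itemsets are
#' enabled, by adding a code to its last itemset (itemset extension). Exactly
#' the patterns whose support reaches `min_support` among the context's
#' patients are returned.
#'
#' @param db A sequential database.
#' @param context Optional context row or patient-id vector (default: all
#'   patients).
#' @param config A [mining_config()].
#' @return A tibble with columns `pattern` (list column), `pattern_str`,
#'   `support` and `n_items`, ordered by support (descending) then pattern
#'   string.
#' @examples
#' db <- tibble::tibble(
#'   patient_id = c("a", "b"),
#'   sequence = list(new_pattern(c("R07", "I20")), new_pattern(c("R07", "I21")))
#' )
#' mine_frequent(db, config = mining_config(min_support = 1))
#' @export
mine_frequent <- function(db, context = NULL, config = mining_config()) {
  if (!inherits(config, "careseq_mining_config")) {
    abort("config must come from mining_config().", class = "careseq_config_error")
  }
  if (!is.null(context)) db <- context_members(db, context)
  seqs <- db$sequence
  n <- length(seqs)
  if (n == 0) {
    abort("Cannot mine an empty context.", class = "careseq_domain_error")
  }
  min_count <- max(1L, support_count_needed(config$min_support, n))
  state <- new.env(parent = emptyenv())
  state$patterns <- list()
  state$supports <- numeric()
  state$count <- 0L

  # projection: integer matrix-free representation; for each live sequence,
  # the itemset position at which the prefix's last itemset matched.
  grow <- function(prefix, live, match_pos) {
    prefix_len <- pattern_length(prefix)
    if (prefix_len >= config$max_pattern_length) return(invisible())
    # sequence extensions: items occurring strictly after match_pos
    cand <- unique(unlist(lapply(seq_along(live), function(i) {
      s <- seqs[[live[i]]]
      from <- match_pos[i] + 1L
      if (from > length(s)) NULL else unique(unlist(s[from:length(s)]))
    })))
    for (item in sort(cand)) {
      hits <- integer(0); pos <- integer(0)
      for (i in seq_along(live)) {
        s <- seqs[[live[i]]]
        j <- match_pos[i] + 1L
        while (j <= length(s) && !(item %in% s[[j]])) j <- j + 1L
        if (j <= length(s)) { hits <- c(hits, live[i]); pos <- c(pos, j) }
      }
      if (length(hits) >= min_count) {
        child <- c(prefix, list(item))
        record_pattern(state, child, length(hits) / n, config)
        grow(child, hits, pos)
      }
    }
    # itemset extensions: add a code (lexicographically after the current
    # last item) to the prefix's last itemset; support re-checked by full
    # embedding since the enlarged itemset may match later than match_pos.
    if (config$allow_multi_item && length(prefix) > 0) {
      last <- prefix[[length(prefix)]]
      icand <- unique(unlist(lapply(seq_along(live), function(i) {
        s <- seqs[[live[i]]]
        hit <- s[match_pos[i]:length(s)]
        big <- hit[vapply(hit, function(it) all(last %in% it), TRUE)]
        setdiff(unique(unlist(big)), last)
      })))
      icand <- icand[icand > last[length(last)]]
      for (item in sort(icand)) {
        child <- prefix
        child[[length(child)]] <- sort(c(last, item))
        sup <- map_lgl(seqs[live], ~ is_subsequence(child, .x))
        if (sum(sup) >= min_count) {
          hits <- live[sup]
          pos <- map_int(seqs[hits], ~ first_match_pos(child, .x))
          record_pattern(state, child, length(hits) / n, config)
          grow(child, hits, pos)
        }
      }
    }
    invisible()
  }
  grow(list(), seq_len(n), rep(0L, n))
  pattern_tibble(state$patterns, state$supports)
}

record_pattern <- function(state, pattern, support, config) {
  state$count <- state$count + 1L
  if (state$count > config$max_patterns) {
    abort(paste0("More than ", config$max_patterns, " frequent patterns; ",
                 "raise min_support or max_patterns."),
          class = "careseq_resource_error")
  }
  state$patterns[[state$count]] <- pattern
  state$supports[[state$count]] <- support
}

# earliest itemset position at which the pattern's last itemset matches,
# given a full greedy embedding (assumes the pattern embeds).
first_match_pos <- function(pattern, sequence) {
  j <- 1L
  pos <- 0L
  for (its in pattern) {
    while (!all(its %in% sequence[[j]])) j <- j + 1L
    pos <- j
    j <- j + 1L
  }
  pos
}

pattern_tibble <- function(patterns, supports) {
  if (length(patterns) == 0) {
    return(tibble(pattern = list(), pattern_str = character(),
                  support = numeric(), n_items = integer()))
  }
  out <- tibble(
    pattern = lapply(patterns, new_pattern),
    pattern_str = vapply(patterns, pattern_to_string, ""),
    support = supports,
    n_items = vapply(patterns, pattern_length, 0L)
  )
  arrange(out, dplyr::desc(.data$support), .data$pattern_str)
}

#' Keep only maximal patterns
#'
#' A pattern is maximal when it is not embedded (as a subsequence with itemset
#' containment) in any other pattern of the set. Removing non-maximal patterns
#' avoids redundant, collinear similarity features downstream.
#'
#' @param patterns A pattern tibble (from [mine_frequent()]) or a bare list of
#'   patterns.
#' @return The same type with only maximal patterns retained.
#' @examples
#' f <- lapply(list("I20", c("I20", "I21", "I25"), c("I20", "I21"),
#'                  c("I21", "I25"), c("I21", "I20"), c("I20", "I21", "I24")),
#'             new_pattern)
#' vapply(filter_maximal(f), pattern_to_string, "")
#' @export
filter_maximal <- function(patterns) {
  plist <- if (is.data.frame(patterns)) patterns$pattern else patterns
  k <- length(plist)
  if (k <= 1) return(patterns)
  keep <- vapply(seq_len(k), function(i) {
    !any(vapply(seq_len(k), function(j) {
      j != i && is_subsequence(plist[[i]], plist[[j]])
    }, TRUE))
  }, TRUE)
  if (is.data.frame(patterns)) patterns[keep, , drop = FALSE] else plist[keep]
}

#' Mine maximal frequent patterns for every context
#'
#' Runs [mine_frequent()] then [filter_maximal()] per context and stacks the
#' results in a canonical order (support descending, then pattern string) so
#' that downstream similarity feature columns are reproducible.
#'
#' @param db A sequential database.
#' @param contexts The context tibble from [enumerate_contexts()]; excluded
#'   contexts are skipped unless `include_excluded = TRUE`.
#' @param config A [mining_config()].
#' @param include_excluded Mine flagged-excluded contexts too.
#' @return A tibble with columns `context_label`, `pattern`, `pattern_str`,
#'   `support`, `n_items`, classed `careseq_patterns`.
#' @export
mine_contextual_maximal <- function(db, contexts, config = mining_config(),
                                    include_excluded = FALSE) {
  use <- if (include_excluded) contexts else contexts[!contexts$excluded, ]
  out <- map(seq_len(nrow(use)), function(i) {
    ctx <- use[i, ]
    mined <- mine_frequent(db, context = ctx, config = config)
    mined <- filter_maximal(mined)
    mined$context_label <- ctx$label
    relocate(mined, "context_label")
  })
  res <- bind_rows(out)
  class(res) <- unique(c("careseq_patterns", class(res)))
  res
}

#' @export
print.careseq_patterns <- function(x, ...) {
  cat(sprintf("Maximal frequent patterns in %d context(s)\n",
              length(unique(x$context_label))))
  NextMethod()
}

#' Tidy mined patterns
#'
#' @param x A `careseq_patterns` tibble.
#' @param ... Unused.
#' @return A plain tibble with `context_label`, `pattern_str`, `support` and
#'   `n_items`.
#' @method tidy careseq_patterns
#' @export
tidy.careseq_patterns <- function(x, ...) {
  as_tibble(x)[c("context_label", "pattern_str", "support", "n_items")]
}

#' Plot mined pattern supports by context
#'
#' @param object A `careseq_patterns` tibble.
#' @param ... Unused.
#' @return A ggplot: supports per pattern, faceted by context.
#' @method autoplot careseq_patterns
#' @export
autoplot.careseq_patterns <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$support,
    y = stats::reorder(.data$pattern_str, .data$support))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~context_label, scales = "free_y") +
    ggplot2::labs(x = "support (fraction of context patients)", y = NULL)
}
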