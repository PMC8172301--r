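# Sequence and pattern primitives.
#
# An event sequence (a patient trajectory) and a sequential pattern share one
# representation: an ordered list of itemsets, each itemset a sorted character
# vector of event codes. Embedding of a pattern in a sequence means itemset
# containment at strictly increasing positions.

#' Construct a sequential pattern or event sequence
#'
#' Builds the canonical list-of-itemsets representation used throughout the
#' package: each itemset is a deduplicated, lexicographically sorted character
#' vector of event codes, and itemsets are kept in the supplied order. A
#' character vector input is interpreted as a sequence of single-item itemsets.
#'
#' @param x A list of character vectors (one per itemset), or a character
#'   vector of codes (one itemset per code).
#' @return A list of sorted character vectors, classed `careseq_pattern`.
#' @examples
#' new_pattern(c("R07", "I20"))            # <(R07)(I20)>
#' new_pattern(list(c("R07", "I21"), "I20"))
#' @export
new_pattern <- function(x) {
  if (is.character(x)) x <- as.list(x)
  if (!is.list(x) || length(x) == 0) {
    abort("A pattern needs at least one itemset.", class = "careseq_domain_error")
  }
  itemsets <- lapply(x, function(it) {
    it <- unique(as.character(it))
    if (length(it) == 0 || any(!nzchar(it))) {
      abort("Itemsets must be non-empty sets of non-empty codes.",
            class = "careseq_domain_error")
    }
    sort(it)
  })
  structure(itemsets, class = "careseq_pattern")
}

#' Format a pattern in angle-bracket notation
#'
#' Renders a pattern as `<(code ...)(code ...)>`, the notation used in the
#' package's pattern tables.
#'
#' @param pattern A `careseq_pattern` or bare list of itemsets.
#' @return A length-one character string.
#' @examples
#' pattern_to_string(new_pattern(list(c("I21", "R07"), "I20")))
#' @export
pattern_to_string <- function(pattern) {
  paste0("<", paste0("(", vapply(pattern, paste, "", collapse = " "), ")",
                     collapse = " "), ">")
}

#' Parse angle-bracket pattern notation
#'
#' Inverse of [pattern_to_string()].
#'
#' @param x A string such as `"<(R07) (I20)>"`.
#' @return A `careseq_pattern`.
#' @export
parse_pattern <- function(x) {
  body <- gsub("^\\s*<|>\\s*$", "", x)
  sets <- regmatches(body, gregexpr("\\(([^)]*)\\)", body))[[1]]
  if (length(sets) == 0) {
    abort(sprintf("Cannot parse pattern string: %s", x),
          class = "careseq_input_error")
  }
  new_pattern(lapply(sets, function(s) {
    strsplit(trimws(gsub("[()]", "", s)), "\\s+")[[1]]
  }))
}

#' @export
print.careseq_pattern <- function(x, ...) {
  cat(pattern_to_string(x), "\n")
  invisible(x)
}

#' Test whether a pattern is embedded in a sequence
#'
#' A pattern is embedded in a sequence when there are strictly increasing
#' itemset positions in the sequence such that each pattern itemset is a
#' subset of the sequence itemset at the matched position. The empty pattern
#' is vacuously embedded in every sequence. The greedy earliest-match scan
#' used here is exact for this embedding relation.
#'
#' @param pattern A pattern (list of itemsets); may be empty (`list()`).
#' @param sequence An event sequence (list of itemsets).
#' @return `TRUE` or `FALSE`.
#' @examples
#' s <- new_pattern(list(c("R07", "I21"), "I20"))
#' is_subsequence(new_pattern(c("R07", "I20")), s)  # TRUE
#' is_subsequence(new_pattern(c("I20", "R07")), s)  # FALSE: order violated
#' @export
is_subsequence <- function(pattern, sequence) {
  if (length(pattern) == 0) return(TRUE)
  j <- 1L
  n <- length(sequence)
  for (its in pattern) {
    while (j <= n && !all(its %in% sequence[[j]])) j <- j + 1L
    if (j > n) return(FALSE)
    j <- j + 1L
  }
  TRUE
}

# Total number of items across itemsets.
pattern_length <- function(pattern) {
  sum(lengths(pattern))
}
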