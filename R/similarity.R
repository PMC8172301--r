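# Token-level string distances between trajectories and patterns.
#
# Trajectories and patterns are flattened to token texts (one token per event
# code) and compared with nine measures in three families: edit-based
# (longest common substring, Levenshtein, optimal string alignment,
# Damerau-Levenshtein), q-gram-based (q-gram, Jaccard, cosine) and heuristic
# (Jaro, Jaro-Winkler). Distances operate on whole tokens, never on the
# characters inside a code: I21 and I25 are simply different tokens, so code
# spelling does not leak into sequence similarity.

#' Similarity measure descriptor
#'
#' @param name One of `"lcs"`, `"levenshtein"`, `"osa"`,
#'   `"damerau_levenshtein"`, `"qgram"`, `"jaccard"`, `"cosine"`, `"jaro"`,
#'   `"jaro_winkler"`.
#' @param q q-gram length for the q-gram family (default 2; trajectories are
#'   short, so longer grams would empty most profiles).
#' @param p Jaro-Winkler prefix scale (default 0.1).
#' @param max_prefix Jaro-Winkler prefix cap (default 4).
#' @return A list of class `careseq_measure` with the measure's family
#'   (`"edition"`, `"qgram"` or `"heuristic"`) attached.
#' @export
similarity_measure <- function(name, q = 2L, p = 0.1, max_prefix = 4L) {
  name <- match.arg(name, names(measure_families))
  if (q < 1) abort("q must be at least 1.", class = "careseq_config_error")
  structure(list(name = name, family = measure_families[[name]],
                 q = as.integer(q), p = p, max_prefix = as.integer(max_prefix)),
            class = "careseq_measure")
}

measure_families <- c(
  lcs = "edition", levenshtein = "edition", osa = "edition",
  damerau_levenshtein = "edition",
  qgram = "qgram", jaccard = "qgram", cosine = "qgram",
  jaro = "heuristic", jaro_winkler = "heuristic"
)

#' The nine similarity measures
#'
#' @return A named list of [similarity_measure()] objects covering all nine
#'   measures with default parameters.
#' @export
all_measures <- function() {
  setNames(lapply(names(measure_families), similarity_measure),
           names(measure_families))
}

#' Flatten a sequence or pattern to a token text
#'
#' Concatenates itemsets in order; codes within an itemset are taken in
#' lexicographic order (the canonical itemset order), so the encoding is
#' deterministic.
#'
#' @param x An event sequence or sequential pattern (list of itemsets).
#' @return A character vector of tokens.
#' @examples
#' seq_tokens(new_pattern(list(c("R07", "I21"), "I20")))  # I21 R07 I20
#' @export
seq_tokens <- function(x) {
  as.character(unlist(lapply(x, sort), use.names = FALSE))
}

#' Token-level distance between two texts
#'
#' @param a,b Character vectors of tokens.
#' @param measure A [similarity_measure()].
#' @return A non-negative distance. The edit family counts operations; the
#'   q-gram measure is the L1 gap between q-gram count profiles; Jaccard,
#'   cosine, Jaro and Jaro-Winkler return 1 minus the corresponding
#'   similarity.
#' @export
token_distance <- function(a, b, measure) {
  stopifnot(inherits(measure, "careseq_measure"))
  a <- as.character(a); b <- as.character(b)
  switch(measure$name,
    levenshtein = dist_levenshtein(a, b),
    osa = dist_osa(a, b),
    damerau_levenshtein = dist_dl(a, b),
    lcs = length(a) + length(b) - 2L * lcstr_len(a, b),
    qgram = dist_qgram(a, b, measure$q),
    jaccard = 1 - sim_jaccard(a, b, measure$q),
    cosine = 1 - sim_cosine(a, b, measure$q),
    jaro = 1 - sim_jaro(a, b),
    jaro_winkler = 1 - sim_jw(a, b, measure$p, measure$max_prefix)
  )
}

#' Normalized similarity between two token texts
#'
#' Maps every measure to \[0, 1\] with 1 meaning identical texts: the Jaro
#' family and the Jaccard/cosine measures are already normalized (similarity
#' = 1 - distance); Levenshtein, optimal string alignment and
#' Damerau-Levenshtein divide by the longer text length; the longest common
#' substring distance divides by the total length; the q-gram distance
#' divides by the total q-gram profile mass. Two empty texts are maximally
#' similar under every measure.
#'
#' @inheritParams token_distance
#' @return A similarity in \[0, 1\].
#' @export
token_similarity <- function(a, b, measure) {
  a <- as.character(a); b <- as.character(b)
  la <- length(a); lb <- length(b)
  if (la == 0 && lb == 0) return(1)
  d <- token_distance(a, b, measure)
  switch(measure$name,
    levenshtein = ,
    osa = ,
    damerau_levenshtein = 1 - d / max(la, lb),
    lcs = 1 - d / (la + lb),
    qgram = {
      mass <- max(0L, la - measure$q + 1L) + max(0L, lb - measure$q + 1L)
      if (mass == 0) 1 else 1 - d / mass
    },
    1 - d
  )
}

# ---- edit family -----------------------------------------------------------

dist_levenshtein <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0) return(lb)
  if (lb == 0) return(la)
  prev <- 0:lb
  for (i in seq_len(la)) {
    cur <- c(i, integer(lb))
    for (j in seq_len(lb)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[lb + 1L]
}

# optimal string alignment: adjacent transposition allowed, no reuse of
# transposed tokens.
dist_osa <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0) return(lb)
  if (lb == 0) return(la)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0:la
  d[1L, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cost <- as.integer(a[i] != b[j])
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + cost)
      if (i > 1 && j > 1 && a[i] == b[j - 1L] && a[i - 1L] == b[j]) {
        d[i + 1L, j + 1L] <- min(d[i + 1L, j + 1L], d[i - 1L, j - 1L] + 1L)
      }
    }
  }
  d[la + 1L, lb + 1L]
}

# unrestricted Damerau-Levenshtein (transposed tokens may be separated).
dist_dl <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0) return(lb)
  if (lb == 0) return(la)
  alphabet <- unique(c(a, b))
  da <- setNames(rep(0L, length(alphabet)), alphabet)
  maxdist <- la + lb
  d <- matrix(0L, la + 2L, lb + 2L)
  d[1L, ] <- maxdist
  d[, 1L] <- maxdist
  d[2L, 2L:(lb + 2L)] <- 0:lb
  d[2L:(la + 2L), 2L] <- 0:la
  for (i in seq_len(la)) {
    db_col <- 0L
    for (j in seq_len(lb)) {
      k <- da[[b[j]]]
      l <- db_col
      if (a[i] == b[j]) {
        cost <- 0L
        db_col <- j
      } else cost <- 1L
      d[i + 2L, j + 2L] <- min(
        d[i + 1L, j + 1L] + cost,
        d[i + 2L, j + 1L] + 1L,
        d[i + 1L, j + 2L] + 1L,
        d[k + 1L, l + 1L] + (i - k - 1L) + 1L + (j - l - 1L)
      )
    }
    da[[a[i]]] <- i
  }
  d[la + 2L, lb + 2L]
}

# longest common contiguous run of tokens.
lcstr_len <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0 || lb == 0) return(0L)
  best <- 0L
  prev <- integer(lb)
  for (i in seq_len(la)) {
    cur <- integer(lb)
    for (j in seq_len(lb)) {
      if (a[i] == b[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# ---- q-gram family ---------------------------------------------------------

qgram_profile <- function(x, q) {
  n <- length(x)
  if (n < q) return(integer(0))
  grams <- vapply(seq_len(n - q + 1L), function(i) {
    paste(x[i:(i + q - 1L)], collapse = "\x1f")
  }, "")
  tab <- table(grams)
  setNames(as.integer(tab), names(tab))
}

dist_qgram <- function(a, b, q) {
  pa <- qgram_profile(a, q)
  pb <- qgram_profile(b, q)
  keys <- union(names(pa), names(pb))
  if (length(keys) == 0) return(0L)
  ca <- setNames(rep(0L, length(keys)), keys); ca[names(pa)] <- pa
  cb <- setNames(rep(0L, length(keys)), keys); cb[names(pb)] <- pb
  sum(abs(ca - cb))
}

sim_jaccard <- function(a, b, q) {
  sa <- names(qgram_profile(a, q))
  sb <- names(qgram_profile(b, q))
  if (length(sa) == 0 && length(sb) == 0) return(1)
  if (length(sa) == 0 || length(sb) == 0) return(0)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

sim_cosine <- function(a, b, q) {
  pa <- qgram_profile(a, q)
  pb <- qgram_profile(b, q)
  if (length(pa) == 0 && length(pb) == 0) return(1)
  if (length(pa) == 0 || length(pb) == 0) return(0)
  keys <- union(names(pa), names(pb))
  ca <- setNames(rep(0, length(keys)), keys); ca[names(pa)] <- pa
  cb <- setNames(rep(0, length(keys)), keys); cb[names(pb)] <- pb
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

# ---- heuristic family ------------------------------------------------------

sim_jaro <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  window <- max(floor(max(la, lb) / 2) - 1L, 0L)
  a_match <- logical(la); b_match <- logical(lb)
  m <- 0L
  for (i in seq_len(la)) {
    lo <- max(1L, i - window)
    hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!b_match[j] && a[i] == b[j]) {
        a_match[i] <- TRUE; b_match[j] <- TRUE; m <- m + 1L
        break
      }
    }
  }
  if (m == 0L) return(0)
  t <- sum(a[a_match] != b[b_match]) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

sim_jw <- function(a, b, p, max_prefix) {
  j <- sim_jaro(a, b)
  l <- 0L
  for (i in seq_len(min(length(a), length(b), max_prefix))) {
    if (a[i] == b[i]) l <- l + 1L else break
  }
  j + l * p * (1 - j)
}

# ---- vectors and features --------------------------------------------------

#' Similarity vector between a trajectory and a context's patterns
#'
#' @param traj An event sequence.
#' @param patterns A pattern tibble for one context ([mine_contextual_maximal()]
#'   output restricted to the context) or a list of patterns.
#' @param measure A [similarity_measure()].
#' @return A numeric vector of length k (the number of patterns), each entry
#'   the similarity between the trajectory and one pattern. A zero-length
#'   vector (with a warning) when the context has no patterns.
#' @export
similarity_vector <- function(traj, patterns, measure) {
  plist <- if (is.data.frame(patterns)) patterns$pattern else patterns
  if (length(plist) == 0) {
    warn("Context has no patterns; similarity vector is empty and the context is unusable for modeling.")
    return(numeric(0))
  }
  ta <- seq_tokens(traj)
  vapply(plist, function(p) token_similarity(ta, seq_tokens(p), measure), 0)
}

#' Similarity feature table for a set of patients
#'
#' Computes the per-patient similarity vector against a context's patterns and
#' returns it in wide form, one `sim_*` column per pattern (in the pattern
#' table's canonical order).
#'
#' @param db A sequential database (typically already restricted to a
#'   context's members).
#' @param patterns The context's pattern tibble.
#' @param measure A [similarity_measure()].
#' @return A tibble: `patient_id`, covariate columns present in `db` (`sex`,
#'   `age_class`), `outcome`, then `sim_1 ... sim_k`.
#' @export
similarity_features <- function(db, patterns, measure) {
  plist <- if (is.data.frame(patterns)) patterns$pattern else patterns
  k <- length(plist)
  ptoks <- lapply(plist, seq_tokens)
  sims <- matrix(0, nrow(db), k)
  for (i in seq_len(nrow(db))) {
    ta <- seq_tokens(db$sequence[[i]])
    sims[i, ] <- vapply(ptoks, function(tb) token_similarity(ta, tb, measure), 0)
  }
  colnames(sims) <- paste0("sim_", seq_len(k))
  keep <- intersect(c("patient_id", "sex", "age_class", "outcome"), names(db))
  dplyr::bind_cols(as_tibble(db)[keep], as_tibble(sims))
}

#' Discretize a similarity value into low / medium / strong
#'
#' Low below 0.4, medium in \[0.4, 0.6), strong at or above 0.6.
#'
#' @param v Numeric similarities in \[0, 1\].
#' @param low_cut,strong_cut Class boundaries (defaults 0.4 and 0.6).
#' @return A factor with levels `low`, `medium`, `strong`.
#' @examples
#' discretize_similarity(c(0.39, 0.4, 0.6))
#' @export
discretize_similarity <- function(v, low_cut = 0.4, strong_cut = 0.6) {
  if (!(low_cut > 0 && low_cut < strong_cut && strong_cut < 1)) {
    abort("Require 0 < low_cut < strong_cut < 1.", class = "careseq_config_error")
  }
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    abort("Similarities must lie in [0, 1].", class = "careseq_domain_error")
  }
  cut(v, breaks = c(-Inf, low_cut, strong_cut, Inf),
      labels = c("low", "medium", "strong"), right = FALSE)
}
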