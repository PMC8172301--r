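# Independent reference implementations, deliberately written with different
# algorithms than the package (recursion and exhaustive search instead of
# projection and dynamic-programming tricks). Expected values in the tests
# are computed by these.

# recursive embedding check (contrast: the package scans greedily)
ref_embed <- function(pattern, sequence) {
  if (length(pattern) == 0) return(TRUE)
  if (length(sequence) == 0) return(FALSE)
  here <- all(pattern[[1]] %in% sequence[[1]]) &&
    ref_embed(pattern[-1], sequence[-1])
  here || ref_embed(pattern, sequence[-1])
}

# exhaustive miner: every single-item pattern up to max_len over the
# vocabulary, scored by counting embeddings
brute_mine <- function(sequences, vocab, min_support, max_len = 4) {
  n <- length(sequences)
  out_pat <- character(0)
  out_sup <- numeric(0)
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(vocab), len),
                      list(stringsAsFactors = FALSE)))
    for (r in seq_len(nrow(grid))) {
      pat <- lapply(unname(unlist(grid[r, ])), identity)
      sup <- sum(vapply(sequences, function(s) ref_embed(pat, s), TRUE)) / n
      if (sup >= min_support - 1e-12) {
        out_pat <- c(out_pat, pattern_to_string(pat))
        out_sup <- c(out_sup, sup)
      }
    }
  }
  data.frame(pattern_str = out_pat, support = out_sup,
             stringsAsFactors = FALSE)
}

# Levenshtein over tokens via adist on a token -> single character recoding
ref_levenshtein <- function(a, b) {
  alphabet <- unique(c(a, b))
  chars <- vapply(seq_along(alphabet), function(i) rawToChar(as.raw(64 + i)), "")
  enc <- function(x) paste(chars[match(x, alphabet)], collapse = "")
  as.integer(utils::adist(enc(a), enc(b)))
}

# memoised recursive optimal string alignment
ref_osa <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  go <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0) j else if (j == 0) i else {
      v <- min(go(i - 1, j) + 1, go(i, j - 1) + 1,
               go(i - 1, j - 1) + (a[i] != b[j]))
      if (i > 1 && j > 1 && a[i] == b[j - 1] && a[i - 1] == b[j]) {
        v <- min(v, go(i - 2, j - 2) + 1)
      }
      v
    }
    memo[[key]] <- res
    res
  }
  go(length(a), length(b))
}

# Lowrance-Wagner unrestricted transposition distance, direct recursion
ref_dl <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  go <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0) j else if (j == 0) i else {
      v <- min(go(i - 1, j) + 1, go(i, j - 1) + 1,
               go(i - 1, j - 1) + (a[i] != b[j]))
      ks <- which(a[seq_len(i - 1)] == b[j])
      ls <- which(b[seq_len(j - 1)] == a[i])
      for (k in ks) for (l in ls) {
        v <- min(v, go(k - 1, l - 1) + (i - k - 1) + (j - l - 1) + 1)
      }
      v
    }
    memo[[key]] <- res
    res
  }
  go(length(a), length(b))
}

# longest common contiguous substring by enumerating substrings of a
ref_lcstr <- function(a, b) {
  best <- 0
  la <- length(a); lb <- length(b)
  for (i in seq_len(la)) for (j in i:la) {
    len <- j - i + 1
    if (len <= best || len > lb) next
    sub <- a[i:j]
    for (s in seq_len(lb - len + 1)) {
      if (all(sub == b[s:(s + len - 1)])) {
        best <- len
        break
      }
    }
  }
  best
}

ref_qgrams <- function(x, q) {
  if (length(x) < q) return(character(0))
  sapply(seq_len(length(x) - q + 1),
         function(i) paste(x[i + 0:(q - 1)], collapse = "\x1f"))
}

ref_qgram_dist <- function(a, b, q = 2) {
  ga <- ref_qgrams(a, q); gb <- ref_qgrams(b, q)
  keys <- unique(c(ga, gb))
  sum(abs(tabulate(match(ga, keys), length(keys)) -
            tabulate(match(gb, keys), length(keys))))
}

ref_jaccard_sim <- function(a, b, q = 2) {
  sa <- unique(ref_qgrams(a, q)); sb <- unique(ref_qgrams(b, q))
  if (length(sa) == 0 && length(sb) == 0) return(1)
  if (length(sa) == 0 || length(sb) == 0) return(0)
  length(intersect(sa, sb)) / length(unique(c(sa, sb)))
}

ref_cosine_sim <- function(a, b, q = 2) {
  ga <- ref_qgrams(a, q); gb <- ref_qgrams(b, q)
  if (length(ga) == 0 && length(gb) == 0) return(1)
  if (length(ga) == 0 || length(gb) == 0) return(0)
  keys <- unique(c(ga, gb))
  va <- tabulate(match(ga, keys), length(keys))
  vb <- tabulate(match(gb, keys), length(keys))
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

# Jaro from the definition: match flags computed over the full window table
ref_jaro_sim <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  w <- max(floor(max(la, lb) / 2) - 1, 0)
  bm <- rep(FALSE, lb)
  ma <- integer(0)
  mb_pos <- integer(0)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      if (!bm[j] && abs(i - j) <= w && a[i] == b[j]) {
        bm[j] <- TRUE
        ma <- c(ma, i)
        mb_pos <- c(mb_pos, j)
        break
      }
    }
  }
  m <- length(ma)
  if (m == 0) return(0)
  t <- sum(a[ma] != b[sort(mb_pos)]) / 2
  mean(c(m / la, m / lb, (m - t) / m))
}

ref_jw_sim <- function(a, b, p = 0.1, maxl = 4) {
  j <- ref_jaro_sim(a, b)
  l <- 0
  for (i in seq_len(min(length(a), length(b), maxl))) {
    if (a[i] == b[i]) l <- l + 1 else break
  }
  j + l * p * (1 - j)
}

# O(n^2) dominance scan for Pareto selection (orientation: larger-is-better
# matrix already applied by the caller)
brute_pareto_keep <- function(m) {
  n <- nrow(m)
  vapply(seq_len(n), function(i) {
    for (j in seq_len(n)) {
      if (j != i && all(m[j, ] >= m[i, ]) && any(m[j, ] > m[i, ])) return(FALSE)
    }
    TRUE
  }, TRUE)
}

# AUC by exhaustive positive-negative pair counting
ref_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
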