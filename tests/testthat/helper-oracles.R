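# Independent brute-force oracles used to pin the dynamic-programming
# implementations.  All are deliberately exponential enumerations written
# without reference to the package's DP code paths.

# Optimal global affine-gap alignment score by exhaustive recursion over all
# alignment paths.  `a`, `b` are integer codes into `mat`; a gap of length L
# costs go + L * ge.
bf_align_score <- function(a, b, mat, go, ge) {
  la <- length(a); lb <- length(b)
  rec <- function(i, j, prev) {
    if (i > la && j > lb) return(0)
    best <- -Inf
    if (i <= la && j <= lb) {
      best <- max(best, mat[a[i], b[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= la) {
      cost <- ge + if (prev != "X") go else 0
      best <- max(best, cost + rec(i + 1L, j, "X"))
    }
    if (j <= lb) {
      cost <- ge + if (prev != "Y") go else 0
      best <- max(best, cost + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# Unit-cost edit distance by exhaustive recursion.
bf_edit_distance <- function(a, b) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j) {
    if (i > length(a)) return(length(b) - j + 1L)
    if (j > length(b)) return(length(a) - i + 1L)
    min(rec(i + 1L, j + 1L) + (a[i] != b[j]),
        rec(i + 1L, j) + 1L,
        rec(i, j + 1L) + 1L)
  }
  rec(1L, 1L)
}

# Minimum number of mutually non-crossing pages needed for a pair set, by
# enumerating every assignment of pairs to pages.
bf_min_pages <- function(pairs) {
  k <- nrow(pairs)
  if (k == 0L) return(0L)
  crossing <- function(p, q) {
    (pairs[p, 1] < pairs[q, 1] & pairs[q, 1] < pairs[p, 2] &
       pairs[p, 2] < pairs[q, 2]) ||
      (pairs[q, 1] < pairs[p, 1] & pairs[p, 1] < pairs[q, 2] &
         pairs[q, 2] < pairs[p, 2])
  }
  grid <- expand.grid(rep(list(seq_len(k)), k))
  best <- k
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    ok <- TRUE
    for (p in seq_len(k - 1L)) {
      for (q in seq(p + 1L, k)) {
        if (asg[p] == asg[q] && crossing(p, q)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) best <- min(best, length(unique(asg)))
  }
  best
}

# Residue-residue aligned pairs of rows p and q as explicit "rp:rq" strings,
# by direct column scanning (reference computation for SPS / PPV).
bf_residue_pairs <- function(alignment, p, q) {
  cp <- strsplit(alignment$structure[p], "")[[1]]
  cq <- strsplit(alignment$structure[q], "")[[1]]
  rp <- 0L; rq <- 0L
  out <- character(0)
  for (col in seq_along(cp)) {
    gp <- cp[col] == "-"; gq <- cq[col] == "-"
    if (!gp) rp <- rp + 1L
    if (!gq) rq <- rq + 1L
    if (!gp && !gq) out <- c(out, paste0(rp, ":", rq))
  }
  out
}

bf_sps <- function(test, reference) {
  n <- nrow(reference)
  vals <- numeric(0)
  for (p in seq_len(n - 1L)) {
    for (q in seq(p + 1L, n)) {
      rk <- bf_residue_pairs(reference, p, q)
      tk <- bf_residue_pairs(test, p, q)
      vals <- c(vals, if (length(rk) == 0L) 1 else mean(rk %in% tk))
    }
  }
  mean(vals)
}

bf_ppv <- function(test, reference) {
  n <- nrow(reference)
  tp <- 0L; fp <- 0L
  for (p in seq_len(n - 1L)) {
    for (q in seq(p + 1L, n)) {
      rk <- bf_residue_pairs(reference, p, q)
      tk <- bf_residue_pairs(test, p, q)
      tp <- tp + sum(tk %in% rk)
      fp <- fp + sum(!tk %in% rk)
    }
  }
  if (tp + fp == 0L) 1 else tp / (tp + fp)
}

# small helpers ---------------------------------------------------------

random_string <- function(len, alphabet) {
  if (len == 0L) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# all strings over `alphabet` of length 0..maxlen
all_strings <- function(alphabet, maxlen) {
  out <- ""
  level <- ""
  for (l in seq_len(maxlen)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}

# a quick aligned toy set used by several metric tests
toy_alignment <- function(ids, seqs, structs) {
  df <- data.frame(id = ids, sequence = seqs, structure = structs,
                   stringsAsFactors = FALSE)
  class(df) <- c("rna_alignment", "rna_set", "data.frame")
  df
}
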