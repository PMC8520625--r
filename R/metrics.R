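alignment_char_matrix <- function(alignment, what = "structure") {
  rows <- strsplit(alignment[[what]], "", fixed = TRUE)
  do.call(rbind, rows)
}

#' Majority-rule consensus structure of an alignment
#'
#' Per column, the most frequent non-gap structure symbol wins; ties and
#' majority-gap columns give `.`.  A repair pass then demotes any unmatched
#' bracket to `.` so the result always parses.
#'
#' @param alignment An `rna_alignment` with structure rows.
#' @return A dot-bracket string of alignment length.
#' @export
consensus_structure <- function(alignment) {
  validate_alignment(alignment)
  m <- alignment_char_matrix(alignment)
  n <- nrow(m)
  cons <- apply(m, 2L, function(col) {
    gaps <- sum(col == "-")
    if (gaps * 2L > n) return(".")
    col <- col[col != "-"]
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    if (length(top) != 1L) "." else top
  })
  # repair: per family, demote unmatched brackets
  for (f in 1:4) {
    op <- OPEN_BRACKETS[f]; cl <- CLOSE_BRACKETS[f]
    stack <- integer(0)
    for (pos in seq_along(cons)) {
      if (cons[pos] == op) {
        stack <- c(stack, pos)
      } else if (cons[pos] == cl) {
        if (length(stack) == 0L) cons[pos] <- "."
        else stack <- stack[-length(stack)]
      }
    }
    cons[stack] <- "."
  }
  paste(cons, collapse = "")
}

#' Edit distance between two dot-bracket strings
#'
#' Minimal-cost global string alignment with unit costs (substitution of
#' different symbols 1, indel 1, match 0); gap characters are removed first.
#' This is a documented approximation of the reference string-alignment
#' distance between secondary structures.
#'
#' @param s1,s2 Dot-bracket strings (may contain `-`, which is stripped).
#' @return Non-negative integer distance.
#' @examples
#' structural_distance("(.)", "()")  # 1
#' @export
structural_distance <- function(s1, s2) {
  s1 <- gsub("-", "", s1, fixed = TRUE)
  s2 <- gsub("-", "", s2, fixed = TRUE)
  a <- match(strsplit(s1, "", fixed = TRUE)[[1]], STRUCTURE_CHARS)
  b <- match(strsplit(s2, "", fixed = TRUE)[[1]], STRUCTURE_CHARS)
  if (anyNA(a) || anyNA(b)) stop("invalid structure character",
                                 call. = FALSE)
  edit_distance_cpp(a, b)
}

#' Mean structural distance of an alignment to its consensus
#'
#' The mean over rows of the edit distance between the consensus structure
#' and each ungapped input structure, and the derived score
#' `1 - mean_distance / consensus length`.
#'
#' @param alignment An `rna_alignment`.
#' @return `mean_structural_distance()`: a non-negative real;
#'   `structural_distance_score()`: a real at most 1.
#' @export
mean_structural_distance <- function(alignment) {
  stopifnot(nrow(alignment) >= 1L)
  cons <- consensus_structure(alignment)
  mean(vapply(alignment$structure,
              function(s) structural_distance(cons, s), 0))
}

#' @rdname mean_structural_distance
#' @export
structural_distance_score <- function(alignment) {
  cons <- consensus_structure(alignment)
  if (nchar(cons) == 0L) stop("zero-length consensus structure",
                              call. = FALSE)
  1 - mean_structural_distance(alignment) / nchar(cons)
}

# Match test rows to reference rows by id and verify the ungapped content is
# identical; returns the test alignment re-ordered like the reference.
match_alignments <- function(test, reference) {
  validate_alignment(test)
  validate_alignment(reference)
  idx <- match(reference$id, test$id)
  if (anyNA(idx) || nrow(test) != nrow(reference)) {
    stop("test and reference alignments contain different ids",
         call. = FALSE)
  }
  test <- test[idx, , drop = FALSE]
  degap <- function(x) gsub("-", "", x, fixed = TRUE)
  if (!identical(degap(test$sequence), degap(reference$sequence)) ||
      !identical(degap(test$structure), degap(reference$structure))) {
    stop("test and reference alignments contain different ungapped content",
         call. = FALSE)
  }
  test
}

# residue-rank pairs induced by rows p and q of an alignment, encoded as
# rank_p * (L+1) + rank_q
aligned_pair_keys <- function(chars_p, chars_q) {
  nong_p <- chars_p != "-"
  nong_q <- chars_q != "-"
  rank_p <- cumsum(nong_p)
  rank_q <- cumsum(nong_q)
  both <- nong_p & nong_q
  rank_p[both] * (sum(nong_q) + 1) + rank_q[both]
}

#' Sum-of-pairs score of a test alignment against a reference
#'
#' For each of the N(N-1)/2 sequence pairs, the fraction of residue-residue
#' aligned pairs in the reference that are reproduced by the test alignment,
#' averaged over sequence pairs.  A pair with no reference residue pairs
#' contributes 1 by convention.
#'
#' @param test,reference `rna_alignment`s over the same records (matched by
#'   id and ungapped content).
#' @return A fraction in `[0, 1]`.
#' @export
sps <- function(test, reference) {
  test <- match_alignments(test, reference)
  mt <- alignment_char_matrix(test)
  mr <- alignment_char_matrix(reference)
  n <- nrow(mt)
  if (n < 2L) return(1)
  vals <- numeric(0)
  for (p in seq_len(n - 1L)) {
    for (q in seq(p + 1L, n)) {
      ref_keys <- aligned_pair_keys(mr[p, ], mr[q, ])
      if (length(ref_keys) == 0L) {
        vals <- c(vals, 1)
      } else {
        test_keys <- aligned_pair_keys(mt[p, ], mt[q, ])
        vals <- c(vals, mean(ref_keys %in% test_keys))
      }
    }
  }
  mean(vals)
}

#' Positive predictive value of a test alignment against a reference
#'
#' Residue column co-memberships (which residues of other sequences share a
#' residue's column) are computed in the test and reference alignments;
#' true positives are co-memberships present in both, false positives those
#' present only in the test.  `PPV = TP / (TP + FP)`; an empty test
#' co-membership set gives 1 by convention.
#'
#' @inheritParams sps
#' @return A fraction in `[0, 1]`.
#' @export
ppv <- function(test, reference) {
  test <- match_alignments(test, reference)
  mt <- alignment_char_matrix(test)
  mr <- alignment_char_matrix(reference)
  n <- nrow(mt)
  if (n < 2L) return(1)
  tp <- 0; fp <- 0
  for (p in seq_len(n - 1L)) {
    for (q in seq(p + 1L, n)) {
      ref_keys <- aligned_pair_keys(mr[p, ], mr[q, ])
      test_keys <- aligned_pair_keys(mt[p, ], mt[q, ])
      hits <- sum(test_keys %in% ref_keys)
      tp <- tp + hits
      fp <- fp + length(test_keys) - hits
    }
  }
  if (tp + fp == 0) 1 else tp / (tp + fp)
}

#' Full metric report for a test alignment
#'
#' @inheritParams sps
#' @return A one-row data frame with columns `sps`, `ppv`,
#'   `mean_structural_distance`, `structural_distance_score`.
#' @export
metric_report <- function(test, reference) {
  data.frame(sps = sps(test, reference),
             ppv = ppv(test, reference),
             mean_structural_distance = mean_structural_distance(test),
             structural_distance_score = structural_distance_score(test))
}
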