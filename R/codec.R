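#' Codec letter for a (nucleotide, structure symbol) pair
#'
#' The simple-mode codec maps the 20 combinations of nucleotide (A, C, G, U)
#' and structure symbol (`.`, `(`, `)`, `[`, `]`) bijectively onto the 20
#' canonical amino-acid letters `ACDEFGHIKLMNPQRSTVWY`:
#' `letter = CANON[4 * s + n]` with `s` the 0-based symbol index and `n` the
#' 0-based nucleotide index.  Scoring is defined on the (nucleotide, symbol)
#' semantics, so the particular bijection only affects interchange files.
#'
#' @param nt Nucleotide character(s), one of A, C, G, U.
#' @param sym Structure symbol(s), one of `. ( ) [ ]`.
#' @return Amino-acid letter(s).
#' @examples
#' codec_letter("A", ".")  # "A"
#' codec_letter("U", ".")  # "E"
#' @export
codec_letter <- function(nt, sym) {
  s <- match(sym, SIMPLE_SYMBOLS)
  n <- match(nt, NUCLEOTIDES)
  if (anyNA(s)) stop("invalid structure symbol for the simple codec",
                     call. = FALSE)
  if (anyNA(n)) stop("invalid nucleotide (expected A/C/G/U)", call. = FALSE)
  CANON20[4L * (s - 1L) + n]
}

#' Codec letter for a structure symbol (structure-only mode)
#'
#' The pseudo-mode codec maps the 9 structure symbols (dot plus 4 bracket
#' families) onto the first 9 canonical letters in symbol order.
#'
#' @param sym Structure symbol(s), one of `. ( ) [ ] { } < >`.
#' @return Amino-acid letter(s).
#' @export
pseudo_letter <- function(sym) {
  s <- match(sym, PSEUDO_SYMBOLS)
  if (anyNA(s)) stop("invalid structure symbol", call. = FALSE)
  CANON20[s]
}

new_pseudo_seq <- function(letters, mode, demoted = integer(0)) {
  structure(list(letters = letters, mode = mode, demoted = demoted),
            class = "pseudo_seq")
}

#' Encode sequence plus structure as a pseudo-amino-acid string (simple mode)
#'
#' @param sequence RNA sequence over A/C/G/U (modified nucleotides must be
#'   stripped first; see [strip_modifications()]).
#' @param structure Dot-bracket structure of the same length, at most two
#'   bracket pages (see [demote_higher_order()]).
#' @return A `pseudo_seq` object with fields `letters`, `mode`, `demoted`.
#' @examples
#' encode_simple("ACGU", "(())")$letters  # "FGLN"
#' @export
encode_simple <- function(sequence, structure) {
  stopifnot(is.character(sequence), is.character(structure))
  nts <- strsplit(sequence, "", fixed = TRUE)[[1]]
  syms <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (length(nts) != length(syms)) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  if (!all(nts %in% NUCLEOTIDES)) {
    bad <- which(!nts %in% NUCLEOTIDES)[1]
    stop(sprintf(paste0("non-ACGU character '%s' at position %d; run ",
                        "strip_modifications() before encoding"),
                 nts[bad], bad), call. = FALSE)
  }
  if (!all(syms %in% SIMPLE_SYMBOLS)) {
    bad <- which(!syms %in% SIMPLE_SYMBOLS)[1]
    stop(sprintf(paste0("structure symbol '%s' at position %d is not ",
                        "representable in simple mode; normalize and demote ",
                        "to at most 2 pages first"),
                 syms[bad], bad), call. = FALSE)
  }
  letters <- if (length(nts) == 0L) "" else
    paste(codec_letter(nts, syms), collapse = "")
  new_pseudo_seq(letters, "simple")
}

#' Encode a structure alone as a pseudo-amino-acid string (pseudo mode)
#'
#' @param structure Dot-bracket structure with at most four bracket pages.
#' @return A `pseudo_seq` object.
#' @examples
#' encode_pseudo("((..))")$letters  # "CCAADD"
#' @export
encode_pseudo <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  syms <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (!all(syms %in% PSEUDO_SYMBOLS)) {
    bad <- which(!syms %in% PSEUDO_SYMBOLS)[1]
    stop(sprintf("invalid structure character '%s' at position %d",
                 syms[bad], bad), call. = FALSE)
  }
  letters <- if (length(syms) == 0L) "" else
    paste(pseudo_letter(syms), collapse = "")
  new_pseudo_seq(letters, "pseudo")
}

#' Decode a (possibly gapped) pseudo-amino-acid string
#'
#' Inverse of the encoders.  The gap character `-` passes through to both the
#' sequence and the structure.  When a demotion record is supplied, the
#' demoted positions (given as ranks in the ungapped string) are restored to
#' their original bracket symbols.
#'
#' @param letters Pseudo-amino-acid string, possibly containing `-`.
#' @param mode `"simple"` or `"pseudo"`.
#' @param demoted Optional demotion record: a data frame with columns `pos`
#'   (1-based rank in the ungapped string) and `char` (original bracket
#'   symbol).
#' @return A list with `sequence` (empty string in pseudo mode) and
#'   `structure`, both gapped like `letters`.
#' @examples
#' pseudo_decode("A-E", "simple")  # sequence "A-U", structure ".-."
#' @export
pseudo_decode <- function(letters, mode = c("simple", "pseudo"),
                          demoted = NULL) {
  mode <- match.arg(mode)
  chars <- strsplit(letters, "", fixed = TRUE)[[1]]
  is_gap <- chars == "-"
  idx <- match(chars[!is_gap], CANON20)
  limit <- if (mode == "simple") 20L else 9L
  if (anyNA(idx) || any(idx > limit)) {
    bad <- chars[!is_gap][which(is.na(idx) | idx > limit)[1]]
    stop(sprintf("letter '%s' is outside the %s-mode codec table", bad, mode),
         call. = FALSE)
  }
  n <- length(chars)
  seq_chars <- rep("-", n)
  struct_chars <- rep("-", n)
  if (mode == "simple") {
    seq_chars[!is_gap] <- NUCLEOTIDES[(idx - 1L) %% 4L + 1L]
    struct_chars[!is_gap] <- SIMPLE_SYMBOLS[(idx - 1L) %/% 4L + 1L]
  } else {
    struct_chars[!is_gap] <- PSEUDO_SYMBOLS[idx]
  }
  if (!is.null(demoted) && nrow(demoted) > 0L) {
    nongap <- which(!is_gap)
    if (max(demoted$pos) > length(nongap)) {
      stop("demotion record position exceeds ungapped length", call. = FALSE)
    }
    struct_chars[nongap[demoted$pos]] <- demoted$char
  }
  list(sequence = if (mode == "pseudo") "" else
         paste(seq_chars, collapse = ""),
       structure = paste(struct_chars, collapse = ""))
}
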