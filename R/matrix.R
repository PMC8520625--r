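PARAM_NAMES <- c("same_bracket", "two_dots", "diff_bracket_same_orientation",
                 "opposite_orientation", "bracket_dot", "same_sequence_bonus",
                 "gap_open", "gap_extend")

#' Scoring-matrix parameters
#'
#' The eight integer parameters from which the whole substitution matrix is
#' generated.  The defaults are the optimized values: same bracket +5, two
#' dots +6, different bracket families with the same orientation +2,
#' brackets with opposite orientation -10, bracket against dot -8, bonus for
#' identical nucleotides +5, gap opening -12, gap extension -1.
#'
#' @param same_bracket Score for two identical bracket symbols.
#' @param two_dots Score for two unpaired positions.
#' @param diff_bracket_same_orientation Score for brackets of different
#'   families that are both opening or both closing.
#' @param opposite_orientation Score for one opening against one closing
#'   bracket (any families, including the same family).
#' @param bracket_dot Score for a bracket against a dot.
#' @param same_sequence_bonus Added when the two encoded nucleotides are
#'   identical (simple mode only).
#' @param gap_open,gap_extend Affine gap penalties (negative).
#' @return A `matrix_params` object (named integer list).
#' @export
matrix_params <- function(same_bracket = 5L, two_dots = 6L,
                          diff_bracket_same_orientation = 2L,
                          opposite_orientation = -10L, bracket_dot = -8L,
                          same_sequence_bonus = 5L,
                          gap_open = -12L, gap_extend = -1L) {
  vals <- list(same_bracket, two_dots, diff_bracket_same_orientation,
               opposite_orientation, bracket_dot, same_sequence_bonus,
               gap_open, gap_extend)
  ok <- vapply(vals, function(v) {
    is.numeric(v) && length(v) == 1L && !is.na(v) && v == round(v)
  }, TRUE)
  if (!all(ok)) {
    stop(sprintf("parameter '%s' must be a single integer",
                 PARAM_NAMES[!ok][1]), call. = FALSE)
  }
  structure(stats::setNames(lapply(vals, as.integer), PARAM_NAMES),
            class = "matrix_params")
}

#' @export
print.matrix_params <- function(x, ...) {
  cat("matrix_params:",
      paste(PARAM_NAMES, unlist(x), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Score a pair of structure symbols
#'
#' Applies the five-way category logic: identical brackets; two dots;
#' different families with the same orientation; opposite orientation (one
#' opening, one closing, regardless of family); bracket against dot.
#'
#' @param sym1,sym2 Structure symbols (vectors recycle).
#' @param params A `matrix_params` object.
#' @return Integer score(s).
#' @examples
#' structure_pair_score(".", ".")  # 6
#' structure_pair_score("(", ")")  # -10
#' structure_pair_score("(", "[")  # 2
#' @export
structure_pair_score <- function(sym1, sym2, params = matrix_params()) {
  if (!all(sym1 %in% STRUCTURE_CHARS) || !all(sym2 %in% STRUCTURE_CHARS)) {
    stop("invalid structure symbol", call. = FALSE)
  }
  n <- max(length(sym1), length(sym2))
  sym1 <- rep_len(sym1, n)
  sym2 <- rep_len(sym2, n)
  dot1 <- sym1 == "."
  dot2 <- sym2 == "."
  open1 <- sym1 %in% OPEN_BRACKETS
  open2 <- sym2 %in% OPEN_BRACKETS
  out <- integer(n)
  out[dot1 & dot2] <- params$two_dots
  out[xor(dot1, dot2)] <- params$bracket_dot
  both <- !dot1 & !dot2
  out[both & sym1 == sym2] <- params$same_bracket
  out[both & sym1 != sym2 & open1 == open2] <-
    params$diff_bracket_same_orientation
  out[both & open1 != open2] <- params$opposite_orientation
  out
}

new_scoring_matrix <- function(alphabet, scores, gap_open, gap_extend,
                               mode = NA, params = NULL) {
  structure(list(alphabet = alphabet, scores = scores,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 mode = mode, params = params),
            class = "scoring_matrix")
}

#' Generate the pseudo-amino-acid substitution matrix
#'
#' In simple mode the entry for letters encoding (n1, s1) and (n2, s2) is
#' `structure_pair_score(s1, s2) + same_sequence_bonus * (n1 == n2)` over the
#' 20-letter codec; in pseudo mode it is the structure score alone over the
#' 9-letter codec.  The matrix is symmetric and carries the gap penalties.
#'
#' @param params A `matrix_params` object.
#' @param mode `"simple"` or `"pseudo"`.
#' @return A `scoring_matrix`: list with `alphabet`, `scores` (square
#'   integer matrix with letter dimnames), `gap_open`, `gap_extend`, `mode`,
#'   `params`.
#' @examples
#' m <- build_matrix()
#' m$scores[codec_letter("A", "."), codec_letter("A", ".")]  # 6 + 5
#' @export
build_matrix <- function(params = matrix_params(),
                         mode = c("simple", "pseudo")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "matrix_params"))
  if (mode == "simple") {
    grid <- expand.grid(n = NUCLEOTIDES, s = SIMPLE_SYMBOLS,
                        stringsAsFactors = FALSE)
    # expand.grid varies n fastest, matching letter = CANON[4*s + n]
    alphabet <- CANON20
    nts <- grid$n
    syms <- grid$s
  } else {
    alphabet <- CANON20[seq_along(PSEUDO_SYMBOLS)]
    nts <- NULL
    syms <- PSEUDO_SYMBOLS
  }
  k <- length(alphabet)
  scores <- matrix(0L, k, k, dimnames = list(alphabet, alphabet))
  for (i in seq_len(k)) {
    scores[i, ] <- structure_pair_score(syms[i], syms, params)
    if (mode == "simple") {
      scores[i, ] <- scores[i, ] +
        ifelse(nts == nts[i], params$same_sequence_bonus, 0L)
    }
  }
  new_scoring_matrix(alphabet, scores, params$gap_open, params$gap_extend,
                     mode = mode, params = params)
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat(sprintf("scoring_matrix: %d letters (%s mode), gap_open=%d, gap_extend=%d\n",
              length(x$alphabet),
              ifelse(is.na(x$mode), "unknown", x$mode),
              x$gap_open, x$gap_extend))
  invisible(x)
}

#' Build and write a substitution matrix file
#'
#' Convenience wrapper around [build_matrix()] and [write_matrix_file()],
#' mirroring the matrix-creation command of the CLI.
#'
#' @param file Output path.
#' @param params A `matrix_params` object.
#' @param mode `"simple"` or `"pseudo"`.
#' @param ... Passed to [write_matrix_file()].
#' @return The `scoring_matrix`, invisibly.
#' @export
create_matrix <- function(file, params = matrix_params(),
                          mode = c("simple", "pseudo"), ...) {
  mode <- match.arg(mode)
  m <- build_matrix(params, mode)
  write_matrix_file(m, file, ...)
  invisible(m)
}
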