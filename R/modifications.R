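#' Default modified-nucleotide code table
#'
#' Reads the packaged two-column table mapping one-letter modification codes
#' to their parent base (e.g. pseudouridine to U, inosine to A).  The
#' ambiguity code `N` is included with parent `A` and, like all codes, is
#' restored verbatim on output.
#'
#' @param file Optional path to a user table (two whitespace-separated
#'   columns: code, parent; `#` comments allowed).
#' @return A named character vector mapping code to parent base.
#' @export
default_modification_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "modification_codes.txt",
                        package = "rna2dalign", mustWork = TRUE)
  }
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\\s+")
  codes <- vapply(fields, `[`, "", 1L)
  parents <- toupper(vapply(fields, `[`, "", 2L))
  if (any(!parents %in% NUCLEOTIDES)) {
    stop("modification table parents must be A/C/G/U", call. = FALSE)
  }
  if (any(codes %in% c(NUCLEOTIDES, "-"))) {
    stop("modification codes must not collide with A/C/G/U/-", call. = FALSE)
  }
  stats::setNames(parents, codes)
}

#' Strip modified-nucleotide codes to their parent bases
#'
#' Replaces every non-ACGU character by its parent base and records the
#' position and original code so that [restore_modifications()] can undo the
#' replacement after alignment.
#'
#' @param sequence RNA sequence possibly containing modification codes.
#' @param table Named character vector code -> parent base.
#' @param on_missing What to do with a character absent from the table:
#'   `"error"` (default) or `"as_n"` (treat it like the ambiguity code `N`,
#'   i.e. substitute the parent of `N` and restore the original character on
#'   output).
#' @return A list with `sequence` (clean, same length, over ACGU) and `map`
#'   (data frame with columns `pos`, `code`).
#' @examples
#' strip_modifications("APGU")  # "AUGU", map records (2, "P")
#' @export
strip_modifications <- function(sequence,
                                table = default_modification_table(),
                                on_missing = c("error", "as_n")) {
  on_missing <- match.arg(on_missing)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  modified <- which(!chars %in% NUCLEOTIDES)
  if (length(modified) == 0L) {
    return(list(sequence = sequence,
                map = data.frame(pos = integer(0), code = character(0),
                                 stringsAsFactors = FALSE)))
  }
  codes <- chars[modified]
  parents <- unname(table[codes])
  if (anyNA(parents)) {
    bad <- which(is.na(parents))[1]
    if (on_missing == "error") {
      stop(sprintf("unknown sequence character '%s' at position %d (not in the modification table)",
                   codes[bad], modified[bad]), call. = FALSE)
    }
    fallback <- unname(table["N"])
    if (is.na(fallback)) fallback <- "A"
    parents[is.na(parents)] <- fallback
  }
  chars[modified] <- parents
  list(sequence = paste(chars, collapse = ""),
       map = data.frame(pos = modified, code = codes,
                        stringsAsFactors = FALSE))
}

#' Restore modification codes into a gapped sequence
#'
#' Walks the non-gap characters of `gapped_sequence` left to right; the k-th
#' non-gap position receives the original code when k appears in the map.
#'
#' @param gapped_sequence Clean sequence, possibly containing `-` gaps.
#' @param map Data frame with columns `pos` (1-based rank among non-gap
#'   characters) and `code`.
#' @return The gapped sequence with the original characters restored.
#' @examples
#' restore_modifications("AU-GU", data.frame(pos = 2, code = "P"))  # "AP-GU"
#' @export
restore_modifications <- function(gapped_sequence, map) {
  if (is.null(map) || nrow(map) == 0L) return(gapped_sequence)
  chars <- strsplit(gapped_sequence, "", fixed = TRUE)[[1]]
  nongap <- which(chars != "-")
  if (max(map$pos) > length(nongap)) {
    stop("modification position exceeds ungapped sequence length",
         call. = FALSE)
  }
  chars[nongap[map$pos]] <- map$code
  paste(chars, collapse = "")
}
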