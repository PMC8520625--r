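new_rna_set <- function(id, sequence, structure, aligned = FALSE) {
  df <- data.frame(id = as.character(id),
                   sequence = as.character(sequence),
                   structure = as.character(structure),
                   stringsAsFactors = FALSE)
  class(df) <- c(if (aligned) "rna_alignment", "rna_set", "data.frame")
  df
}

#' Validate an alignment object
#'
#' Checks that all gapped structure rows share one length and that gapped
#' sequence rows either match that length or are empty (structure-only
#' inputs).
#'
#' @param alignment An `rna_alignment` data frame.
#' @return The alignment, invisibly; errors on violation.
#' @export
validate_alignment <- function(alignment) {
  stopifnot(is.data.frame(alignment))
  ls <- nchar(alignment$structure)
  if (length(unique(ls)) > 1L) {
    stop("alignment rows have unequal structure lengths", call. = FALSE)
  }
  lq <- nchar(alignment$sequence)
  if (!all(lq == ls | lq == 0L)) {
    stop("alignment rows have unequal sequence lengths", call. = FALSE)
  }
  invisible(alignment)
}

normalize_input_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  gsub("T", "U", sequence, fixed = TRUE)
}

#' Read a Vienna-style sequence + structure file
#'
#' Parses the 3-line dialect: a `>` header, the RNA sequence (which may
#' contain one-letter modified-nucleotide codes) and a dot-bracket structure
#' of equal length.  In pseudo mode records have 2 lines (header and
#' structure; the sequence is stored empty).  Blank lines and Windows line
#' endings are tolerated; sequences are upper-cased and `T` is converted to
#' `U`.
#'
#' @param file Path to the input file (ignored when `text` is given).
#' @param text Optional character scalar holding the file content.
#' @param mode `"simple"` (3-line records) or `"pseudo"` (2-line records).
#' @param gapped Accept `-` gap characters (for reading aligned files);
#'   rows must then share one length and the result is an `rna_alignment`.
#' @return An `rna_set` data frame with columns `id`, `sequence`,
#'   `structure` (an `rna_alignment` when `gapped = TRUE`).
#' @export
read_vienna <- function(file = NULL, text = NULL,
                        mode = c("simple", "pseudo"), gapped = FALSE) {
  mode <- match.arg(mode)
  lines <- if (!is.null(text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(file, warn = FALSE)
  }
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input", call. = FALSE)
  per <- if (mode == "simple") 3L else 2L
  if (length(lines) %% per != 0L) {
    stop(sprintf("expected records of %d lines each, got %d lines",
                 per, length(lines)), call. = FALSE)
  }
  nrec <- length(lines) %/% per
  ids <- seqs <- structs <- character(nrec)
  for (k in seq_len(nrec)) {
    block <- lines[(k - 1L) * per + seq_len(per)]
    if (!startsWith(block[1], ">")) {
      stop(sprintf("record %d does not start with a '>' header", k),
           call. = FALSE)
    }
    id <- trimws(sub("^>", "", block[1]))
    if (mode == "simple") {
      sq <- normalize_input_sequence(trimws(block[2]))
      st <- trimws(block[3])
      if (nchar(sq) != nchar(st)) {
        stop(sprintf("length mismatch between sequence and structure in record '%s'",
                     id), call. = FALSE)
      }
    } else {
      sq <- ""
      st <- trimws(block[2])
    }
    tryCatch(
      parse_dotbracket(if (gapped) gsub("-", "", st, fixed = TRUE) else st),
      error = function(e) {
        stop(sprintf("record '%s': %s", id, conditionMessage(e)),
             call. = FALSE)
      })
    ids[k] <- id; seqs[k] <- sq; structs[k] <- st
  }
  out <- new_rna_set(ids, seqs, structs, aligned = gapped)
  if (gapped) validate_alignment(out)
  out
}

#' Write records or an alignment in the Vienna-style dialect
#'
#' Emits 3-line records (header, sequence, structure), or 2-line records when
#' every sequence is empty (structure-only sets).  Output uses `\n` line
#' endings; `read_vienna(write_vienna(x))` round-trips.
#'
#' @param x An `rna_set` or `rna_alignment` data frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_vienna <- function(x, file) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  two_line <- all(nchar(x$sequence) == 0L)
  lines <- unlist(lapply(seq_len(nrow(x)), function(k) {
    if (two_line) c(paste0(">", x$id[k]), x$structure[k])
    else c(paste0(">", x$id[k]), x$sequence[k], x$structure[k])
  }))
  writeLines(lines, file)
  invisible(file)
}

#' Read a plain FASTA file
#'
#' @param file Path to a FASTA file (sequences may be gapped).
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(file) {
  set <- Biostrings::readBStringSet(file)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to a plain FASTA file
#'
#' @param sequences Named character vector.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(sequences, file) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}

#' Read a connectivity (.ct) file
#'
#' Parses the standard 6-column connectivity format.  Any line whose first
#' whitespace-separated field is not a positive integer is treated as a
#' comment and skipped; the first line is taken as the header (residue count
#' and title).  The pairing column is converted to dot-bracket with canonical
#' greedy page assignment, so crossing pair sets come out in the same
#' notation as [normalize_pseudoknots()].
#'
#' @param file Path to the .ct file.
#' @return A one-row `rna_set` data frame.
#' @export
read_ct <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty .ct file", call. = FALSE)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_declared <- suppressWarnings(as.integer(header[1]))
  id <- if (length(header) > 1L) paste(header[-1], collapse = " ")
        else basename(file)
  body <- lines[-1]
  rows <- list()
  for (ln in body) {
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(fields) < 6L) next
    pos <- suppressWarnings(as.integer(fields[1]))
    if (is.na(pos) || pos <= 0L) next  # comment line
    pair <- suppressWarnings(as.integer(fields[5]))
    if (is.na(pair)) next
    if (!is.na(n_declared) && length(rows) >= n_declared) break
    rows[[length(rows) + 1L]] <- list(pos = pos, base = fields[2],
                                      pair = pair)
  }
  if (length(rows) == 0L) stop("no residue lines found in .ct file",
                               call. = FALSE)
  pos <- vapply(rows, `[[`, 0L, "pos")
  base <- vapply(rows, `[[`, "", "base")
  pair <- vapply(rows, `[[`, 0L, "pair")
  n <- max(pos)
  seq_chars <- rep("N", n)
  seq_chars[pos] <- base
  pairing <- integer(n)
  pairing[pos] <- pair
  # consistency: i pairs j => j pairs i
  for (i in seq_len(n)) {
    j <- pairing[i]
    if (j > 0L) {
      if (j > n || pairing[j] != i) {
        stop(sprintf("inconsistent pairing: position %d pairs %d but %d pairs %d",
                     i, j, j, if (j <= n) pairing[j] else NA_integer_),
             call. = FALSE)
      }
    }
  }
  idx <- which(pairing > seq_len(n))
  pairs <- cbind(idx, pairing[idx])
  ps <- pairset_from_pairs(pairs, n)
  sequence <- normalize_input_sequence(paste(seq_chars, collapse = ""))
  new_rna_set(id, sequence, render_dotbracket(ps))
}

#' Read a substitution-matrix file
#'
#' Reads the whitespace-delimited NCBI-style layout used by standard protein
#' matrices: an optional block of `#` comment lines, a header row of residue
#' letters, and one labelled row per residue.
#'
#' @param file Path to the matrix file.
#' @param gap_open,gap_extend Gap penalties to attach (the file format does
#'   not carry them).
#' @return A `scoring_matrix` object (see [build_matrix()]).
#' @export
read_matrix_file <- function(file, gap_open = -12L, gap_extend = -1L) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) < 2L) stop("matrix file too short", call. = FALSE)
  alphabet <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- length(alphabet)
  body <- lines[-1]
  if (length(body) != n) {
    stop(sprintf("matrix file has %d data rows for a %d-letter header",
                 length(body), n), call. = FALSE)
  }
  scores <- matrix(0L, n, n, dimnames = list(alphabet, alphabet))
  for (k in seq_len(n)) {
    fields <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (length(fields) != n + 1L) {
      stop(sprintf("matrix row %d has %d fields, expected %d",
                   k, length(fields), n + 1L), call. = FALSE)
    }
    if (fields[1] != alphabet[k]) {
      stop(sprintf("matrix row label '%s' does not match header letter '%s'",
                   fields[1], alphabet[k]), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals) || any(vals != round(vals))) {
      stop(sprintf("non-integer entry in matrix row %d", k), call. = FALSE)
    }
    scores[k, ] <- as.integer(vals)
  }
  new_scoring_matrix(alphabet, scores, gap_open, gap_extend, mode = NA)
}

#' Write a substitution matrix in the NCBI-style layout
#'
#' By default the four letters `B`, `Z`, `X`, `*` (absent from the codec) are
#' appended with a large negative sentinel (-100) so the file is accepted by
#' standard protein aligners; pass `passthrough = character(0)` to write the
#' codec alphabet only.
#'
#' @param matrix A `scoring_matrix`.
#' @param file Output path.
#' @param passthrough Extra letters to append with sentinel scores.
#' @param sentinel Score used for the pass-through letters.
#' @return `file`, invisibly.
#' @export
write_matrix_file <- function(matrix, file,
                              passthrough = c("B", "Z", "X", "*"),
                              sentinel = -100L) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  alphabet <- matrix$alphabet
  extra <- setdiff(passthrough, alphabet)
  full <- c(alphabet, extra)
  n <- length(full)
  scores <- base::matrix(sentinel, n, n, dimnames = list(full, full))
  scores[alphabet, alphabet] <- matrix$scores
  width <- max(nchar(as.character(scores)), nchar(full)) + 1L
  fmt <- function(x) formatC(x, width = width)
  lines <- c(paste0(" ", paste(fmt(full), collapse = "")),
             vapply(seq_len(n), function(k) {
               paste0(full[k], paste(fmt(scores[k, ]), collapse = ""))
             }, ""))
  writeLines(lines, file)
  invisible(file)
}
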