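letters_to_codes <- function(letters, alphabet) {
  chars <- strsplit(letters, "", fixed = TRUE)[[1]]
  codes <- match(chars, alphabet)
  if (anyNA(codes)) {
    stop(sprintf("letter '%s' is not in the matrix alphabet",
                 chars[which(is.na(codes))[1]]), call. = FALSE)
  }
  codes
}

codes_to_letters <- function(codes, alphabet) {
  out <- rep("-", length(codes))
  out[codes > 0L] <- alphabet[codes[codes > 0L]]
  paste(out, collapse = "")
}

#' Align a single pair of pseudo-amino-acid strings
#'
#' Global affine-gap alignment (a gap of length L costs
#' `gap_open + L * gap_extend`).  Mostly useful for inspection and testing;
#' [align_builtin()] runs the full progressive alignment.
#'
#' @param s1,s2 Ungapped pseudo-amino-acid strings.
#' @param matrix A `scoring_matrix`.
#' @param gap_open,gap_extend Override the matrix's gap penalties.
#' @return List with `score` and the two gapped strings `s1`, `s2`.
#' @export
pairwise_align <- function(s1, s2, matrix,
                           gap_open = matrix$gap_open,
                           gap_extend = matrix$gap_extend) {
  a <- letters_to_codes(s1, matrix$alphabet)
  b <- letters_to_codes(s2, matrix$alphabet)
  res <- pairwise_align_cpp(a, b, matrix$scores + 0.0, gap_open, gap_extend)
  ga <- ifelse(res$a > 0L, a[pmax(res$a, 1L)], 0L)
  gb <- ifelse(res$b > 0L, b[pmax(res$b, 1L)], 0L)
  list(score = res$score,
       s1 = codes_to_letters(ga, matrix$alphabet),
       s2 = codes_to_letters(gb, matrix$alphabet))
}

#' Progressive multiple alignment of pseudo-amino-acid strings
#'
#' The offline backend: (a) pairwise distances as 1 minus the fractional
#' identity of pairwise affine-gap alignments; (b) a UPGMA guide tree
#' (average linkage; ties resolved deterministically by lexicographic
#' sequence id); (c) profile-profile alignment with sum-of-pairs column
#' scoring, gap penalties scaled by column gap content, and
#' once-a-gap-always-a-gap column handling.  Fully deterministic.
#'
#' @param pseudo Named character vector of ungapped pseudo-amino-acid
#'   strings (names are ids; made unique internally if needed).
#' @param matrix A `scoring_matrix` whose alphabet covers the letters.
#' @param gap_open,gap_extend Override the matrix's gap penalties.
#' @return Named character vector of gapped strings, input order.
#' @export
align_builtin <- function(pseudo, matrix,
                          gap_open = matrix$gap_open,
                          gap_extend = matrix$gap_extend) {
  n <- length(pseudo)
  if (n == 0L) stop("no sequences to align", call. = FALSE)
  if (n == 1L) return(pseudo)
  ids <- names(pseudo)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  scores <- matrix$scores + 0.0
  codes <- lapply(pseudo, letters_to_codes, alphabet = matrix$alphabet)

  # lexicographic-id processing order makes guide-tree tie-breaks
  # independent of input order
  ord <- order(ids, seq_len(n))
  codes <- codes[ord]

  if (n == 2L) {
    res <- pairwise_align_cpp(codes[[1]], codes[[2]], scores,
                              gap_open, gap_extend)
    paths <- list(res$a, res$b)
    gapped <- vapply(1:2, function(k) {
      cc <- ifelse(paths[[k]] > 0L, codes[[k]][pmax(paths[[k]], 1L)], 0L)
      codes_to_letters(cc, matrix$alphabet)
    }, "")
    out <- character(n)
    out[ord] <- gapped
    names(out) <- names(pseudo)
    return(out)
  }

  D <- base::matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      res <- pairwise_align_cpp(codes[[i]], codes[[j]], scores,
                                gap_open, gap_extend)
      both <- res$a > 0L & res$b > 0L
      ident <- sum(codes[[i]][res$a[both]] == codes[[j]][res$b[both]])
      D[i, j] <- D[j, i] <- 1 - ident / length(res$a)
    }
  }
  tree <- stats::hclust(stats::as.dist(D), method = "average")

  # progressive merge along the UPGMA tree; profiles are integer matrices
  # (rows = member sequences, 0 = gap)
  profiles <- vector("list", nrow(tree$merge))
  members <- vector("list", nrow(tree$merge))
  fetch <- function(k) {
    if (k < 0L) {
      list(profile = base::matrix(codes[[-k]], nrow = 1L), members = -k)
    } else {
      list(profile = profiles[[k]], members = members[[k]])
    }
  }
  for (s in seq_len(nrow(tree$merge))) {
    A <- fetch(tree$merge[s, 1L])
    B <- fetch(tree$merge[s, 2L])
    res <- profile_align_cpp(A$profile, B$profile, scores,
                             gap_open, gap_extend)
    ncolumns <- length(res$a)
    newA <- base::matrix(0L, nrow(A$profile), ncolumns)
    newA[, res$a > 0L] <- A$profile[, res$a[res$a > 0L], drop = FALSE]
    newB <- base::matrix(0L, nrow(B$profile), ncolumns)
    newB[, res$b > 0L] <- B$profile[, res$b[res$b > 0L], drop = FALSE]
    profiles[[s]] <- rbind(newA, newB)
    members[[s]] <- c(A$members, B$members)
  }
  final <- profiles[[nrow(tree$merge)]]
  rows <- members[[nrow(tree$merge)]]
  gapped_sorted <- character(n)
  for (k in seq_len(n)) {
    gapped_sorted[rows[k]] <- codes_to_letters(final[k, ], matrix$alphabet)
  }
  out <- character(n)
  out[ord] <- gapped_sorted
  names(out) <- names(pseudo)
  out
}

#' Align pseudo-amino-acid strings with an external protein aligner
#'
#' Writes the encoded sequences and the substitution matrix to temporary
#' files and invokes an external MUSCLE-compatible binary
#' (`-in`, `-out`, `-matrix`, `-gapopen`, `-gapextend`, `-seqtype protein`).
#' Output rows are re-ordered to the input order.
#'
#' @param pseudo Named character vector of ungapped pseudo-amino-acid
#'   strings.
#' @param matrix A `scoring_matrix`.
#' @param gap_open,gap_extend Override the matrix's gap penalties.
#' @param binary Name or path of the aligner binary.
#' @param keep_temp Keep the temporary files (for debugging).
#' @return Named character vector of gapped strings, input order.
#' @export
align_external <- function(pseudo, matrix,
                           gap_open = matrix$gap_open,
                           gap_extend = matrix$gap_extend,
                           binary = "muscle", keep_temp = FALSE) {
  if (length(pseudo) == 0L) stop("no sequences to align", call. = FALSE)
  path <- Sys.which(binary)
  if (!nzchar(path) && !file.exists(binary)) {
    stop(sprintf(paste0("external aligner '%s' not found on PATH; install ",
                        "it or use backend = \"builtin\""), binary),
         call. = FALSE)
  }
  keys <- sprintf("s%06d", seq_along(pseudo))
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  fmat <- tempfile(fileext = ".mat")
  if (!keep_temp) on.exit(unlink(c(fin, fout, fmat)), add = TRUE)
  write_fasta(stats::setNames(pseudo, keys), fin)
  write_matrix_file(matrix, fmat)
  args <- c("-in", fin, "-out", fout, "-matrix", fmat,
            "-gapopen", gap_open, "-gapextend", gap_extend,
            "-seqtype", "protein")
  err <- tempfile()
  status <- suppressWarnings(
    system2(if (nzchar(path)) path else binary, args,
            stdout = FALSE, stderr = err))
  if (status != 0L) {
    msg <- tryCatch(paste(readLines(err, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop(sprintf("external aligner exited with status %d:\n%s", status, msg),
         call. = FALSE)
  }
  aligned <- read_fasta(fout)
  missing <- setdiff(keys, names(aligned))
  if (length(missing) > 0L) {
    stop("external aligner output is missing sequences", call. = FALSE)
  }
  out <- unname(aligned[keys])
  names(out) <- names(pseudo)
  out
}

#' Run the full encode-align-decode pipeline
#'
#' The five-step workflow: (1) strip modified-nucleotide codes, (2)
#' canonicalize pseudoknot notation (optional) and demote higher-order
#' pseudoknot pages, then encode to pseudo-amino acids, (3) align, (4)
#' decode back to gapped RNA sequence plus structure, (5) restore the
#' original modification codes.  Demoted positions come out as dots in the
#' aligned structures (post-alignment gaps can separate demoted partners);
#' the demotion log is attached as the `"demoted"` attribute and a warning
#' names each affected record.
#'
#' @param records An `rna_set` data frame (see [read_vienna()]).
#' @param mode `"simple"` (sequence + structure) or `"pseudo"`
#'   (structure only).
#' @param matrix A `scoring_matrix`; defaults to `build_matrix(mode = mode)`.
#' @param backend `"builtin"` or `"external"`.
#' @param normalize Canonicalize pseudoknot notation before encoding.
#' @param modification_table Named vector code -> parent base.
#' @param gap_open,gap_extend Override the matrix's gap penalties.
#' @param ... Passed to the backend (e.g. `binary` for
#'   [align_external()]).
#' @return An `rna_alignment` data frame (columns `id`, `sequence`,
#'   `structure`); removing gaps from any row reproduces the corresponding
#'   input record.
#' @export
run_pipeline <- function(records, mode = c("simple", "pseudo"),
                         matrix = NULL,
                         backend = c("builtin", "external"),
                         normalize = TRUE,
                         modification_table = default_modification_table(),
                         gap_open = NULL, gap_extend = NULL, ...) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (is.null(matrix)) matrix <- build_matrix(mode = mode)
  if (is.null(gap_open)) gap_open <- matrix$gap_open
  if (is.null(gap_extend)) gap_extend <- matrix$gap_extend
  max_pages <- if (mode == "simple") 2L else 4L

  n <- nrow(records)
  pseudo <- character(n)
  maps <- vector("list", n)
  demoted_counts <- integer(n)
  for (k in seq_len(n)) {
    id <- records$id[k]
    st <- records$structure[k]
    res <- tryCatch({
      if (normalize) st <- normalize_pseudoknots(st)
      ps <- parse_dotbracket(st)
      dem <- demote_higher_order(ps, max_pages)
      demoted_counts[k] <- length(dem$demoted)
      st_demoted <- render_dotbracket(dem$pair_set)
      if (mode == "simple") {
        stripped <- strip_modifications(records$sequence[k],
                                        modification_table)
        maps[[k]] <- stripped$map
        encode_simple(stripped$sequence, st_demoted)
      } else {
        if (nzchar(records$sequence[k])) {
          stripped <- strip_modifications(records$sequence[k],
                                          modification_table)
          maps[[k]] <- stripped$map
        }
        encode_pseudo(st_demoted)
      }
    }, error = function(e) {
      stop(sprintf("record '%s': %s", id, conditionMessage(e)),
           call. = FALSE)
    })
    pseudo[k] <- res$letters
  }
  if (any(demoted_counts > 0L)) {
    hit <- which(demoted_counts > 0L)
    warning(sprintf("higher-order pseudoknot pairs demoted to unpaired: %s",
                    paste(sprintf("%s (%d positions)", records$id[hit],
                                  demoted_counts[hit]), collapse = ", ")),
            call. = FALSE)
  }

  names(pseudo) <- sprintf("q%06d", seq_len(n))
  aligned <- switch(backend,
    builtin = align_builtin(pseudo, matrix, gap_open, gap_extend),
    external = align_external(pseudo, matrix, gap_open, gap_extend, ...))

  seqs <- structs <- character(n)
  for (k in seq_len(n)) {
    dec <- pseudo_decode(aligned[k], mode)
    if (mode == "simple") {
      seqs[k] <- restore_modifications(dec$sequence, maps[[k]])
    } else if (nzchar(records$sequence[k])) {
      # project the alignment's gap pattern onto the original sequence
      gchars <- strsplit(dec$structure, "", fixed = TRUE)[[1]]
      schars <- strsplit(records$sequence[k], "", fixed = TRUE)[[1]]
      out <- rep("-", length(gchars))
      out[gchars != "-"] <- schars
      seqs[k] <- paste(out, collapse = "")
    } else {
      seqs[k] <- ""
    }
    structs[k] <- dec$structure
  }
  out <- new_rna_set(records$id, seqs, structs, aligned = TRUE)
  attr(out, "mode") <- mode
  attr(out, "demoted") <- data.frame(id = records$id,
                                     n_demoted = demoted_counts,
                                     stringsAsFactors = FALSE)
  validate_alignment(out)
  out
}

#' Remove gaps from alignment rows
#'
#' @param alignment An `rna_alignment`.
#' @return An `rna_set` with gap characters removed from sequences and
#'   structures.
#' @export
ungap_alignment <- function(alignment) {
  new_rna_set(alignment$id,
              gsub("-", "", alignment$sequence, fixed = TRUE),
              gsub("-", "", alignment$structure, fixed = TRUE))
}
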