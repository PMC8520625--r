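#' Parse a dot-bracket string into base-pair pages
#'
#' Matches each bracket family (`()`, `[]`, `{}`, `<>`) independently with a
#' stack.  Page k collects the pairs written with the k-th family.
#'
#' @param structure A dot-bracket string over `. ( ) [ ] { } < >`.
#' @return An object of class `pair_set`: a list with `n` (structure length),
#'   `pages` (list of integer matrices with columns `i`, `j`, 1-based,
#'   `i < j`, sorted by `i`; trailing empty pages dropped) and `unpaired`
#'   (integer vector of unpaired positions).
#' @examples
#' parse_dotbracket("((..))")
#' parse_dotbracket("(([[..))]]")
#' @export
parse_dotbracket <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bad <- which(!chars %in% STRUCTURE_CHARS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown structure character '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  pages <- vector("list", 4L)
  paired <- logical(n)
  for (f in 1:4) {
    stack <- integer(0)
    pairs <- NULL
    op <- OPEN_BRACKETS[f]
    cl <- CLOSE_BRACKETS[f]
    for (pos in seq_len(n)) {
      ch <- chars[pos]
      if (ch == op) {
        stack <- c(stack, pos)
      } else if (ch == cl) {
        if (length(stack) == 0L) {
          stop(sprintf("unbalanced '%s' at position %d", cl, pos),
               call. = FALSE)
        }
        i <- stack[length(stack)]
        stack <- stack[-length(stack)]
        pairs <- rbind(pairs, c(i, pos))
        paired[c(i, pos)] <- TRUE
      }
    }
    if (length(stack) > 0L) {
      stop(sprintf("unbalanced '%s' at position %d", op, stack[1]),
           call. = FALSE)
    }
    if (is.null(pairs)) {
      pairs <- matrix(integer(0), ncol = 2L)
    } else {
      pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    }
    colnames(pairs) <- c("i", "j")
    pages[[f]] <- pairs
  }
  # drop trailing empty pages
  last <- max(c(0L, which(vapply(pages, nrow, 0L) > 0L)))
  pages <- pages[seq_len(last)]
  structure(list(n = n, pages = pages,
                 unpaired = which(!paired)),
            class = "pair_set")
}

#' Render a pair set back to a dot-bracket string
#'
#' @param pairset A `pair_set` (see [parse_dotbracket()]).
#' @return A dot-bracket string; page k is written with the k-th bracket
#'   family.
#' @export
render_dotbracket <- function(pairset) {
  stopifnot(inherits(pairset, "pair_set"))
  if (length(pairset$pages) > 4L) {
    stop("more than 4 bracket pages cannot be rendered", call. = FALSE)
  }
  chars <- rep(".", pairset$n)
  for (p in seq_along(pairset$pages)) {
    pairs <- pairset$pages[[p]]
    if (nrow(pairs) == 0L) next
    chars[pairs[, 1L]] <- OPEN_BRACKETS[p]
    chars[pairs[, 2L]] <- CLOSE_BRACKETS[p]
  }
  paste(chars, collapse = "")
}

# TRUE where pair (i1,j1) crosses (i2,j2); vectorized over the second pair
pairs_cross <- function(i1, j1, i2, j2) {
  (i1 < i2 & i2 < j1 & j1 < j2) | (i2 < i1 & i1 < j2 & j2 < j1)
}

# Canonical page assignment: the minimum number of mutually non-crossing
# pages, and among minimal assignments the lexicographically first one over
# pairs sorted by opening position (found by lowest-page-first backtracking,
# trying page counts 1..max_pages).  Minimality matters: a simple greedy
# sweep can waste a bracket family on crossing patterns that two families
# cover.  `pairs` is an n x 2 matrix; returns an integer page per pair.
assign_pages <- function(pairs, max_pages = 4L) {
  k <- nrow(pairs)
  if (k == 0L) return(integer(0))
  ord <- order(pairs[, 1L])
  p <- pairs[ord, , drop = FALSE]
  cross <- outer(seq_len(k), seq_len(k), function(a, b) {
    pairs_cross(p[a, 1L], p[a, 2L], p[b, 1L], p[b, 2L])
  })
  for (npage in seq_len(max_pages)) {
    asg <- integer(k)
    kk <- 1L
    while (kk >= 1L && kk <= k) {
      pg <- asg[kk] + 1L          # next page to try at this depth
      placed <- FALSE
      while (pg <= npage) {
        before <- seq_len(kk - 1L)
        if (!any(asg[before] == pg & cross[kk, before])) {
          asg[kk] <- pg
          placed <- TRUE
          break
        }
        pg <- pg + 1L
      }
      if (placed) {
        kk <- kk + 1L
      } else {
        asg[kk] <- 0L
        kk <- kk - 1L
      }
    }
    if (kk > k) {
      out <- integer(k)
      out[ord] <- asg
      return(out)
    }
  }
  stop(sprintf("structure requires more than %d bracket families",
               max_pages), call. = FALSE)
}

# Build a pair_set from a bare pair matrix and a length, assigning pages
# canonically (minimal count, lexicographically first).
pairset_from_pairs <- function(pairs, n) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(structure(list(n = n, pages = list(),
                          unpaired = seq_len(n)),
                     class = "pair_set"))
  }
  swap <- pairs[, 1L] > pairs[, 2L]
  pairs[swap, ] <- pairs[swap, c(2L, 1L)]
  page <- assign_pages(pairs)
  npage <- max(page)
  pages <- lapply(seq_len(npage), function(p) {
    m <- pairs[page == p, , drop = FALSE]
    m <- m[order(m[, 1L]), , drop = FALSE]
    colnames(m) <- c("i", "j")
    m
  })
  paired <- sort(c(pairs))
  structure(list(n = n, pages = pages,
                 unpaired = setdiff(seq_len(n), paired)),
            class = "pair_set")
}

#' Canonicalize pseudoknot bracket notation
#'
#' The same pseudoknotted pair set can be written with the bracket families
#' swapped (e.g. the `(((\[\[\[` vs `\[\[\[(((` notations describe one
#' structure).  This function reassigns pairs to pages canonically: the
#' minimum number of mutually non-crossing pages is used, ties between
#' minimal assignments are broken by taking the lexicographically first
#' assignment over pairs sorted by opening position, and page k is rendered
#' with the k-th bracket family.  The pair set is preserved exactly and the
#' operation is idempotent.
#'
#' @param structure A dot-bracket string.
#' @return The canonical dot-bracket string for the same pair set.
#' @examples
#' normalize_pseudoknots("[[[(((...]]])))")  # -> "((([[[...)))]]]"
#' @export
normalize_pseudoknots <- function(structure) {
  ps <- parse_dotbracket(structure)
  pairs <- do.call(rbind, c(list(matrix(integer(0), ncol = 2L)), ps$pages))
  canon <- pairset_from_pairs(pairs, ps$n)
  if (length(canon$pages) > 4L) {
    stop("structure requires more than 4 bracket families", call. = FALSE)
  }
  render_dotbracket(canon)
}

#' Demote higher-order pseudoknot pages to unpaired
#'
#' Pages beyond `max_pages` are removed and their positions reported as
#' demoted (treated as unpaired downstream).  The simple encoding supports 2
#' pages; the structure-only encoding supports 4.
#'
#' @param pairset A `pair_set`.
#' @param max_pages Maximum number of pages to keep.
#' @return A list with `pair_set` (the truncated pair set) and `demoted`
#'   (sorted integer positions whose brackets were removed).
#' @export
demote_higher_order <- function(pairset, max_pages) {
  stopifnot(inherits(pairset, "pair_set"), max_pages >= 1L)
  if (length(pairset$pages) <= max_pages) {
    return(list(pair_set = pairset, demoted = integer(0)))
  }
  dropped <- pairset$pages[-seq_len(max_pages)]
  demoted <- sort(unlist(lapply(dropped, function(m) c(m))))
  pairset$pages <- pairset$pages[seq_len(max_pages)]
  pairset$unpaired <- sort(c(pairset$unpaired, demoted))
  list(pair_set = pairset, demoted = as.integer(demoted))
}
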