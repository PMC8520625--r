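# Run fn() under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# Watson-Crick + GU wobble pair types with usage weights
PAIR_TYPES <- rbind(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"),
                    c("G", "U"), c("U", "G"))
PAIR_WEIGHTS <- c(0.3, 0.3, 0.15, 0.15, 0.05, 0.05)

sample_pair_type <- function(exclude = NULL) {
  w <- PAIR_WEIGHTS
  if (!is.null(exclude)) {
    same <- PAIR_TYPES[, 1L] == exclude[1L] & PAIR_TYPES[, 2L] == exclude[2L]
    w[same] <- 0
  }
  PAIR_TYPES[sample.int(nrow(PAIR_TYPES), 1L, prob = w), ]
}

# Random nested (page-1) helices over positions lo..hi; appends to `acc`
# (an environment holding a pair matrix).
sample_nested_pairs <- function(lo, hi, acc) {
  len <- hi - lo + 1L
  if (len < 7L) return(invisible())
  if (len >= 20L && runif(1) < 0.3) {
    mid <- lo + 6L + sample.int(len - 13L, 1L)
    sample_nested_pairs(lo, mid, acc)
    sample_nested_pairs(mid + 1L, hi, acc)
    return(invisible())
  }
  h <- min(sample(2:4, 1L), (len - 3L) %/% 2L)
  if (h < 1L) return(invisible())
  for (t in 0:(h - 1L)) {
    acc$pairs <- rbind(acc$pairs, c(lo + t, hi - t))
  }
  sample_nested_pairs(lo + h, hi - h, acc)
}

unpaired_runs <- function(unpaired) {
  if (length(unpaired) == 0L) return(list())
  breaks <- c(0L, which(diff(unpaired) > 1L), length(unpaired))
  lapply(seq_len(length(breaks) - 1L), function(k) {
    unpaired[(breaks[k] + 1L):breaks[k + 1L]]
  })
}

# Add one helix on a new page that crosses the existing pair set; NULL if no
# feasible placement exists.
add_crossing_helix <- function(pairs, n) {
  unp <- setdiff(seq_len(n), c(pairs))
  runs <- unpaired_runs(unp)
  if (length(runs) < 2L) return(NULL)
  cands <- list()
  for (a in seq_len(length(runs) - 1L)) {
    for (b in seq(a + 1L, length(runs))) {
      h <- min(3L, length(runs[[a]]), length(runs[[b]]))
      if (h < 2L) next
      ra <- runs[[a]]; rb <- runs[[b]]
      new_pairs <- cbind(ra[seq_len(h)],
                         rb[length(rb) - seq_len(h) + 1L])
      crosses <- any(pairs_cross(new_pairs[1L, 1L], new_pairs[1L, 2L],
                                 pairs[, 1L], pairs[, 2L]))
      if (crosses) cands[[length(cands) + 1L]] <- new_pairs
    }
  }
  if (length(cands) == 0L) return(NULL)
  rbind(pairs, cands[[sample.int(length(cands), 1L)]])
}

#' Specification of a synthetic RNA family
#'
#' @param n_sequences Number of family members.
#' @param length Consensus length (at least 4; pseudoknotted families need
#'   room for two crossing helices, in practice 30+).
#' @param pseudoknot_pages Number of bracket pages in the consensus (1-3).
#' @param mutation_rate Per-position point-mutation probability (paired
#'   positions mutate jointly to a different compatible pair type).
#' @param indel_rate Per-unpaired-position indel probability (split evenly
#'   between deletions and single-base insertions, so loops grow and shrink
#'   but helices are untouched).
#' @param modification_rate Per-residue probability of carrying a
#'   modified-nucleotide code compatible with its parent base.
#' @param seed RNG seed; the same spec always generates the same family.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_sequences = 5L, length = 60L,
                        pseudoknot_pages = 1L, mutation_rate = 0.1,
                        indel_rate = 0.05, modification_rate = 0.1,
                        seed = 1L) {
  stopifnot(n_sequences >= 1L, length >= 4L,
            pseudoknot_pages >= 1L, pseudoknot_pages <= 3L,
            mutation_rate >= 0, mutation_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            modification_rate >= 0, modification_rate <= 1)
  structure(list(n_sequences = as.integer(n_sequences),
                 length = as.integer(length),
                 pseudoknot_pages = as.integer(pseudoknot_pages),
                 mutation_rate = mutation_rate,
                 indel_rate = indel_rate,
                 modification_rate = modification_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate a synthetic RNA family with a known reference alignment
#'
#' Samples a random consensus structure with the requested number of
#' pseudoknot pages (rendered in canonical notation), a structure-compatible
#' consensus sequence, and derives members by jointly-compatible point
#' mutations, loop indels, and sprinkled modification codes.  The generative
#' alignment is returned as the reference.
#'
#' @param spec A [family_spec()].
#' @return A list with `records` (an `rna_set`), `reference` (an
#'   `rna_alignment` whose ungapped rows equal the records) and
#'   `consensus_structure`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, function() {
    L <- spec$length
    canon <- NULL
    for (attempt in 1:60) {
      acc <- new.env()
      acc$pairs <- NULL
      # terminal dangles; at least 2 nt when a crossing helix must anchor
      # into them later
      dangle <- function() {
        if (spec$pseudoknot_pages > 1L) sample(2:4, 1L) else sample(0:2, 1L)
      }
      sample_nested_pairs(1L + dangle(), L - dangle(), acc)
      pairs <- acc$pairs
      if (is.null(pairs)) {
        if (spec$pseudoknot_pages == 1L) {
          pairs <- matrix(integer(0), ncol = 2L)
        } else next
      }
      ok <- TRUE
      if (spec$pseudoknot_pages > 1L) {
        for (p in seq(2L, spec$pseudoknot_pages)) {
          pairs <- add_crossing_helix(pairs, L)
          if (is.null(pairs)) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      cand <- pairset_from_pairs(pairs, L)
      if (length(cand$pages) == spec$pseudoknot_pages ||
          (spec$pseudoknot_pages == 1L && length(cand$pages) <= 1L)) {
        canon <- cand
        break
      }
    }
    if (is.null(canon)) {
      stop("could not generate a structure with the requested page count; increase length",
           call. = FALSE)
    }
    struct_chars <- strsplit(render_dotbracket(canon), "", fixed = TRUE)[[1]]
    all_pairs <- do.call(rbind, c(list(matrix(integer(0), ncol = 2L)),
                                  canon$pages))
    unp <- canon$unpaired

    seq_chars <- character(L)
    for (pos in unp) seq_chars[pos] <- sample(NUCLEOTIDES, 1L)
    if (nrow(all_pairs) > 0L) {
      for (k in seq_len(nrow(all_pairs))) {
        pt <- sample_pair_type()
        seq_chars[all_pairs[k, 1L]] <- pt[1L]
        seq_chars[all_pairs[k, 2L]] <- pt[2L]
      }
    }

    mod_table <- default_modification_table()
    codes_by_parent <- split(names(mod_table), mod_table)

    M <- spec$n_sequences
    member_chars <- vector("list", M)   # length-L vectors, '-' = deleted
    member_ins <- vector("list", M)     # [[pos+1]]: chars inserted after pos
    for (m in seq_len(M)) {
      chars <- seq_chars
      if (nrow(all_pairs) > 0L) {
        for (k in seq_len(nrow(all_pairs))) {
          if (runif(1) < spec$mutation_rate) {
            i <- all_pairs[k, 1L]; j <- all_pairs[k, 2L]
            pt <- sample_pair_type(exclude = c(chars[i], chars[j]))
            chars[i] <- pt[1L]; chars[j] <- pt[2L]
          }
        }
      }
      for (pos in unp) {
        if (runif(1) < spec$mutation_rate) {
          chars[pos] <- sample(setdiff(NUCLEOTIDES, chars[pos]), 1L)
        }
      }
      ins <- rep(list(character(0)), L + 1L)
      for (pos in unp) {
        r <- runif(1)
        if (r < spec$indel_rate / 2) {
          chars[pos] <- "-"
        } else if (r < spec$indel_rate) {
          ins[[pos + 1L]] <- c(ins[[pos + 1L]], sample(NUCLEOTIDES, 1L))
        }
      }
      # modifications on surviving residues and insertions
      for (pos in which(chars != "-")) {
        if (runif(1) < spec$modification_rate) {
          codes <- codes_by_parent[[chars[pos]]]
          if (length(codes) > 0L) chars[pos] <- sample(codes, 1L)
        }
      }
      for (pos in which(lengths(ins) > 0L)) {
        v <- ins[[pos]]
        for (t in seq_along(v)) {
          if (runif(1) < spec$modification_rate) {
            codes <- codes_by_parent[[v[t]]]
            if (length(codes) > 0L) v[t] <- sample(codes, 1L)
          }
        }
        ins[[pos]] <- v
      }
      member_chars[[m]] <- chars
      member_ins[[m]] <- ins
    }

    # assemble the reference alignment column by column; insertions of
    # different members occupy separate columns (no claim of homology)
    aln_seq <- lapply(seq_len(M), function(m) character(0))
    aln_struct <- lapply(seq_len(M), function(m) character(0))
    emit_insertions <- function(pos) {
      for (m in seq_len(M)) {
        for (ch in member_ins[[m]][[pos + 1L]]) {
          for (mm in seq_len(M)) {
            aln_seq[[mm]][length(aln_seq[[mm]]) + 1L] <<-
              if (mm == m) ch else "-"
            aln_struct[[mm]][length(aln_struct[[mm]]) + 1L] <<-
              if (mm == m) "." else "-"
          }
        }
      }
    }
    emit_insertions(0L)
    for (pos in seq_len(L)) {
      for (m in seq_len(M)) {
        ch <- member_chars[[m]][pos]
        aln_seq[[m]][length(aln_seq[[m]]) + 1L] <- ch
        aln_struct[[m]][length(aln_struct[[m]]) + 1L] <-
          if (ch == "-") "-" else struct_chars[pos]
      }
      emit_insertions(pos)
    }

    ids <- sprintf("seq%02d", seq_len(M))
    ref <- new_rna_set(ids,
                       vapply(aln_seq, paste, "", collapse = ""),
                       vapply(aln_struct, paste, "", collapse = ""),
                       aligned = TRUE)
    records <- ungap_alignment(ref)
    list(records = records, reference = ref,
         consensus_structure = paste(struct_chars, collapse = ""))
  })
}
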