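#!/usr/bin/env Rscript

# Command-line front end over the rna2dalign package.
#
#   Rscript scripts/rna2dalign.R align -i IN -o OUT [-matrix FILE]
#          [-gapopen INT] [-gapextend INT] [-mode simple|pseudo]
#          [-normalize] [-backend builtin|external] [-binary NAME]
#          [-modtable FILE]
#   Rscript scripts/rna2dalign.R matrix -o OUT [-mode simple|pseudo]
#          [-same_bracket INT] [-two_dots INT]
#          [-diff_bracket_same_orientation INT] [-opposite_orientation INT]
#          [-bracket_dot INT] [-same_sequence_bonus INT]
#          [-gap_open INT] [-gap_extend INT]
#   Rscript scripts/rna2dalign.R consensus -i ALIGNED [-o OUT]
#   Rscript scripts/rna2dalign.R score -i TEST -r REFERENCE [-o OUT]
#   Rscript scripts/rna2dalign.R fixtures -o PREFIX [-n INT] [-length INT]
#          [-pages INT] [-mutation REAL] [-indel REAL] [-modification REAL]
#          [-seed INT]
#   Rscript scripts/rna2dalign.R optimize -t DIR [-starts INT]
#          [-iterations INT] [-seed INT] [-o TRACE_TSV]
#          (DIR holds paired <name>.in / <name>.ref Vienna-style files)

suppressPackageStartupMessages(library(rna2dalign))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0L) {
  stop("usage: rna2dalign.R <align|matrix|consensus|score|fixtures|optimize> [options]",
       call. = FALSE)
}
cmd <- args[1]
args <- args[-1]

flag <- function(name, default = NULL) {
  hit <- which(args == paste0("-", name))
  if (length(hit) == 0L) return(default)
  if (hit == length(args)) stop(sprintf("flag -%s needs a value", name),
                                call. = FALSE)
  args[hit + 1L]
}
has_flag <- function(name) any(args == paste0("-", name))
int_flag <- function(name, default) {
  v <- flag(name)
  if (is.null(v)) return(default)
  iv <- suppressWarnings(as.integer(v))
  if (is.na(iv)) stop(sprintf("flag -%s expects an integer, got '%s'",
                              name, v), call. = FALSE)
  iv
}
num_flag <- function(name, default) {
  v <- flag(name)
  if (is.null(v)) default else as.numeric(v)
}

params_from_flags <- function() {
  matrix_params(
    same_bracket = int_flag("same_bracket", 5L),
    two_dots = int_flag("two_dots", 6L),
    diff_bracket_same_orientation =
      int_flag("diff_bracket_same_orientation", 2L),
    opposite_orientation = int_flag("opposite_orientation", -10L),
    bracket_dot = int_flag("bracket_dot", -8L),
    same_sequence_bonus = int_flag("same_sequence_bonus", 5L),
    gap_open = int_flag("gap_open", -12L),
    gap_extend = int_flag("gap_extend", -1L))
}

if (cmd == "align") {
  mode <- flag("mode", "simple")
  records <- read_vienna(flag("i"), mode = mode)
  mat <- if (!is.null(flag("matrix"))) read_matrix_file(flag("matrix"))
         else build_matrix(mode = mode)
  table <- if (!is.null(flag("modtable")))
    default_modification_table(flag("modtable"))
  else default_modification_table()
  aln <- run_pipeline(records, mode = mode, matrix = mat,
                      backend = flag("backend", "builtin"),
                      normalize = !has_flag("nonormalize"),
                      modification_table = table,
                      gap_open = int_flag("gapopen", mat$gap_open),
                      gap_extend = int_flag("gapextend", mat$gap_extend),
                      binary = flag("binary", "muscle"))
  write_vienna(aln, flag("o", stop("-o is required", call. = FALSE)))
} else if (cmd == "matrix") {
  create_matrix(flag("o", stop("-o is required", call. = FALSE)),
                params = params_from_flags(),
                mode = flag("mode", "simple"))
} else if (cmd == "consensus") {
  aln <- read_vienna(flag("i"), gapped = TRUE)
  cons <- consensus_structure(aln)
  out <- flag("o")
  if (is.null(out)) cat(cons, "\n", sep = "") else writeLines(cons, out)
} else if (cmd == "score") {
  test <- read_vienna(flag("i"), gapped = TRUE)
  reference <- read_vienna(flag("r"), gapped = TRUE)
  report <- metric_report(test, reference)
  out <- flag("o")
  if (is.null(out)) {
    write.table(format(report, digits = 6), sep = "\t", row.names = FALSE,
                quote = FALSE)
  } else {
    write.table(report, out, sep = "\t", row.names = FALSE, quote = FALSE)
  }
} else if (cmd == "fixtures") {
  prefix <- flag("o", "family")
  fam <- generate_family(family_spec(
    n_sequences = int_flag("n", 5L),
    length = int_flag("length", 60L),
    pseudoknot_pages = int_flag("pages", 1L),
    mutation_rate = num_flag("mutation", 0.1),
    indel_rate = num_flag("indel", 0.05),
    modification_rate = num_flag("modification", 0.1),
    seed = int_flag("seed", 1L)))
  write_vienna(fam$records, paste0(prefix, ".in"))
  write_vienna(fam$reference, paste0(prefix, ".ref"))
} else if (cmd == "optimize") {
  dir <- flag("t", stop("-t (training directory) is required", call. = FALSE))
  ins <- sort(list.files(dir, pattern = "\\.in$", full.names = TRUE))
  training <- lapply(ins, function(f) {
    ref <- sub("\\.in$", ".ref", f)
    list(records = read_vienna(f), reference = read_vienna(ref, gapped = TRUE))
  })
  res <- optimize_matrix_params(
    training,
    starts = default_start_params(int_flag("starts", 18L)),
    iterations = int_flag("iterations", 50L),
    seed = int_flag("seed", 1L))
  print(res$params)
  cat(sprintf("objective: %.4f\n", res$objective))
  out <- flag("o")
  if (!is.null(out)) {
    write.table(res$trace, out, sep = "\t", row.names = FALSE, quote = FALSE)
  }
} else {
  stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
}
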