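test_that("pairwise alignment scores and reproduces simple cases", {
  m <- build_matrix()
  # "F" encodes (A, "("): diagonal entry 5 + 5
  res <- pairwise_align("FF", "FF", m)
  expect_equal(res$score, 20)
  expect_equal(res$s1, "FF")
  expect_equal(res$s2, "FF")

  # aligning any sequence with itself gives the sum of diagonal entries
  set.seed(9)
  for (k in 1:10) {
    s <- random_string(sample(3:12, 1), m$alphabet)
    res <- pairwise_align(s, s, m)
    chars <- strsplit(s, "")[[1]]
    expect_equal(res$score, sum(diag(m$scores)[match(chars, m$alphabet)]))
    expect_equal(res$s1, s)
  }
})

test_that("pairwise DP equals the exponential enumeration oracle", {
  m <- build_matrix()
  letters3 <- c("A", "F", "L")  # (A,.), (A,(), (C,))
  set.seed(31)
  for (k in 1:25) {
    s1 <- random_string(sample(0:5, 1), letters3)
    s2 <- random_string(sample(0:5, 1), letters3)
    a <- match(strsplit(s1, "")[[1]], m$alphabet)
    b <- match(strsplit(s2, "")[[1]], m$alphabet)
    expect_equal(pairwise_align(s1, s2, m)$score,
                 bf_align_score(a, b, m$scores, m$gap_open, m$gap_extend),
                 info = paste(s1, s2))
  }
})

test_that("the builtin progressive aligner preserves rows and columns", {
  fam <- generate_family(family_spec(n_sequences = 6L, length = 50L,
                                     seed = 17))
  m <- build_matrix()
  enc <- vapply(seq_len(nrow(fam$records)), function(k) {
    encode_simple(strip_modifications(fam$records$sequence[k])$sequence,
                  fam$records$structure[k])$letters
  }, "")
  names(enc) <- fam$records$id
  aligned <- align_builtin(enc, m)
  # gap projection: deleting gaps reproduces the encoded input
  expect_identical(gsub("-", "", aligned, fixed = TRUE), enc)
  # column conservation: equal lengths and no all-gap columns
  widths <- unique(nchar(aligned))
  expect_length(widths, 1L)
  cols <- do.call(rbind, strsplit(aligned, ""))
  expect_true(all(colSums(cols != "-") > 0L))
  # determinism
  expect_identical(align_builtin(enc, m), aligned)
  # input order is restored even for shuffled input
  shuffle <- c(4L, 1L, 6L, 3L, 2L, 5L)
  expect_identical(unname(align_builtin(enc[shuffle], m)),
                   unname(aligned[shuffle]))
})

test_that("the pipeline handles degenerate record counts", {
  recs <- read_vienna(text = ">only\nGGGAAACCC\n(((...)))\n")
  aln <- run_pipeline(recs)
  expect_equal(nrow(aln), 1L)
  expect_identical(aln$sequence, recs$sequence)
  expect_identical(aln$structure, recs$structure)

  twin <- read_vienna(text = ">a\nGGGAAACCC\n(((...)))\n>b\nGGGAAACCC\n(((...)))\n")
  aln2 <- run_pipeline(twin)
  expect_false(any(grepl("-", aln2$sequence, fixed = TRUE)))
  expect_identical(aln2$sequence, twin$sequence)
})

test_that("a loop insertion is gapped inside the loop", {
  recs <- read_vienna(text = paste0(
    ">short\nGGGGAAAACCCC\n((((....))))\n",
    ">long\nGGGGAAAAAACCCC\n((((......))))\n"))
  aln <- run_pipeline(recs)
  expect_equal(unique(nchar(aln$sequence)), 14L)
  gap_cols <- which(strsplit(aln$sequence[1], "")[[1]] == "-")
  expect_length(gap_cols, 2L)
  # the gapped columns fall in the partner's loop region
  partner_struct <- strsplit(aln$structure[2], "")[[1]]
  expect_true(all(partner_struct[gap_cols] == "."))
  # ungapping reproduces the inputs
  ung <- ungap_alignment(aln)
  expect_identical(ung$sequence, recs$sequence)
  expect_identical(ung$structure, recs$structure)
})

test_that("pipeline demotes higher-order pseudoknots with a warning", {
  # three mutually crossing helices force page 3 in simple mode
  recs <- data.frame(
    id = c("pk", "pk2"),
    sequence = c("GGAACCGGUUCCAAGG", "GGAACCGGUUCCAAGG"),
    structure = c("((..[[{{..))]]}}", "((..[[{{..))]]}}"),
    stringsAsFactors = FALSE)
  expect_warning(aln <- run_pipeline(recs), "demoted")
  # demoted third-page brackets come out as dots
  expect_identical(ungap_alignment(aln)$structure[1], "((..[[....))]]..")
  expect_equal(attr(aln, "demoted")$n_demoted, c(4L, 4L))
  # pseudo mode keeps all three pages
  aln_p <- run_pipeline(recs[1, ], mode = "pseudo")
  expect_identical(ungap_alignment(aln_p)$structure, recs$structure[1])
})

test_that("the external adapter fails actionably when the binary is absent", {
  m <- build_matrix()
  expect_error(align_external(c(a = "AAF"), m,
                              binary = "no_such_aligner_xyz"),
               "builtin")
  expect_error(align_external(character(0), m), "no sequences")
  recs <- read_vienna(text = ">a\nGGAACC\n((..))\n>b\nGGAACC\n((..))\n")
  expect_error(run_pipeline(recs, backend = "external",
                            binary = "no_such_aligner_xyz"),
               "not found")
})
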