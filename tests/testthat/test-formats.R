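test_that("Vienna-style records parse with validation", {
  recs <- read_vienna(text = ">r1\nACGU\n.().\n")
  expect_equal(recs$id, "r1")
  expect_equal(recs$sequence, "ACGU")
  expect_equal(recs$structure, ".().")

  expect_error(read_vienna(text = ">r1\nACG\n.().\n"), "length mismatch")
  expect_error(read_vienna(text = ">r1\nACGU\n.((.\n"), "unbalanced")
  expect_error(read_vienna(text = ">r1\nACGU\n.(x.\n"),
               "unknown structure character")
  expect_error(read_vienna(text = ""), "empty input")

  # pseudo mode: 2-line records, sequence stored empty
  recs2 <- read_vienna(text = ">a\n((..))\n", mode = "pseudo")
  expect_equal(recs2$sequence, "")
  expect_equal(recs2$structure, "((..))")
})

test_that("input tolerates CRLF, blank lines, case and T", {
  txt <- ">r1\r\n\r\nacgt\r\n.().\r\n\r\n>r2\nGGAA\n(..)\n"
  recs <- read_vienna(text = txt)
  expect_equal(recs$sequence, c("ACGU", "GGAA"))
  expect_equal(nrow(recs), 2L)
})

test_that("vienna write/read round-trips, including empty sets", {
  f <- withr::local_tempfile()
  aln <- toy_alignment("r1", "AC-GU", ".(-).")
  write_vienna(aln, f)
  expect_identical(readLines(f), c(">r1", "AC-GU", ".(-)."))

  write_vienna(read_vienna(text = ">a\n((..))\n", mode = "pseudo"), f)
  expect_identical(readLines(f), c(">a", "((..))"))

  empty <- read_vienna(text = ">x\nA\n.\n")[0, ]
  write_vienna(empty, f)
  expect_length(readLines(f), 0L)

  # property: identity over 50 generated records
  for (k in 1:10) {
    fam <- generate_family(family_spec(n_sequences = 5L, length = 40L,
                                       seed = 100 + k))
    write_vienna(fam$records, f)
    back <- read_vienna(f)
    expect_equal(back$id, fam$records$id)
    expect_equal(back$sequence, fam$records$sequence)
    expect_equal(back$structure, fam$records$structure)
  }
})

test_that("aligned files read back with gaps when requested", {
  fam <- generate_family(family_spec(n_sequences = 4L, length = 40L,
                                     indel_rate = 0.2, seed = 55))
  f <- withr::local_tempfile()
  write_vienna(fam$reference, f)
  back <- read_vienna(f, gapped = TRUE)
  expect_s3_class(back, "rna_alignment")
  expect_identical(back$structure, fam$reference$structure)
  # without gapped = TRUE the gap characters are rejected
  expect_error(read_vienna(f), "unknown structure character '-'")
})

write_ct <- function(lines) {
  f <- tempfile(fileext = ".ct")
  writeLines(lines, f)
  f
}

test_that(".ct files convert to canonical dot-bracket", {
  f <- write_ct(c("4 tiny hairpin",
                  "1 A 0 2 4 1",
                  "2 C 1 3 3 2",
                  "3 G 2 4 2 3",
                  "4 U 3 0 1 4"))
  rec <- read_ct(f)
  expect_equal(rec$sequence, "ACGU")
  expect_equal(rec$structure, "(())")
  expect_equal(rec$id, "tiny hairpin")

  # unpaired-only, with an interleaved comment line
  f2 <- write_ct(c("3 all loop",
                   "# ENERGY = 0",
                   "1 A 0 2 0 1",
                   "2 C 1 3 0 2",
                   "3 G 2 0 0 3"))
  expect_equal(read_ct(f2)$structure, "...")

  # crossing pairs (1,6), (2,7): needs two pages
  f3 <- write_ct(c("8 crossing",
                   "1 A 0 2 6 1",
                   "2 C 1 3 7 2",
                   "3 G 2 4 0 3",
                   "4 U 3 5 0 4",
                   "5 A 4 6 0 5",
                   "6 C 5 7 1 6",
                   "7 G 6 8 2 7",
                   "8 U 7 0 0 8"))
  rec3 <- read_ct(f3)
  expect_equal(rec3$structure, "([...)].")
  pairs <- rbind(c(1L, 6L), c(2L, 7L))
  expect_equal(bf_min_pages(pairs), 2L)

  f4 <- write_ct(c("2 broken", "1 A 0 2 2 1", "2 C 1 0 1 2", "3"))
  expect_equal(read_ct(f4)$structure, "()")
  f5 <- write_ct(c("3 inconsistent",
                   "1 A 0 2 3 1",
                   "2 C 1 3 0 2",
                   "3 G 2 0 2 3"))
  expect_error(read_ct(f5), "inconsistent pairing")
})

test_that("matrix files round-trip in the NCBI-style layout", {
  f <- withr::local_tempfile()
  m <- build_matrix()
  write_matrix_file(m, f)
  back <- read_matrix_file(f)
  # pass-through letters are appended with the sentinel
  expect_setequal(back$alphabet, c(m$alphabet, "B", "Z", "X", "*"))
  expect_equal(back$scores[m$alphabet, m$alphabet], m$scores)
  expect_true(all(back$scores["B", ] == -100L))

  # diagonal entries of the written file match build_matrix
  for (l in m$alphabet) expect_equal(back$scores[l, l], m$scores[l, l])

  # toy matrix, no pass-through: byte-level round trip
  toy <- rna2dalign:::new_scoring_matrix(
    c("A", "C"), matrix(c(2L, -1L, -1L, 2L), 2, 2,
                        dimnames = list(c("A", "C"), c("A", "C"))),
    -5L, -1L)
  write_matrix_file(toy, f, passthrough = character(0))
  first <- readLines(f)
  back2 <- read_matrix_file(f)
  expect_equal(back2$scores, toy$scores)
  write_matrix_file(back2, f, passthrough = character(0))
  expect_identical(readLines(f), first)
})

test_that("malformed matrix files are rejected", {
  f <- withr::local_tempfile()
  writeLines(c("  A  C", "A  1  2"), f)
  expect_error(read_matrix_file(f), "1 data rows for a 2-letter header")
  writeLines(c("  A  C", "A  1  2", "C  2  x"), f)
  expect_error(read_matrix_file(f), "non-integer")
  writeLines(c("  A  C", "A  1  2", "B  2  1"), f)
  expect_error(read_matrix_file(f), "label")
})

test_that("plain FASTA read/write round-trips gapped sequences", {
  f <- withr::local_tempfile()
  x <- c(s1 = "AC-GU", s2 = "ACCGU")
  write_fasta(x, f)
  expect_identical(read_fasta(f), x)
})
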