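test_that("dot-bracket parsing assigns pairs to bracket-family pages", {
  ps <- parse_dotbracket("((..))")
  expect_equal(ps$n, 6L)
  expect_length(ps$pages, 1L)
  expect_equal(unname(ps$pages[[1]]), rbind(c(1L, 6L), c(2L, 5L)),
               ignore_attr = TRUE)
  expect_equal(ps$unpaired, c(3L, 4L))

  ps2 <- parse_dotbracket("(([[..))]]")
  expect_length(ps2$pages, 2L)
  expect_equal(unname(ps2$pages[[1]]), rbind(c(1L, 8L), c(2L, 7L)),
               ignore_attr = TRUE)
  expect_equal(unname(ps2$pages[[2]]), rbind(c(3L, 10L), c(4L, 9L)),
               ignore_attr = TRUE)

  empty <- parse_dotbracket("")
  expect_equal(empty$n, 0L)
  expect_length(empty$pages, 0L)
})

test_that("unbalanced or unknown structures are rejected with a position", {
  expect_error(parse_dotbracket("(()"), "unbalanced '\\(' at position 1")
  expect_error(parse_dotbracket("())"), "unbalanced '\\)' at position 3")
  expect_error(parse_dotbracket("..x."), "unknown structure character 'x'")
  expect_error(parse_dotbracket("]["), "unbalanced '\\]' at position 1")
})

test_that("parse/render identity holds on exhaustive short structures", {
  # every valid structure over {., (, ), [, ]} up to length 5
  for (s in all_strings(c(".", "(", ")", "[", "]"), 5L)) {
    ps <- tryCatch(parse_dotbracket(s), error = function(e) NULL)
    if (is.null(ps)) next
    expect_identical(render_dotbracket(ps), s)
  }
})

test_that("pseudoknot normalization preserves pairs and is idempotent", {
  expect_identical(normalize_pseudoknots("[[[(((...]]])))"),
                   "((([[[...)))]]]")
  expect_identical(normalize_pseudoknots("((..))"), "((..))")
  for (s in all_strings(c(".", "(", ")", "[", "]"), 5L)) {
    ps <- tryCatch(parse_dotbracket(s), error = function(e) NULL)
    if (is.null(ps)) next
    norm <- normalize_pseudoknots(s)
    # identical pair set, page labels aside
    flat <- function(x) {
      p <- do.call(rbind, c(list(matrix(0L, 0, 2)), x$pages))
      p[order(p[, 1]), , drop = FALSE]
    }
    expect_equal(flat(parse_dotbracket(norm)), flat(ps),
                 ignore_attr = TRUE)
    expect_identical(normalize_pseudoknots(norm), norm)
  }
})

test_that("higher-order pages demote to unpaired and are restorable", {
  # 3-page structure: ( [ { . ) ] }
  s <- "([{.)]}"
  ps <- parse_dotbracket(s)
  expect_length(ps$pages, 3L)
  dem <- demote_higher_order(ps, 2L)
  expect_equal(dem$demoted, c(3L, 7L))
  expect_identical(render_dotbracket(dem$pair_set), "([..)].")
  expect_length(demote_higher_order(ps, 3L)$demoted, 0L)

  # demotion record restores the original string through encode/decode
  rec <- data.frame(pos = dem$demoted,
                    char = strsplit(s, "")[[1]][dem$demoted])
  enc <- encode_pseudo(render_dotbracket(dem$pair_set))
  out <- pseudo_decode(enc$letters, "pseudo", demoted = rec)
  expect_identical(out$structure, s)
})

test_that("simple-mode codec follows the canonical index formula", {
  expect_identical(codec_letter("A", "."), "A")
  expect_identical(codec_letter("U", "."), "E")
  expect_identical(encode_simple("ACGU", "(())")$letters, "FGMN")
  # full table: letter index = 4*symbol + nucleotide (0-based)
  canon <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  syms <- c(".", "(", ")", "[", "]")
  nts <- c("A", "C", "G", "U")
  for (s in 0:4) {
    for (n in 0:3) {
      expect_identical(codec_letter(nts[n + 1], syms[s + 1]),
                       canon[4 * s + n + 1])
    }
  }
})

test_that("pseudo-mode codec covers the 9 structure symbols", {
  expect_identical(encode_pseudo("((..))")$letters, "CCAADD")
  expect_identical(encode_pseudo("")$letters, "")
  expect_identical(encode_pseudo(".([{<)]}>")$letters, "ACEGIDFHK")
})

test_that("encode errors instruct on unstripped or undemoted input", {
  expect_error(encode_simple("APGU", "...."), "strip_modifications")
  expect_error(encode_simple("ACGU", "{..}"), "demote")
  expect_error(encode_simple("ACG", "...."), "lengths differ")
  expect_error(encode_pseudo("(#)"), "invalid structure character")
})

test_that("decode inverts encode and passes gaps through", {
  expect_equal(pseudo_decode("A-E", "simple"),
               list(sequence = "A-U", structure = ".-."))
  expect_error(pseudo_decode("J", "simple"), "outside")
  expect_error(pseudo_decode("M", "pseudo"), "outside")

  set.seed(402)
  for (k in 1:60) {
    fam <- generate_family(family_spec(
      n_sequences = 1L, length = sample(20:50, 1),
      pseudoknot_pages = sample(1:2, 1), modification_rate = 0,
      seed = k))
    rec <- fam$records
    enc <- encode_simple(rec$sequence, rec$structure)
    dec <- pseudo_decode(enc$letters, "simple")
    expect_identical(dec$sequence, rec$sequence)
    expect_identical(dec$structure, rec$structure)
    encp <- encode_pseudo(rec$structure)
    expect_identical(pseudo_decode(encp$letters, "pseudo")$structure,
                     rec$structure)
  }
})
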