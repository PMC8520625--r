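test_that("consensus structure follows majority rule with repair", {
  aln <- toy_alignment(c("a", "b", "c"),
                       c("GGAACC", "GGAACC", "GGAACC"),
                       c("((..))", "((..))", "((..))"))
  expect_equal(consensus_structure(aln), "((..))")

  aln2 <- toy_alignment(c("a", "b", "c"),
                        c("GAC", "GAC", "GAC"),
                        c("(.)", "(.)", "..."))
  expect_equal(consensus_structure(aln2), "(.)")

  # per-column majority can produce unmatched brackets; repair demotes them
  aln3 <- toy_alignment(c("a", "b"), c("GG", "CC"), c("((", "))"))
  expect_equal(consensus_structure(aln3), "..")

  # majority-gap columns and ties become dots
  aln4 <- toy_alignment(c("a", "b", "c"),
                        c("G--", "GA-", "GAC"),
                        c(".--", ".(-", ".()"))
  expect_equal(consensus_structure(aln4), "...")
})

test_that("structural distance is a unit-cost edit distance", {
  expect_equal(structural_distance("(.)", "(.)"), 0L)
  expect_equal(structural_distance("(.)", "()"), 1L)
  expect_equal(structural_distance("(-.)", "()"), 1L)  # gaps stripped

  # exhaustive short pairs plus seeded longer draws vs enumeration oracle
  short <- all_strings(c(".", "(", ")"), 2L)
  for (s1 in short) {
    for (s2 in short) {
      expect_equal(structural_distance(s1, s2), bf_edit_distance(s1, s2))
    }
  }
  set.seed(5)
  for (k in 1:30) {
    s1 <- random_string(sample(3:5, 1), c(".", "(", ")"))
    s2 <- random_string(sample(3:5, 1), c(".", "(", ")"))
    expect_equal(structural_distance(s1, s2), bf_edit_distance(s1, s2))
  }
})

test_that("structural distance satisfies metric axioms on random triples", {
  set.seed(21)
  for (k in 1:40) {
    xs <- replicate(3, random_string(sample(0:8, 1), c(".", "(", ")")))
    d12 <- structural_distance(xs[1], xs[2])
    d13 <- structural_distance(xs[1], xs[3])
    d23 <- structural_distance(xs[2], xs[3])
    expect_gte(d12, 0L)
    expect_equal(d12, structural_distance(xs[2], xs[1]))
    expect_lte(d13, d12 + d23)
  }
})

test_that("mean structural distance and its score behave as defined", {
  ident <- toy_alignment(c("a", "b"), c("GGAACC", "GGAACC"),
                         c("((..))", "((..))"))
  expect_equal(mean_structural_distance(ident), 0)
  expect_equal(structural_distance_score(ident), 1)

  # consensus "((..))"; row b at distance 2, row a at 0 -> mean 1
  aln <- toy_alignment(c("a", "b", "c"),
                       c("GGAACC", "GGAACC", "GGAACC"),
                       c("((..))", "(....)", "((..))"))
  cons <- consensus_structure(aln)
  expect_equal(cons, "((..))")
  d <- vapply(aln$structure, function(s) structural_distance(cons, s), 0L)
  expect_equal(unname(d), c(0L, 2L, 0L))
  expect_equal(mean_structural_distance(aln), 2 / 3)
  expect_equal(structural_distance_score(aln), 1 - (2 / 3) / 6)
})

test_that("SPS and PPV are exact on identity and disjoint columnizations", {
  fam <- generate_family(family_spec(n_sequences = 4L, length = 40L,
                                     seed = 3))
  expect_equal(sps(fam$reference, fam$reference), 1)
  expect_equal(ppv(fam$reference, fam$reference), 1)

  # a shifted test alignment whose residue pairs are all wrong
  ref <- toy_alignment(c("a", "b"), c("AC-", "-AC"), c("..-", "-.."))
  test <- toy_alignment(c("a", "b"), c("A-C", "-AC"), c(".-.", "-.."))
  expect_equal(sps(ref, ref), 1)
  expect_equal(sps(test, ref), 0)
  expect_equal(ppv(test, ref), 0)

  # a test alignment with no residue pairs at all hits the =1 convention
  # for PPV (empty test set) but scores 0 on SPS (no reference pair found)
  apart <- toy_alignment(c("a", "b"), c("AC--", "--AC"), c("..--", "--.."))
  expect_equal(sps(apart, ref), 0)
  expect_equal(ppv(apart, ref), 1)
})

test_that("SPS and PPV match brute-force set computations on a toy", {
  ref <- toy_alignment(c("a", "b", "c"),
                       c("GGAAC-", "G-AACC", "GGA-CC"),
                       c("..... -", "-.....", ".....-"))
  # fix structures to be valid strings of the same gap pattern
  ref$structure <- gsub("[^-]", ".", ref$sequence)
  test <- toy_alignment(c("a", "b", "c"),
                        c("GGAAC-", "GAACC-", "GGACC-"),
                        c("", "", ""))
  test$structure <- gsub("[^-]", ".", test$sequence)
  expect_equal(sps(test, ref), bf_sps(test, ref))
  expect_equal(ppv(test, ref), bf_ppv(test, ref))
  expect_lt(sps(test, ref), 1)

  # and on pipeline output for a mutated family
  fam <- generate_family(family_spec(n_sequences = 3L, length = 30L,
                                     mutation_rate = 0.2, indel_rate = 0.1,
                                     seed = 12))
  aln <- run_pipeline(fam$records)
  expect_equal(sps(aln, fam$reference), bf_sps(aln, fam$reference))
  expect_equal(ppv(aln, fam$reference), bf_ppv(aln, fam$reference))
})

test_that("metric inputs are validated", {
  ref <- toy_alignment(c("a", "b"), c("AC", "AC"), c("..", ".."))
  wrong_id <- toy_alignment(c("a", "x"), c("AC", "AC"), c("..", ".."))
  wrong_seq <- toy_alignment(c("a", "b"), c("AC", "AG"), c("..", ".."))
  expect_error(sps(wrong_id, ref), "different ids")
  expect_error(sps(wrong_seq, ref), "different ungapped content")
  ragged <- toy_alignment(c("a", "b"), c("AC", "AC"), c("..", "..."))
  expect_error(sps(ragged, ref), "unequal")
})
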