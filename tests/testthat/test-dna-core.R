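test_that("reverse, complement and reverse-complement match their definitions", {
  expect_equal(dna_reverse("TCATGGAA"), "AAGGTACT")
  expect_equal(dna_complement("TCATGGAA"), "AGTACCTT")
  # the definition applied symbol by symbol (not the misprinted example)
  expect_equal(dna_revcomp("TCATGGAA"), "TTCCATGA")
  expect_equal(dna_reverse("A"), "A")
  expect_equal(dna_complement("AT"), "TA")
  expect_equal(dna_revcomp("AT"), "AT")
})

test_that("reverse/complement/revcomp are involutions and commute", {
  set.seed(42)
  for (w in c("ACGT", "GATTACA", "ACCGT", random_words(20, 9))) {
    expect_equal(dna_reverse(dna_reverse(w)), w)
    expect_equal(dna_complement(dna_complement(w)), w)
    expect_equal(dna_revcomp(dna_revcomp(w)), w)
    expect_equal(dna_revcomp(w), dna_reverse(dna_complement(w)))
    expect_equal(dna_revcomp(w), dna_complement(dna_reverse(w)))
    expect_equal(dna_revcomp(w), bf_revcomp(w))
  }
})

test_that("revcomp agrees with the Biostrings implementation", {
  set.seed(7)
  words <- random_words(25, 12)
  expect_equal(dna_revcomp(words),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAStringSet(words))))
})

test_that("hamming_dist counts mismatched positions and rejects bad input", {
  expect_equal(hamming_dist("ACGT", "ACGT"), 0)
  expect_equal(hamming_dist("CTGTGAC", "ATGTACG"), 4)
  expect_equal(hamming_dist("AAAA", "TTTT"), 4)
  expect_error(hamming_dist("ACG", "ACGT"), "length mismatch")
  expect_error(as_dna("ACGU"), "invalid DNA")
})

test_that("hamming distance is a metric on the full space at small n", {
  words <- all_words(3)
  H <- outer(words, words, Vectorize(hamming_dist))
  expect_true(all(diag(H) == 0))
  expect_true(all(H == t(H)))
  expect_true(all(H[words != rep(words, each = length(words))] > 0))
  # triangle inequality over a random sample of triples (full space n=3)
  set.seed(1)
  for (rep in 1:200) {
    ijk <- sample(length(words), 3)
    expect_lte(H[ijk[1], ijk[3]], H[ijk[1], ijk[2]] + H[ijk[2], ijk[3]])
  }
})

test_that("gc_count is exact and invariant under complementation", {
  expect_equal(gc_count("CTGTGAC"), 4)
  expect_equal(gc_count("AAAA"), 0)
  expect_equal(gc_count("GCGC"), 4)
  set.seed(3)
  w <- random_words(30, 8)
  expect_equal(gc_count(dna_complement(w)), gc_count(w))
})

test_that("GC constraint admits both balanced counts at odd n", {
  cc7 <- dna_constraints(7, 3)
  expect_true(satisfies_gc("ATGTACG", cc7))   # GC = 3 = floor(7/2)
  expect_true(satisfies_gc("CTGTGAC", cc7))   # GC = 4 = ceiling(7/2)
  expect_false(satisfies_gc("ATATATA", cc7))
  cc4 <- dna_constraints(4, 2)
  expect_true(satisfies_gc("GCAT", cc4))
  expect_false(satisfies_gc("AAAA", cc4))
  # exact-W mode via explicit tolerance
  strict <- dna_constraints(7, 3, gc_tolerance = 3)
  expect_false(satisfies_gc("CTGTGAC", strict))
})

test_that("no-runlength predicate matches a run-length-encoding scan", {
  expect_true(is_run_free("CTGTGAC"))
  expect_false(is_run_free("GAGATTC"))  # adjacent TT
  expect_false(is_run_free("AAAA"))
  expect_true(is_run_free("AATA", max_run = 2))
  set.seed(11)
  for (w in random_words(40, 10)) {
    for (cap in 1:3) {
      expect_identical(is_run_free(w, cap), bf_run_free(w, cap),
                       info = paste(w, cap))
    }
  }
})

test_that("reverse-complement pair predicate follows its definition", {
  expect_true(satisfies_rc_pair("AAAA", "AAAA", 4))
  expect_false(satisfies_rc_pair("AT", "AT", 1))
  set.seed(5)
  for (rep in 1:30) {
    x <- random_words(1, 7); y <- random_words(1, 7)
    for (d in c(3, 5)) {
      expect_identical(satisfies_rc_pair(x, y, d),
                       bf_hamming(x, bf_revcomp(y)) >= d)
    }
  }
})

test_that("secondary-structure screen finds stems and matches brute force", {
  expect_false(has_secondary_structure("AAAAA", 2))
  expect_true(has_secondary_structure("ACGTAACGT", 4))
  expect_false(has_secondary_structure("ACGT", 2))
  set.seed(9)
  for (n in 5:8) {
    for (w in random_words(25, n)) {
      for (stem in 2:3) {
        expect_identical(has_secondary_structure(w, stem),
                         bf_secondary_structure(w, stem),
                         info = paste(w, stem))
      }
    }
  }
})

test_that("constraint-set construction enforces its invariants", {
  expect_error(dna_constraints(4, 5), "1 <= d <= n")
  expect_error(dna_constraints(4, 2, W = 7), "0 <= W <= n")
  expect_error(dna_constraints(4, 2, ss_min_stem = 1), "ss_min_stem")
  cc <- dna_constraints(8, 5, use_rc = TRUE, use_ss = TRUE)
  expect_s3_class(cc, "dna_constraints")
  expect_identical(cc$gc_tolerance, 4L)
})
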