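table5_path <- system.file("extdata", "mfos_n7_d5.cod", package = "dnacodes")

test_that("code-set construction rejects duplicates and mixed lengths", {
  expect_error(dna_codeset(c("ACGT", "ACGT")), "duplicate")
  expect_error(dna_codeset(c("ACGT", "ACG")), "equal length")
  expect_error(dna_codeset(c("ACGT", "TGCA"), dna_constraints(5, 3)),
               "does not match")
  cs <- dna_codeset(c("ACGT", "TGCA"))
  expect_equal(length(cs), 2)
})

test_that("validator agrees with a brute-force pairwise checker", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    K <- sample(2:50, 1)
    words <- unique(random_words(K, n))
    cons <- dna_constraints(n, d = sample(1:n, 1),
                            use_rc = runif(1) < 0.5,
                            use_ss = runif(1) < 0.3)
    got <- validate_codeset(dna_codeset(words), cons)
    expect_identical(got$overall_pass, bf_validate(words, cons),
                     info = paste("rep", rep))
    # report internally consistent: pass iff no violations listed
    expect_identical(got$overall_pass,
                     nrow(got$word_violations) + nrow(got$pair_violations) == 0)
  }
})

test_that("validator agrees with brute force over the full word space at n <= 4", {
  for (n in 2:4) {
    words <- all_words(n)
    cons <- dna_constraints(n, d = max(1, n - 1), use_rc = (n == 3))
    set.seed(n)
    # partition the full 4^n space into sets and check each
    grp <- split(sample(words), rep(1:8, length.out = length(words)))
    for (g in grp) {
      got <- validate_codeset(dna_codeset(g), cons)
      expect_identical(got$overall_pass, bf_validate(g, cons))
    }
  }
})

test_that("published 23-word set shows its printed inconsistencies", {
  cs <- read_codes(table5_path)
  expect_equal(length(cs), 23)
  # GC-only validation: the printed set itself contains two words with
  # unbalanced GC (direct count: GTACTAT has 2, CTGCCTC has 5)
  rep_gc <- validate_codeset(cs, dna_constraints(7, 1, use_nl = FALSE))
  expect_setequal(rep_gc$word_violations$word, c("GTACTAT", "CTGCCTC"))
  # full C^{GC,NL,RC}(7, 3, 5): fails with specific violations
  full <- dna_constraints(7, 5, use_rc = TRUE)
  rep_full <- validate_codeset(cs, full)
  expect_false(rep_full$overall_pass)
  expect_true("GAGATTC" %in%
                rep_full$word_violations$word[
                  rep_full$word_violations$rule == "runlength"])
  ham <- rep_full$pair_violations[rep_full$pair_violations$rule == "hamming", ]
  expect_true(any(ham$word_i == "CTGTGAC" & ham$word_j == "ATGTACG" &
                    ham$value == 4))
})

test_that("coding rates reproduce printed values under truncation", {
  expect_equal(coding_rate(5, 2, digits = 4), 0.5804)
  expect_equal(coding_rate(4, 1), 1.0)
  expect_equal(coding_rate(190, 12, digits = 3), 0.315)
  expect_error(coding_rate(0, 5), ">= 1")
  # monotonicity: increasing in K, decreasing in n (K > 1)
  Ks <- c(2, 5, 20, 100, 500)
  expect_true(all(diff(sapply(Ks, coding_rate, n = 8)) > 0))
  ns <- 2:10
  expect_true(all(diff(sapply(ns, function(n) coding_rate(50, n))) < 0))
})

test_that("percent comparisons reproduce printed values", {
  expect_equal(percent_change(11967, 12068, digits = 2), -0.83)
  expect_equal(percent_change(8, 9, digits = 2), -11.11)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(5, 0), "positive")
})

test_that("truncation toward zero differs from rounding where it must", {
  expect_equal(trunc_digits(0.58048, 4), 0.5804)   # rounding would give 0.5805
  expect_equal(trunc_digits(0.54574, 3), 0.545)
  expect_equal(trunc_digits(-0.8368, 2), -0.83)
  expect_equal(trunc_digits(0.8368, 2), 0.83)
})

test_that("cod and FASTA round trips preserve order and content", {
  set.seed(31)
  words <- unique(random_words(15, 6))
  cons <- dna_constraints(6, 3, use_rc = TRUE)
  cs <- dna_codeset(words, cons, provenance = "round-trip test")
  for (ext in c("cod", "fasta")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_codes(cs, path)
    back <- read_codes(path)
    expect_identical(back$words, cs$words, info = ext)
  }
  # .cod header restores the constraint specification
  path <- withr::local_tempfile(fileext = ".cod")
  write_codes(cs, path)
  back <- read_codes(path)
  expect_equal(back$constraints$n, 6L)
  expect_equal(back$constraints$d, 3L)
  expect_true(back$constraints$use_rc)
})

test_that("malformed code files are rejected with line context", {
  path <- withr::local_tempfile(fileext = ".cod")
  writeLines(c("# n=4 d=2", "ACGT", "ACGU"), path)
  expect_error(read_codes(path), "line 3")
  writeLines(character(0), path)
  expect_error(read_codes(path), "no codewords")
})

test_that("validation reports export as JSON", {
  cs <- dna_codeset(c("ACGT", "AGGT"))  # Hamming distance 1 (position 2)
  js <- validation_to_json(validate_codeset(cs, dna_constraints(4, 3)))
  parsed <- jsonlite::fromJSON(js)
  expect_false(parsed$overall_pass)
  expect_equal(parsed$pair_violations$value, 1)
})
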