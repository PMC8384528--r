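test_that("mutation notation parses in either order with duplicates collapsed", {
  one <- parse_variant_spec("I77L")
  expect_s3_class(one, "mutation_set")
  expect_identical(nrow(one), 1L)
  expect_identical(one$wt, "I")
  expect_identical(one$pos, 77L)
  expect_identical(one$mut, "L")

  two <- parse_variant_spec("I77L_H210N")
  expect_identical(two$pos, c(77L, 210L))
  expect_identical(parse_variant_spec("H210N_I77L"), two)
  expect_identical(parse_variant_spec("I77L_I77L_H210N"), two)

  expect_identical(nrow(parse_variant_spec("")), 0L)
  expect_identical(nrow(parse_variant_spec("WT")), 0L)
  expect_identical(nrow(parse_variant_spec("wt")), 0L)
})

test_that("malformed or contradictory mutation specs are rejected", {
  expect_error(parse_variant_spec("I77I"), "silent")
  expect_error(parse_variant_spec("I77L_I77M"), "conflicting.*77")
  expect_error(parse_variant_spec("77L"), "malformed")
  expect_error(parse_variant_spec("I77"), "malformed")
  expect_error(parse_variant_spec("I0L"), ">= 1")
})

test_that("signatures round-trip through parse and format", {
  for (sig in c("WT", "I77L", "I77L_H210N", "I77L_Q97E_H210N_N245D_G292D_I295V")) {
    expect_identical(format_variant_spec(parse_variant_spec(sig)), sig)
  }
  # order normalizes to position-sorted
  expect_identical(format_variant_spec(parse_variant_spec("H210N_I77L")),
                   "I77L_H210N")
})

test_that("apply_variant substitutes exactly the mutated positions", {
  expect_identical(apply_variant("ACDEF", parse_variant_spec("C2G")), "AGDEF")
  expect_identical(apply_variant("ACDEF", mutation_set()), "ACDEF")
  expect_error(apply_variant("ACDEF", parse_variant_spec("G2C")),
               "position 2.*expected G.*found C")
  expect_error(apply_variant("ACDEF", parse_variant_spec("C9G")),
               "exceeds sequence length")
  # escape hatch for deliberately mismatched numbering
  expect_identical(apply_variant("ACDEF", parse_variant_spec("G2C"),
                                 validate_wt = FALSE), "ACDEF")
})

test_that("enumerate_library produces every subset exactly once", {
  ms3 <- parse_variant_spec("A1C_D2E_F3G")
  lib <- enumerate_library(ms3)
  expect_length(lib, 8L)
  # brute-force subset enumeration oracle
  muts <- c("A1C", "D2E", "F3G")
  expected <- unlist(lapply(0:3, function(k) {
    if (k == 0) return("WT")
    apply(combn(muts, k), 2, paste, collapse = "_")
  }))
  expect_setequal(names(lib), expected)
  # deterministic order: subset size first
  expect_identical(vapply(lib, nrow, integer(1)),
                   setNames(c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L), names(lib)))

  expect_length(enumerate_library(mutation_set()), 1L)
  expect_identical(names(enumerate_library(mutation_set())), "WT")
})

test_that("the six-mutation panel spans 64 distinct sequences at the right Hamming distances", {
  six <- parse_variant_spec("I77L_Q97E_H210N_N245D_G292D_I295V")
  lib <- enumerate_library(six)
  expect_length(lib, 64L)
  expect_true("WT" %in% names(lib))
  expect_true("I77L_Q97E_H210N_N245D_G292D_I295V" %in% names(lib))

  wt <- synthetic_transaminase_wt()
  seqs <- vapply(lib, function(ms) apply_variant(wt, ms), character(1))
  expect_identical(anyDuplicated(seqs), 0L)
  hamming <- vapply(seqs, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(wt, "")[[1]])
  }, integer(1))
  expect_identical(unname(hamming), unname(vapply(lib, nrow, integer(1))))
})

test_that("the bundled panel table reads with 13 labeled records", {
  path <- system.file("extdata", "transaminase_t50.csv", package = "ftsar")
  tbl <- read_variant_table(path)
  expect_s3_class(tbl, "activity_table")
  expect_identical(nrow(tbl), 13L)
  expect_true(all(tbl$labeled))
  expect_equal(tbl$activity[tbl$variant_id == "WT"], 6.9)
  expect_identical(tbl$mutations[tbl$variant_id == "P7"], "I77L_H210N")
  expect_equal(tbl$activity[tbl$variant_id == "P7"], 42.2)
  expect_equal(tbl$activity[tbl$variant_id == "P2"], 16.5)
  expect_identical(tbl$mutations[tbl$variant_id == "P2"], "Q97E")
  expect_true("activity_sd" %in% names(tbl))
  sets <- attr(tbl, "mutation_sets")
  expect_length(sets, 13L)
  expect_identical(nrow(sets$WT), 0L)
})

test_that("variant tables handle sniffed delimiters, blanks and errors", {
  # header only
  tmp <- withr::local_tempfile(lines = "variant_id,mutations,activity")
  expect_identical(nrow(read_variant_table(tmp)), 0L)

  # TSV sniffing + an unlabeled row
  tsv <- withr::local_tempfile(lines = c(
    "variant_id\tmutations\tactivity",
    "P2\tQ97E\t16.5",
    "NEW\tI77L_Q97E\t"
  ))
  tbl <- read_variant_table(tsv)
  expect_identical(tbl$labeled, c(TRUE, FALSE))
  expect_equal(tbl$activity, c(16.5, NA))
  expect_identical(tbl$mutations[2], "I77L_Q97E")

  # missing required column
  bad <- withr::local_tempfile(lines = c("variant_id,activity", "WT,5"))
  expect_error(read_variant_table(bad), "missing required column.*mutations")

  # unparseable activity names its row
  badact <- withr::local_tempfile(lines = c(
    "variant_id,mutations,activity", "WT,,6.9", "P1,I77L,fast"
  ))
  expect_error(read_variant_table(badact), "row 2.*'P1'.*'fast'")
})

test_that("variant tables and FASTA libraries round-trip through disk", {
  path <- system.file("extdata", "transaminase_t50.csv", package = "ftsar")
  tbl <- read_variant_table(path)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_variant_table(tbl, tmp)
  back <- read_variant_table(tmp)
  expect_identical(back$variant_id, tbl$variant_id)
  expect_identical(back$mutations, tbl$mutations)
  expect_equal(back$activity, tbl$activity)

  wt <- synthetic_transaminase_wt()
  lib <- enumerate_library(parse_variant_spec("I77L_H210N"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_library_fasta(wt, lib, fa)
  expect_identical(read_protein_fasta(fa), wt) # first record is WT
  expect_identical(read_protein_fasta(fa, id = "I77L_H210N"),
                   apply_variant(wt, parse_variant_spec("I77L_H210N")))
})
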