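test_that("substitution extraction handles matches, clips and deletions", {
  p <- extract_mismatches("100M", "100", "forward")
  expect_identical(p$cycle_positions, integer(0))
  expect_identical(p$aligned_bases, 100L)

  p <- extract_mismatches("100M", "10A89", "forward")
  expect_identical(p$cycle_positions, 10L)
  expect_identical(p$aligned_bases, 100L)

  p <- extract_mismatches("5S50M", "0A49", "forward", read_length = 55L)
  expect_identical(p$cycle_positions, 5L)
  expect_identical(p$aligned_bases, 50L)

  p <- extract_mismatches("20M2D30M", "20^AC30", "forward")
  expect_identical(p$cycle_positions, integer(0))
  expect_identical(p$aligned_bases, 50L)

  # reverse strand: stored position 10 sits at cycle 89
  p <- extract_mismatches("100M", "10A89", "reverse")
  expect_identical(p$cycle_positions, 89L)
})

test_that("inconsistent MD/CIGAR pairs are rejected", {
  expect_error(extract_mismatches("50M", "10A89", "forward"), "disagrees|past")
  expect_error(extract_mismatches("10M", "5A5", "forward"), "disagrees|past")
  expect_error(extract_mismatches("*", "10", "forward"), "unaligned")
  expect_error(parse_cigar("10Q"), "malformed")
})

test_that("N read bases are excluded from numerator and denominator", {
  # read has N at position 2; MD reports it as a mismatch against ref 'G'
  p <- extract_mismatches("4M", "2G1", "forward", seq = "ACNT")
  expect_identical(p$cycle_positions, integer(0))
  expect_identical(p$aligned_bases, 3L)
})

test_that("cycle conversion is strand-correct and involutive", {
  expect_identical(to_cycle_coordinate(0L, "forward", 100L), 0L)
  expect_identical(to_cycle_coordinate(0L, "reverse", 100L), 99L)
  expect_identical(to_cycle_coordinate(42L, "reverse", 151L), 108L)
  expect_error(to_cycle_coordinate(100L, "forward", 100L), "out of range")
  for (len in c(50L, 101L, 151L)) {
    pos <- 0:(len - 1L)
    twice <- to_cycle_coordinate(to_cycle_coordinate(pos, "reverse", len),
                                 "reverse", len)
    expect_identical(twice, pos)
  }
})

test_that("MD construction follows the calmd convention", {
  expect_identical(compute_md("ACGT", "ACGT", "4M"), "4")
  expect_identical(compute_md("ACGT", "AGGT", "4M"), "1G2")
  expect_identical(compute_md("ACGT", "ACTGT", "2M1D2M"), "2^T2")
  # adjacent events are separated by zero-length match runs
  expect_identical(compute_md("TTGT", "ACGT", "4M"), "0A0C2")
  expect_identical(compute_md("AC", "ACT", "2M1D"), "2^T0")
  expect_error(compute_md("ACGT", "ACG", "4M"), "disagrees")
})

test_that("MD route, comparison route and injected truth agree on random alignments", {
  cases <- random_alignments(300, seed = 5)
  agr <- parser_agreement(cases)
  expect_true(all(agr$cycles_equal))
  expect_true(all(agr$aligned_equal))
  expect_true(all(agr$truth_equal))
})

test_that("emitted MD tags match samtools calmd", {
  sim <- simulate_sample(sim_config(n_pairs = 150L, seed = 11L, sample_id = "cal"))
  dir <- tempfile()
  paths <- emit_sam(sim, dir)
  lines <- readLines(paths$sam)
  hdr <- grepl("^@", lines)
  body <- lines[!hdr]
  fields <- strsplit(body, "\t", fixed = TRUE)
  stripped <- vapply(fields, function(f) paste(f[1:11], collapse = "\t"), character(1))
  naked <- write_sam(c(lines[hdr], stripped))
  out <- system2("samtools", c("calmd", "-S", naked, paths$reference),
                 stdout = TRUE, stderr = FALSE)
  out_fields <- strsplit(out[!grepl("^@", out)], "\t", fixed = TRUE)
  md_of <- function(f) sub("^MD:Z:", "", grep("^MD:Z:", f, value = TRUE))
  expect_identical(vapply(out_fields, md_of, character(1)),
                   vapply(fields, md_of, character(1)))
})
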