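test_that("mismatch rate is substitutions over aligned bases", {
  prof <- structure(list(cycle_positions = c(3L, 7L), aligned_bases = 100L,
                         read_length = 100L), class = "mismatch_profile")
  expect_equal(mismatch_rate(prof), 0.02)
  prof$cycle_positions <- integer(0)
  expect_equal(mismatch_rate(prof), 0)
  prof$aligned_bases <- 0L
  expect_error(mismatch_rate(prof), "undefined")
})

test_that("mean Phred averages decoded scores", {
  expect_equal(mean_phred(rep(30L, 100L)), 30)
  expect_equal(mean_phred("??"), 30)        # '?' is ASCII 63, offset 33
  expect_equal(mean_phred(c(20L, 40L)), 30)
  expect_error(mean_phred(integer(0)), "undefined")
})

test_that("low-quality classification uses strict inequalities", {
  spec <- stratum_spec()
  expect_true(classify_read(0.02, 35, spec)$lq_by_mismatch)
  expect_false(classify_read(0.01, 35, spec)$lq_by_mismatch)   # exactly at cutoff
  expect_true(classify_read(0.0101, 35, spec)$lq_by_mismatch)
  expect_true(classify_read(0, 29.9, spec)$lq_by_phred)
  expect_false(classify_read(0, 30, spec)$lq_by_phred)          # exactly at cutoff
  expect_true(is.na(classify_read(0, NA, spec)$lq_by_phred))
})

test_that("positional profile counts per-cycle substitutions over coverage", {
  spec <- stratum_spec(min_cycle_coverage = 1L)
  reads <- manual_reads(frag_len = rep(300L, 5L), lq_r1 = rep(0, 5), lq_r2 = rep(0, 5))
  reads$read_length <- 10L
  reads$aligned_bases <- 10L
  reads$cigar <- "10M"
  reads$md <- "10"
  prof <- positional_profile(reads, "R1", "short", spec)
  expect_identical(nrow(prof), 10L)
  expect_true(all(prof$rate == 0))
  expect_true(all(prof$coverage == 5L))

  # one substitution at cycle 5 of one R1 read
  reads$cycles[[1]] <- 5L
  prof <- positional_profile(reads, "R1", "short", spec)
  expect_equal(prof$rate[prof$cycle == 5L], 0.2)
  expect_true(all(prof$rate[prof$cycle != 5L] == 0))

  # reverse-strand record whose stored position maps to the same cycle
  rev_prof <- extract_mismatches("10M", "4A5", "reverse")  # stored 4 -> cycle 5
  reads$cycles[[6L + 0L]] <- rev_prof$cycle_positions      # an R2 read
  prof2 <- positional_profile(reads, "R2", "short", spec)
  expect_equal(prof2$rate[prof2$cycle == 5L], 0.2)
})

test_that("per-cycle rates are masked below the coverage minimum", {
  spec <- stratum_spec(min_cycle_coverage = 10L)
  reads <- manual_reads(frag_len = rep(300L, 3L), lq_r1 = rep(0, 3), lq_r2 = rep(0, 3))
  prof <- positional_profile(reads, "R1", "short", spec)
  expect_true(all(is.na(prof$rate)))
  expect_true(all(prof$coverage == 3L))
})

test_that("profile mass is conserved and rates are strand-invariant", {
  sim <- simulate_sample(sim_config(n_pairs = 400L, seed = 21L, sample_id = "cons"))
  spec <- stratum_spec(min_cycle_coverage = 1L)
  reads <- read_quality_table(sim$records, spec)
  for (mate in c("R1", "R2")) {
    for (win in c("short", "long")) {
      prof <- positional_profile(reads, mate, win, spec)
      sel <- reads$mate == mate & !is.na(reads$fragment_length) &
        reads$fragment_length >= spec[[paste0(win, "_window")]][1] &
        reads$fragment_length <= spec[[paste0(win, "_window")]][2]
      expect_equal(sum(prof$rate * prof$coverage), sum(reads$n_mismatch[sel]))
    }
  }
  # strand flips positions, never counts
  by_strand <- split(reads$n_mismatch, reads$strand)
  expect_identical(sum(reads$n_mismatch),
                   sum(by_strand$forward) + sum(by_strand$reverse))
  rev_reads <- reads[reads$strand == "reverse", ]
  expect_identical(rev_reads$n_mismatch, lengths(rev_reads$cycles))
})

test_that("constant per-cycle error is recovered within 4 binomial SEs at every cycle", {
  model <- error_model(r1_base = 0.01, r1_cycle_slope = 0,
                       r2_base = 0.01, r2_cycle_slope = 0, r2_long_effect = 0)
  frag <- fragment_dist(p_long = 0)
  cfg <- sim_config(n_pairs = 2000L, seed = 31L, sample_id = "flat",
                    model = model, frag = frag)
  spec <- stratum_spec(min_cycle_coverage = 500L)
  reads <- read_quality_table(simulate_sample(cfg)$records, spec)
  eps <- 0.01
  for (mate in c("R1", "R2")) {
    prof <- positional_profile(reads, mate, "short", spec)
    unmasked <- !is.na(prof$rate)
    expect_true(any(unmasked))
    se <- sqrt(eps * (1 - eps) / prof$coverage[unmasked])
    expect_true(all(abs(prof$rate[unmasked] - eps) <= 4 * se))
  }
})
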