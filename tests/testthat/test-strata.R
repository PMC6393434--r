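test_that("fragment length is |TLEN| within the accepted insert range", {
  spec <- stratum_spec()
  expect_identical(fragment_length(-450L, spec), 450L)
  expect_identical(fragment_length(0L, spec), NA_integer_)
  expect_identical(fragment_length(1200L, spec), NA_integer_)
  expect_identical(fragment_length(1000L, spec), 1000L)
  expect_identical(fragment_length(c(100L, -100L, 0L), spec), c(100L, 100L, NA))
})

test_that("strata are half-open and 'long' is strictly above the cutoff", {
  spec <- stratum_spec()
  st <- assign_stratum(c(350L, 400L, 500L, 501L, 999L), spec)
  expect_identical(as.character(st$stratum),
                   c("[300,400)", "[400,500)", "[500,600)", "[500,600)", "[900,1000)"))
  expect_identical(st$is_long, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  over <- assign_stratum(1500L, stratum_spec(max_insert = 2000L))
  expect_identical(as.character(over$stratum), "overflow")
})

test_that("sample summary reproduces a hand count", {
  # 10 pairs, 3 long (>500), 2 R2 reads low quality, 0 R1 reads low quality
  frag <- c(300L, 350L, 400L, 450L, 320L, 380L, 280L, 600L, 700L, 800L)
  s <- summarize_sample(manual_reads(frag,
                                     lq_r1 = rep(0, 10),
                                     lq_r2 = c(1, 1, rep(0, 8))))
  expect_identical(s$n_pairs, 10L)
  expect_equal(s$frac_long, 0.3)
  expect_equal(s$frac_lq_r1, 0)
  expect_equal(s$frac_lq_r2, 0.2)
  expect_equal(s$lq_diff, 0.2)

  all_lq <- summarize_sample(manual_reads(frag, rep(1, 10), rep(1, 10)))
  expect_equal(all_lq$frac_lq_r1, 1)
  expect_equal(all_lq$frac_lq_r2, 1)
  expect_equal(all_lq$lq_diff, 0)

  empty <- manual_reads(frag, rep(0, 10), rep(0, 10))
  empty$fragment_length <- NA_integer_
  expect_error(summarize_sample(empty), "empty sample")
})

test_that("stratum table conserves read counts and masks thin cells", {
  frag <- rep(c(250L, 350L, 650L), times = c(60L, 60L, 30L))
  reads <- manual_reads(frag, lq_r1 = rep(0, 150), lq_r2 = rep(0, 150))
  spec <- stratum_spec(min_stratum_reads = 50L)
  st <- stratum_table(reads, spec)
  for (m in c("R1", "R2")) {
    expect_identical(sum(st$n_reads[st$mate == m]), 150L)
  }
  r2 <- st[st$mate == "R2", ]
  expect_true(all(is.na(r2$frac_lq[r2$n_reads < 50L])))
  expect_true(all(!is.na(r2$frac_lq[r2$n_reads >= 50L])))
})

test_that("stratum matrix rows aggregate back to the per-sample LQ fraction", {
  sims <- simulate_study(p_long = c(0.1, 0.3, 0.5),
                         config = sim_config(n_pairs = 800L), seed = 17L)
  spec <- stratum_spec(min_stratum_reads = 1L)
  strata <- dplyr::bind_rows(lapply(sims, function(s) {
    stratum_table(read_quality_table(s$records, spec), spec)
  }))
  summaries <- dplyr::bind_rows(lapply(sims, function(s) {
    summarize_sample(read_quality_table(s$records, spec), spec)
  }))
  m <- stratum_matrix(strata, "R2")
  expect_identical(dim(m), c(3L, 10L))
  counts <- stratum_matrix(dplyr::mutate(strata, frac_lq = .data$n_reads), "R2")
  agg <- rowSums(m * counts, na.rm = TRUE) / rowSums(counts, na.rm = TRUE)
  expect_equal(unname(agg[summaries$sample_id]), summaries$frac_lq_r2)
})

test_that("R2 low-quality fractions jump above the long-fragment cutoff", {
  sim <- simulate_sample(sim_config(n_pairs = 4000L, seed = 23L, sample_id = "jump"))
  st <- stratum_table(read_quality_table(sim$records), stratum_spec())
  r2 <- st[st$mate == "R2", ]
  low <- r2$frac_lq[as.character(r2$stratum) == "[200,300)"]
  for (s in c("[500,600)", "[600,700)", "[700,800)")) {
    high <- r2$frac_lq[as.character(r2$stratum) == s]
    if (!is.na(high)) expect_gt(high, low)
  }
})

test_that("without a fragment-length effect the R2 stratum profile is flat", {
  cfg <- sim_config(n_pairs = 4000L, seed = 29L, sample_id = "null",
                    model = error_model(r2_long_effect = 0))
  sim <- simulate_sample(cfg)
  st <- stratum_table(read_quality_table(sim$records), stratum_spec())
  r2 <- st[st$mate == "R2" & !is.na(st$frac_lq), ]
  overall <- sum(r2$n_lq) / sum(r2$n_reads)
  se <- sqrt(pmax(overall * (1 - overall), 1e-12) / r2$n_reads)
  expect_true(all(abs(r2$frac_lq - overall) <= 4 * se))
})
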