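test_that("reference generation is seeded and compositionally uniform", {
  a <- generate_reference(1000L, seed = 4L)
  b <- generate_reference(1000L, seed = 4L)
  expect_identical(a, b)
  expect_identical(nchar(a), 1000L)
  expect_true(all(strsplit(a, "")[[1]] %in% c("A", "C", "G", "T")))
  big <- generate_reference(100000L, seed = 8L)
  gc <- lengths(regmatches(big, gregexpr("[GC]", big))) / 100000
  expect_lt(abs(gc - 0.5), 4 * sqrt(0.25 / 100000))
  expect_error(generate_reference(0L, 1L), "positive")
})

test_that("fragment draws respect the mixture and truncation", {
  set.seed(1)
  short_only <- draw_fragments(500L, fragment_dist(p_long = 0), 10000L, 100L)
  expect_true(all(short_only$length >= 100L & short_only$length <= 1000L))
  expect_lt(max(short_only$length), 550L)   # short component only
  set.seed(1)
  long_only <- draw_fragments(500L, fragment_dist(p_long = 1), 10000L, 100L)
  expect_gt(min(long_only$length), 350L)    # long component only

  set.seed(2)
  frag <- fragment_dist(p_long = 0.3)
  draws <- draw_fragments(10000L, frag, 50000L, 100L)
  implied <- expected_frac_long(frag, 500L, 100L)
  se <- sqrt(implied * (1 - implied) / 10000)
  expect_lt(abs(mean(draws$length > 500L) - implied), 4 * se)
  expect_true(all(draws$start >= 1L &
                    draws$start + draws$length - 1L <= 50000L))

  expect_error(draw_fragments(10L, fragment_dist(max_insert = 150L), 1000L, 200L),
               "infeasible")
})

test_that("a zero-error model reproduces the reference exactly", {
  model <- error_model(r1_base = 0, r1_cycle_slope = 0, r2_base = 0,
                       r2_cycle_slope = 0, r2_long_effect = 0)
  cfg <- sim_config(n_pairs = 50L, seed = 13L, sample_id = "clean", model = model)
  sim <- simulate_sample(cfg)
  expect_true(all(sim$records$md == "100"))
  expect_true(all(lengths(sim$truth$substitution_cycles) == 0L))
  slices <- substring(sim$reference, sim$records$pos, sim$records$pos + 99L)
  expect_identical(sim$records$seq, slices)
})

test_that("substitution counts follow the configured error probability", {
  model <- error_model(r1_base = 0.01, r1_cycle_slope = 0, r2_base = 0.01,
                       r2_cycle_slope = 0, r2_long_effect = 0)
  cfg <- sim_config(n_pairs = 500L, seed = 19L, sample_id = "binom", model = model)
  sim <- simulate_sample(cfg)
  n_bases <- 2L * 500L * 100L
  total <- sum(lengths(sim$truth$substitution_cycles))
  expect_lt(abs(total - n_bases * 0.01), 4 * sqrt(n_bases * 0.01 * 0.99))

  # probabilities above the 0.75 ceiling are rejected
  bad <- sim_config(model = error_model(r2_base = 0.8))
  expect_error(simulate_sample(bad), "0.75")
})

test_that("Phred scores are set truthfully from the error model", {
  model <- error_model(r1_base = 0.01, r1_cycle_slope = 0, r2_base = 0.01,
                       r2_cycle_slope = 0, r2_long_effect = 0)
  cfg <- sim_config(n_pairs = 20L, seed = 3L, sample_id = "q", model = model)
  sim <- simulate_sample(cfg)
  # eps = 0.01 at every cycle -> Q20 everywhere
  expect_true(all(sim$records$qual == strrep("5", 100L)))
  reads <- read_quality_table(sim$records)
  expect_true(all(reads$mean_phred == 20))
})

test_that("emitted SAM round-trips through ingest with nothing filtered", {
  cfg <- sim_config(n_pairs = 300L, seed = 37L, sample_id = "rt")
  sim <- simulate_sample(cfg)
  dir <- tempfile()
  paths <- emit_sam(sim, dir)
  aln <- load_alignments(paths$sam)
  log <- filter_log(aln)
  expect_identical(log$count[log$record_class == "passed"], 600L)
  expect_identical(sum(log$count), 600L)

  reads <- read_quality_table(aln)
  key <- paste(reads$qname, reads$mate)
  tkey <- paste(sim$truth$qname, sim$truth$mate)
  m <- match(key, tkey)
  expect_false(anyNA(m))
  expect_identical(as.integer(reads$fragment_length),
                   as.integer(sim$truth$fragment_length[m]))
  same <- mapply(function(a, b) identical(as.integer(a), as.integer(b)),
                 reads$cycles, sim$truth$substitution_cycles[m])
  expect_true(all(same))
  # both FR flag orientations occur
  expect_setequal(unique(paste(aln$mate, aln$strand)),
                  c("R1 forward", "R1 reverse", "R2 forward", "R2 reverse"))
})

test_that("identical seeds give byte-identical outputs", {
  cfg <- sim_config(n_pairs = 200L, seed = 41L, sample_id = "det")
  d1 <- tempfile(); d2 <- tempfile()
  emit_sam(simulate_sample(cfg), d1)
  emit_sam(simulate_sample(cfg), d2)
  for (f in c("det.sam", "det.truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("study simulation produces independent, reproducible samples", {
  sims <- simulate_study(p_long = c(0.1, 0.3, 0.5),
                         config = sim_config(n_pairs = 100L), seed = 5L)
  expect_identical(length(sims), 3L)
  expect_identical(names(sims), c("sample01", "sample02", "sample03"))
  for (s in sims) expect_identical(nrow(s$truth), 200L)
  expect_identical(sims[[1]]$reference, sims[[2]]$reference)
  sims2 <- simulate_study(p_long = c(0.1, 0.3, 0.5),
                          config = sim_config(n_pairs = 100L), seed = 5L)
  expect_identical(sims[[2]]$records$seq, sims2[[2]]$records$seq)
  expect_error(simulate_study(p_long = c(0.1, 0.2)), "at least 3")
})
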