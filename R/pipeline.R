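#' Profile one sample end to end
#'
#' Convenience wrapper chaining ingest (or a simulated sample's records),
#' per-read quality, the per-sample summary, the stratum table and the four
#' positional profiles (R1/R2 crossed with the short and long windows).
#'
#' @param x A SAM/BAM path, an alignment tibble from [load_alignments()], or
#'   a `fraglenqc_sim`.
#' @param spec A [stratum_spec()].
#' @param ... Passed to [load_alignments()] when `x` is a path.
#' @return List with `reads`, `summary`, `strata`, `profiles` (tibble binding
#'   the four positional profiles), and `filter_log` (when available).
#' @export
profile_sample <- function(x, spec = stratum_spec(), ...) {
  log <- NULL
  if (inherits(x, "fraglenqc_sim")) {
    aln <- x$records
  } else if (is.character(x)) {
    aln <- load_alignments(x, ...)
    log <- filter_log(aln)
  } else {
    aln <- x
    log <- attr(x, "filter_log")
  }
  reads <- read_quality_table(aln, spec)
  profiles <- dplyr::bind_rows(
    positional_profile(reads, "R1", "short", spec),
    positional_profile(reads, "R1", "long", spec),
    positional_profile(reads, "R2", "short", spec),
    positional_profile(reads, "R2", "long", spec)
  )
  list(
    reads = reads,
    summary = summarize_sample(reads, spec),
    strata = stratum_table(reads, spec),
    profiles = profiles,
    filter_log = log
  )
}

#' Run the profiling stage over a set of alignment files
#'
#' One sample per input file. Writes `summary.tsv` (per-sample low-quality
#' and long-fragment fractions), `strata.tsv` (long-format stratum table),
#' `profiles.tsv` (positional mismatch profiles), `filter_log.tsv` and a JSON
#' run manifest echoing thresholds and filter counts.
#'
#' @param inputs Character vector of SAM/BAM paths (at least one).
#' @param out_dir Output directory, created if needed.
#' @param spec A [stratum_spec()].
#' @param sample_ids Optional labels, default file names without extension.
#' @return Invisibly, a list with `summaries`, `strata`, `profiles`,
#'   `filter_logs` tibbles and the manifest path.
#' @export
run_profile <- function(inputs, out_dir, spec = stratum_spec(),
                        sample_ids = NULL) {
  if (length(inputs) < 1L) stop("need at least one input file")
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) stop("input not found: ", paste(missing, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.(sam|bam)$", "", basename(inputs), ignore.case = TRUE)
  }

  summaries <- list(); strata <- list(); profiles <- list(); logs <- list()
  for (i in seq_along(inputs)) {
    aln <- load_alignments(inputs[i], sample_id = sample_ids[i])
    if (nrow(aln) == 0L) {
      stop("sample '", sample_ids[i], "' has no records after filtering")
    }
    res <- profile_sample(aln, spec)
    summaries[[i]] <- res$summary
    strata[[i]] <- res$strata
    profiles[[i]] <- dplyr::mutate(res$profiles, sample_id = sample_ids[i],
                                   .before = 1L)
    logs[[i]] <- dplyr::mutate(res$filter_log, sample_id = sample_ids[i],
                               .before = 1L)
  }
  summaries <- dplyr::bind_rows(summaries)
  strata <- dplyr::bind_rows(strata)
  profiles <- dplyr::bind_rows(profiles)
  logs <- dplyr::bind_rows(logs)

  readr::write_tsv(summaries, file.path(out_dir, "summary.tsv"))
  readr::write_tsv(strata, file.path(out_dir, "strata.tsv"))
  readr::write_tsv(profiles, file.path(out_dir, "profiles.tsv"))
  readr::write_tsv(logs, file.path(out_dir, "filter_log.tsv"))

  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    tool = "fraglenqc",
    version = as.character(utils::packageVersion("fraglenqc")),
    stage = "profile",
    inputs = inputs,
    sample_ids = sample_ids,
    thresholds = list(
      mismatch_cutoff = spec$mismatch_cutoff,
      phred_cutoff = spec$phred_cutoff,
      long_cutoff = spec$long_cutoff,
      min_insert = spec$min_insert,
      max_insert = spec$max_insert,
      bin_edges = spec$bin_edges,
      short_window = spec$short_window,
      long_window = spec$long_window,
      min_stratum_reads = spec$min_stratum_reads,
      min_cycle_coverage = spec$min_cycle_coverage
    ),
    filter_counts = logs
  ), manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(summaries = summaries, strata = strata, profiles = profiles,
                 filter_logs = logs, manifest = manifest))
}

#' Run the cross-sample correlation stage
#'
#' @param summary Path to a `summary.tsv` written by [run_profile()], or the
#'   summaries tibble itself (at least 3 rows).
#' @param out Optional output TSV path for the three-row correlation table.
#' @param alpha Significance level (default 0.05).
#' @return The correlation table tibble (columns `comparison`, `rho`,
#'   `p_value`, `n`, `significant`).
#' @export
run_correlate <- function(summary, out = NULL, alpha = 0.05) {
  if (is.character(summary)) {
    summary <- readr::read_tsv(summary, show_col_types = FALSE)
  }
  tab <- correlation_table(summary, alpha = alpha)
  if (!is.null(out)) readr::write_tsv(tab, out)
  tab
}

#' Run the simulation stage
#'
#' Simulates a multi-sample study and writes one SAM and one truth TSV per
#' sample plus a JSON manifest with the full parameter set and seed.
#'
#' @param out_dir Output directory.
#' @param p_long Long-fragment mixing weight per sample (at least 3 values).
#' @param config A [sim_config()] template.
#' @param seed Master seed.
#' @return Invisibly, the list of simulated samples.
#' @export
run_simulate <- function(out_dir, p_long = seq(0.05, 0.6, length.out = 10),
                         config = sim_config(), seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sims <- simulate_study(p_long, config = config, seed = seed, dir = out_dir)
  jsonlite::write_json(list(
    tool = "fraglenqc",
    version = as.character(utils::packageVersion("fraglenqc")),
    stage = "simulate",
    seed = seed,
    p_long = p_long,
    genome_length = config$genome_length,
    read_length = config$read_length,
    n_pairs = config$n_pairs,
    model = unclass(config$model),
    frag = unclass(config$frag)
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
  digits = NA)
  invisible(sims)
}
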