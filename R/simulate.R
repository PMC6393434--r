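#' Substitution error model for simulated paired-end reads
#'
#' Parametric per-base substitution model in which the first read's error
#' probability depends on sequencing cycle only, while the second read's
#' additionally depends on fragment length:
#' \deqn{\epsilon_{R1}(c) = b_1 + s_1 c}
#' \deqn{\epsilon_{R2}(c, L) = b_2 + s_2 c + e(L)}
#' with cycle `c` counted from 0. The fragment-length term `e(L)` is either a
#' step (`r2_long_effect` added when `L` is strictly above `effect_cutoff`) or
#' a linear ramp rising from 0 at `effect_cutoff` to `r2_long_effect` at
#' `effect_cutoff + effect_scale`.
#'
#' @param r1_base,r2_base Baseline per-base substitution probabilities.
#' @param r1_cycle_slope,r2_cycle_slope Added probability per cycle.
#' @param r2_long_effect Added R2 probability for long fragments.
#' @param effect_cutoff Fragment length (bases) above which the R2 effect
#'   applies.
#' @param effect_form `"step"` (default) or `"linear"`.
#' @param effect_scale Ramp width in bases for the linear form.
#' @return An object of class `error_model`.
#' @export
error_model <- function(r1_base = 0.002, r1_cycle_slope = 2e-5,
                        r2_base = 0.003, r2_cycle_slope = 3e-5,
                        r2_long_effect = 0.015, effect_cutoff = 500L,
                        effect_form = c("step", "linear"),
                        effect_scale = 500L) {
  effect_form <- match.arg(effect_form)
  vals <- c(r1_base, r1_cycle_slope, r2_base, r2_cycle_slope, r2_long_effect)
  if (any(vals < 0)) stop("error-model parameters must be non-negative")
  structure(list(
    r1_base = r1_base, r1_cycle_slope = r1_cycle_slope,
    r2_base = r2_base, r2_cycle_slope = r2_cycle_slope,
    r2_long_effect = r2_long_effect,
    effect_cutoff = as.integer(effect_cutoff),
    effect_form = effect_form,
    effect_scale = as.integer(effect_scale)
  ), class = "error_model")
}

#' Fragment-length distribution: two-component truncated normal mixture
#'
#' Emulates a library with a short fragment mode and a variable admixture of
#' long fragments; varying `p_long` across simulated samples reproduces the
#' between-library spread of long-fragment content.
#'
#' @param short_mean,short_sd Mean and SD of the short component (bases).
#' @param long_mean,long_sd Mean and SD of the long component.
#' @param p_long Mixing weight of the long component in `[0, 1]`.
#' @param min_insert,max_insert Truncation bounds; drawn lengths are also
#'   forced to be at least the read length so both mates fit on the fragment.
#' @return An object of class `fragment_dist`.
#' @export
fragment_dist <- function(short_mean = 300, short_sd = 50,
                          long_mean = 700, long_sd = 100,
                          p_long = 0.3, min_insert = 1L, max_insert = 1000L) {
  if (p_long < 0 || p_long > 1) stop("p_long must be in [0, 1]")
  if (short_sd <= 0 || long_sd <= 0) stop("component SDs must be positive")
  structure(list(
    short_mean = short_mean, short_sd = short_sd,
    long_mean = long_mean, long_sd = long_sd,
    p_long = p_long,
    min_insert = as.integer(min_insert),
    max_insert = as.integer(max_insert)
  ), class = "fragment_dist")
}

#' Expected fraction of long fragments under a fragment_dist
#'
#' Mixture-implied probability that a drawn length exceeds `cutoff`, from the
#' truncated-normal component CDFs.
#'
#' @param frag A [fragment_dist()].
#' @param cutoff Length threshold (default 500).
#' @param read_length Lower truncation applied at draw time.
#' @return Probability in `[0, 1]`.
#' @export
expected_frac_long <- function(frag, cutoff = 500L, read_length = 0L) {
  lo <- max(frag$min_insert, read_length)
  hi <- frag$max_insert
  trunc_tail <- function(mean, sd) {
    denom <- stats::pnorm(hi + 0.5, mean, sd) - stats::pnorm(lo - 0.5, mean, sd)
    num <- stats::pnorm(hi + 0.5, mean, sd) -
      stats::pnorm(max(cutoff + 0.5, lo - 0.5), mean, sd)
    if (denom <= 0) return(0)
    max(0, num / denom)
  }
  (1 - frag$p_long) * trunc_tail(frag$short_mean, frag$short_sd) +
    frag$p_long * trunc_tail(frag$long_mean, frag$long_sd)
}

#' Simulation configuration for one sample
#'
#' @param genome_length Reference length in bases.
#' @param read_length Read length in bases (both mates).
#' @param n_pairs Number of read pairs.
#' @param seed Integer seed; fully determines the sample.
#' @param sample_id Sample label.
#' @param model An [error_model()].
#' @param frag A [fragment_dist()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L, read_length = 100L,
                       n_pairs = 5000L, seed = 1L, sample_id = "sample1",
                       model = error_model(), frag = fragment_dist()) {
  if (read_length > min(frag$max_insert, genome_length)) {
    stop("read_length exceeds the largest allowed fragment")
  }
  if (genome_length <= frag$max_insert) {
    stop("genome_length must exceed the largest fragment length")
  }
  structure(list(
    genome_length = as.integer(genome_length),
    read_length = as.integer(read_length),
    n_pairs = as.integer(n_pairs),
    seed = as.integer(seed),
    sample_id = sample_id,
    model = model,
    frag = frag
  ), class = "sim_config")
}

# deterministic substream seed derivation (kept below 2^31)
derive_seed <- function(seed, i) {
  as.integer(((as.double(seed) %% 2147483647) * 48271 + i * 1299721) %% 2147483647)
}

#' Generate a uniform random reference sequence
#'
#' @param length Sequence length in bases.
#' @param seed Integer seed.
#' @return A single character string over `ACGT`.
#' @export
generate_reference <- function(length, seed) {
  if (length <= 0) stop("length must be positive")
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Draw fragment start positions and lengths
#'
#' Lengths come from the truncated two-component normal mixture (component
#' choice Bernoulli(`p_long`), values rounded to integer bases and redrawn
#' until they fall inside `[max(min_insert, read_length), max_insert]`);
#' starts are uniform over positions where the fragment fits on the
#' reference. Uses the current RNG state.
#'
#' @param n Number of fragments.
#' @param frag A [fragment_dist()].
#' @param genome_length Reference length.
#' @param read_length Minimum usable fragment length.
#' @return Tibble with integer columns `start` (1-based) and `length`.
#' @export
draw_fragments <- function(n, frag, genome_length, read_length = 0L) {
  lo <- max(frag$min_insert, read_length)
  hi <- min(frag$max_insert, genome_length)
  if (lo > hi) stop("infeasible truncation: no fragment length satisfies the bounds")

  is_long <- stats::runif(n) < frag$p_long
  mean_v <- ifelse(is_long, frag$long_mean, frag$short_mean)
  sd_v <- ifelse(is_long, frag$long_sd, frag$short_sd)
  len <- as.integer(round(stats::rnorm(n, mean_v, sd_v)))
  tries <- 0L
  redo <- which(len < lo | len > hi)
  while (length(redo)) {
    tries <- tries + 1L
    if (tries > 1000L) stop("infeasible truncation: rejection sampling failed")
    len[redo] <- as.integer(round(stats::rnorm(length(redo), mean_v[redo], sd_v[redo])))
    redo <- redo[len[redo] < lo | len[redo] > hi]
  }
  start <- as.integer(floor(stats::runif(n) * (genome_length - len + 1L))) + 1L
  tibble::tibble(start = start, length = len)
}

# per-base substitution probabilities: n_reads x read_length matrix
epsilon_matrix <- function(model, mate, read_length, frag_len) {
  cycles <- 0:(read_length - 1L)
  if (mate == "R1") {
    row <- model$r1_base + model$r1_cycle_slope * cycles
    eps <- matrix(row, nrow = length(frag_len), ncol = read_length, byrow = TRUE)
  } else {
    row <- model$r2_base + model$r2_cycle_slope * cycles
    eff <- fragment_effect(model, frag_len)
    eps <- outer(eff, row, `+`)
  }
  if (any(eps > 0.75)) stop("per-base substitution probability exceeds 0.75")
  eps
}

# the R2 fragment-length error term e(L)
fragment_effect <- function(model, frag_len) {
  if (model$effect_form == "step") {
    model$r2_long_effect * (frag_len > model$effect_cutoff)
  } else {
    model$r2_long_effect *
      pmin(1, pmax(0, (frag_len - model$effect_cutoff) / model$effect_scale))
  }
}

# QUAL string for one eps vector in cycle order (Phred set truthfully from eps)
qual_from_eps <- function(eps) {
  q <- round(-10 * log10(pmax(eps, 1e-12)))
  q <- pmin(41L, pmax(2L, as.integer(q)))
  intToUtf8(q + 33L)
}

reverse_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

# Vectorized core: simulate both mates of every pair. Uses current RNG state.
# Returns list(records = tibble, truth = tibble).
simulate_reads <- function(config, reference, fragments, r1_forward) {
  n <- nrow(fragments)
  rl <- config$read_length
  model <- config$model
  fl <- fragments$length
  start <- fragments$start
  bases <- c("A", "C", "G", "T")

  mate_records <- vector("list", 2L)
  mate_truth <- vector("list", 2L)

  for (m in 1:2) {
    mate <- c("R1", "R2")[m]
    fwd <- if (mate == "R1") r1_forward else !r1_forward
    # leftmost mate is the forward one: forward mate at fragment start,
    # reverse mate ends at the fragment end
    pos <- ifelse(fwd, start, start + fl - rl)
    tlen <- ifelse(fwd, fl, -fl)

    eps <- epsilon_matrix(model, mate, rl, fl)
    u <- matrix(stats::runif(n * rl), nrow = n)
    err <- which(u < eps, arr.ind = TRUE)
    read_idx <- as.integer(err[, 1L])
    cycle <- as.integer(err[, 2L]) - 1L

    # stored-orientation position of each substituted cycle: SAM stores
    # reverse-strand reads reverse-complemented, and complementing a uniform
    # substitute keeps it uniform, so errors are injected in stored space
    stored <- ifelse(fwd[read_idx], cycle, rl - 1L - cycle)

    seqs <- substring(reference, pos, pos + rl - 1L)
    ref_base <- substring(seqs[read_idx], stored + 1L, stored + 1L)
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 4L, byrow = TRUE)  # alternatives per original base
    new_base <- alt[cbind(match(ref_base, bases),
                          sample.int(3L, length(ref_base), replace = TRUE))]

    # apply substitutions round by round (a read can carry several)
    ord <- order(read_idx, stored)
    ri <- read_idx[ord]; sp <- stored[ord]; nb <- new_base[ord]
    while (length(ri)) {
      first <- !duplicated(ri)
      ii <- ri[first]
      x <- seqs[ii]
      substr(x, sp[first] + 1L, sp[first] + 1L) <- nb[first]
      seqs[ii] <- x
      ri <- ri[!first]; sp <- sp[!first]; nb <- nb[!first]
    }

    # MD tags from the substituted stored positions and reference bases
    md <- rep(as.character(rl), n)
    if (length(read_idx)) {
      by_read <- split(seq_along(read_idx), read_idx)
      md_new <- vapply(by_read, function(j) {
        md_from_positions(rl, stored[j], ref_base[j])
      }, character(1))
      md[as.integer(names(by_read))] <- md_new
    }

    # truthful QUAL from eps, cached per distinct eps row (mate x effect)
    eff_key <- if (mate == "R1") rep(0, n) else fragment_effect(model, fl)
    qual <- character(n)
    for (e in unique(eff_key)) {
      sel <- eff_key == e
      row <- eps[which(sel)[1L], ]
      qf <- qual_from_eps(row)
      qual[sel & fwd] <- qf
      if (any(sel & !fwd)) qual[sel & !fwd] <- reverse_string(qf)
    }

    cyc_truth <- vector("list", n)
    cyc_truth[] <- list(integer(0))
    if (length(read_idx)) {
      by_read <- split(cycle, read_idx)
      cyc_truth[as.integer(names(by_read))] <- lapply(by_read, sort)
    }

    qname <- sprintf("%s_p%06d", config$sample_id, seq_len(n))
    mate_records[[m]] <- tibble::tibble(
      sample_id = config$sample_id,
      qname = qname,
      mate = mate,
      strand = ifelse(fwd, "forward", "reverse"),
      pos = as.integer(pos),
      cigar = paste0(rl, "M"),
      tlen = as.integer(tlen),
      md = md,
      seq = seqs,
      qual = qual,
      read_length = rl
    )
    mate_truth[[m]] <- tibble::tibble(
      qname = qname,
      mate = mate,
      fragment_length = fl,
      substitution_cycles = cyc_truth
    )
  }

  # interleave R1/R2 per pair, as an aligner emits name-adjacent pairs
  ix <- rep(seq_len(n), each = 2L)
  off <- rep(c(0L, n), times = n)
  records <- dplyr::bind_rows(mate_records)[ix + off, ]
  truth <- dplyr::bind_rows(mate_truth)[ix + off, ]
  list(records = records, truth = truth)
}

#' Simulate one paired-end sample
#'
#' Generates (or reuses) a reference, draws fragments, simulates both reads
#' of every pair under the error model, and returns alignment records in the
#' same shape as [load_alignments()] output together with a truth table of
#' injected substitution cycles. R1 reads the fragment's 5' end and R2 the
#' reverse complement of its 3' end; the fragment itself sits on either
#' reference strand with equal probability, so FLAG pairs 99/147 and 83/163
#' both occur. Per-base Phred scores are set truthfully from the model's
#' error probability (`round(-10 log10 eps)`, capped to `[2, 41]`).
#'
#' @param config A [sim_config()].
#' @param reference Optional reference string shared across samples; by
#'   default one is generated from the config seed.
#' @return A list of class `fraglenqc_sim` with elements `records` (tibble),
#'   `truth` (tibble: `qname`, `mate`, `fragment_length`,
#'   `substitution_cycles` list column), `reference`, `config`.
#' @export
simulate_sample <- function(config, reference = NULL) {
  if (is.null(reference)) {
    reference <- generate_reference(config$genome_length, derive_seed(config$seed, 0L))
  } else if (nchar(reference) != config$genome_length) {
    stop("reference length disagrees with config$genome_length")
  }
  set.seed(derive_seed(config$seed, 1L))
  fragments <- draw_fragments(config$n_pairs, config$frag,
                              config$genome_length, config$read_length)
  r1_forward <- stats::runif(config$n_pairs) < 0.5
  sim <- simulate_reads(config, reference, fragments, r1_forward)
  structure(list(records = sim$records, truth = sim$truth,
                 reference = reference, config = config),
            class = "fraglenqc_sim")
}

#' Simulate one read pair
#'
#' Scalar convenience wrapper around the vectorized pair simulator; uses the
#' current RNG state.
#'
#' @param start 1-based fragment start on the reference.
#' @param length Fragment length in bases.
#' @param reference Reference string.
#' @param model An [error_model()].
#' @param read_length Read length.
#' @param r1_forward Does R1 sit on the forward strand (default `TRUE`)?
#' @param sample_id Label used in the query name.
#' @return List with `records` (2-row tibble) and `truth` (2-row tibble).
#' @export
simulate_pair <- function(start, length, reference, model, read_length,
                          r1_forward = TRUE, sample_id = "pair") {
  config <- list(read_length = as.integer(read_length), model = model,
                 sample_id = sample_id)
  simulate_reads(config, reference,
                 tibble::tibble(start = as.integer(start), length = as.integer(length)),
                 r1_forward)
}

#' Write a simulated sample as SAM + truth TSV (+ reference FASTA)
#'
#' Emits a spec-conformant single-reference SAM file: FLAG pairs 99/147 or
#' 83/163, `PNEXT`/`RNEXT` consistent, signed TLEN, all-M CIGAR, MD and NM
#' tags, and the truthful QUAL strings. Loading the file back with
#' [load_alignments()] yields every record with nothing filtered.
#'
#' @param sim A `fraglenqc_sim` from [simulate_sample()].
#' @param dir Output directory (created if needed).
#' @param write_reference Also write `<sample>.ref.fa` (default `TRUE`).
#' @return Invisibly, a named list of the paths written (`sam`, `truth`,
#'   optionally `reference`).
#' @export
emit_sam <- function(sim, dir, write_reference = TRUE) {
  stopifnot(inherits(sim, "fraglenqc_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- sim$config$sample_id
  sam_path <- file.path(dir, paste0(id, ".sam"))
  truth_path <- file.path(dir, paste0(id, ".truth.tsv"))

  r <- sim$records
  flag <- integer(nrow(r))
  flag[r$mate == "R1" & r$strand == "forward"] <- 99L
  flag[r$mate == "R1" & r$strand == "reverse"] <- 83L
  flag[r$mate == "R2" & r$strand == "forward"] <- 163L
  flag[r$mate == "R2" & r$strand == "reverse"] <- 147L

  # mate position: the other record of the pair (records are pair-adjacent)
  n <- nrow(r)
  mate_pos <- r$pos[ifelse(seq_len(n) %% 2L == 1L, seq_len(n) + 1L, seq_len(n) - 1L)]
  nm <- vapply(strsplit(r$md, "[0-9]+|\\^[A-Za-z]+"), function(x) sum(nzchar(x)), integer(1))

  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:ref\tLN:", nchar(sim$reference)),
    "@PG\tID:fraglenqc\tPN:fraglenqc"
  )
  lines <- paste(r$qname, flag, "ref", r$pos, 60L, r$cigar, "=", mate_pos,
                 r$tlen, r$seq, r$qual,
                 paste0("NM:i:", nm), paste0("MD:Z:", r$md),
                 sep = "\t")
  writeLines(c(header, lines), sam_path)

  tr <- sim$truth
  readr::write_tsv(tibble::tibble(
    qname = tr$qname,
    mate = tr$mate,
    fragment_length = tr$fragment_length,
    substitution_cycles = vapply(tr$substitution_cycles, paste, character(1),
                                 collapse = ",")
  ), truth_path)

  out <- list(sam = sam_path, truth = truth_path)
  if (write_reference) {
    ref_path <- file.path(dir, paste0(id, ".ref.fa"))
    ref <- Biostrings::DNAStringSet(sim$reference)
    names(ref) <- "ref"
    Biostrings::writeXStringSet(ref, ref_path)
    out$reference <- ref_path
  }
  invisible(out)
}

#' Simulate a multi-sample study with varying long-fragment content
#'
#' One sample per `p_long` value, all sharing one reference generated from
#' the master seed; each sample runs on an independent substream seed derived
#' deterministically from the master seed, so the whole study is reproducible
#' and samples are independent.
#'
#' @param p_long Numeric vector of long-component mixing weights, one sample
#'   each (at least 3).
#' @param config A [sim_config()] template; its `seed`, `sample_id` and
#'   `frag$p_long` are overridden per sample.
#' @param seed Master seed.
#' @param dir If non-`NULL`, write each sample's SAM + truth there.
#' @return List of `fraglenqc_sim` objects (invisibly when `dir` is given).
#' @export
simulate_study <- function(p_long, config = sim_config(), seed = 1L, dir = NULL) {
  if (length(p_long) < 3L) stop("a study needs at least 3 samples")
  reference <- generate_reference(config$genome_length, derive_seed(seed, 0L))
  sims <- vector("list", length(p_long))
  for (i in seq_along(p_long)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, i)
    cfg$sample_id <- sprintf("sample%02d", i)
    cfg$frag$p_long <- p_long[i]
    sims[[i]] <- simulate_sample(cfg, reference = reference)
    if (!is.null(dir)) emit_sam(sims[[i]], dir)
  }
  names(sims) <- vapply(sims, function(s) s$config$sample_id, character(1))
  if (is.null(dir)) sims else invisible(sims)
}
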