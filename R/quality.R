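#' Aligned-base mismatch rate of a read
#'
#' @param profile A `mismatch_profile` from [extract_mismatches()] or
#'   [mismatches_by_comparison()].
#' @return Substitution count divided by aligned-base count.
#' @export
mismatch_rate <- function(profile) {
  if (profile$aligned_bases == 0L) {
    stop("mismatch rate undefined: no aligned bases")
  }
  length(profile$cycle_positions) / profile$aligned_bases
}

#' Decode a SAM QUAL string into integer Phred scores
#'
#' @param qual QUAL string (ASCII, offset 33).
#' @return Integer vector of Phred scores.
#' @export
decode_phred <- function(qual) {
  if (is.na(qual) || qual == "*") return(integer(0))
  as.integer(charToRaw(qual)) - 33L
}

#' Mean Phred score of a read
#'
#' @param phred Non-empty integer vector of Phred scores, or a QUAL string.
#' @return Arithmetic mean of the scores.
#' @export
mean_phred <- function(phred) {
  if (is.character(phred)) phred <- decode_phred(phred)
  if (length(phred) == 0L) stop("mean Phred undefined: no quality scores")
  mean(phred)
}

#' Classify a read as low quality under both definitions
#'
#' A read is low quality by mismatch when its aligned-base mismatch rate is
#' strictly above the cutoff (default 0.01), and low quality by Phred when its
#' mean Phred score is strictly below the cutoff (default 30). A rate of
#' exactly 0.01 or a mean Phred of exactly 30 is therefore not low quality.
#'
#' @param rate Mismatch rate in `[0, 1]`.
#' @param mean_q Mean Phred score, or `NA` when qualities are absent.
#' @param spec A [stratum_spec()] holding the cutoffs.
#' @return A list with logicals `lq_by_mismatch` and `lq_by_phred` (the
#'   latter `NA` when `mean_q` is `NA`).
#' @export
classify_read <- function(rate, mean_q = NA_real_, spec = stratum_spec()) {
  list(
    lq_by_mismatch = rate > spec$mismatch_cutoff,
    lq_by_phred = ifelse(is.na(mean_q), NA, mean_q < spec$phred_cutoff)
  )
}

# Vectorized MD-walk for records whose CIGAR is a single M run.
# Returns a list of 0-based mismatch read-string positions per record.
md_positions_allm <- function(md, read_length) {
  out <- vector("list", length(md))
  clean <- grepl("^[0-9]+$", md)
  out[clean] <- list(integer(0))
  n_bad <- sum(as.integer(md[clean]) != read_length[clean])
  if (n_bad > 0L) {
    stop("MD tag length disagrees with aligned bases for ", n_bad, " record(s)")
  }
  todo <- which(!clean)
  if (length(todo)) {
    toks <- regmatches(md[todo], gregexpr("[A-Za-z]|[0-9]+", md[todo]))
    out[todo] <- Map(function(tok, len) {
      nums <- suppressWarnings(as.integer(tok))
      isnum <- !is.na(nums)
      adv <- ifelse(isnum, nums, 1L)
      consumed <- cumsum(adv)
      if (consumed[length(consumed)] != len) {
        stop("MD tag length disagrees with aligned bases (md walk = ",
             consumed[length(consumed)], ", aligned = ", len, ")")
      }
      as.integer(consumed[!isnum] - 1L)
    }, toks, read_length[todo])
  }
  out
}

#' Per-read quality table from loaded alignments
#'
#' Runs substitution extraction, fragment-length derivation, Phred averaging
#' and low-quality classification over every record of an alignment table.
#' Records whose MD tag is absent or inconsistent with the CIGAR, or that have
#' zero aligned bases, are dropped and counted in the `"extraction_log"`
#' attribute rather than failing the run.
#'
#' @param aln Alignment tibble from [load_alignments()] (or the in-memory
#'   records of a simulated sample).
#' @param spec A [stratum_spec()].
#' @return Tibble with one row per usable read: `sample_id`, `qname`, `mate`,
#'   `strand`, `fragment_length` (`NA` when TLEN is invalid), `read_length`,
#'   `aligned_bases`, `n_mismatch`, `mismatch_rate`, `mean_phred`,
#'   `lq_mismatch`, `lq_phred`, and a list column `cycles` of 0-based
#'   substitution cycle positions. Attribute `"extraction_log"` tallies
#'   dropped records.
#' @export
read_quality_table <- function(aln, spec = stratum_spec()) {
  n <- nrow(aln)
  dropped <- c(no_md = 0L, md_parse_error = 0L, no_aligned_bases = 0L)

  has_md <- !is.na(aln$md)
  dropped["no_md"] <- sum(!has_md)
  aln <- aln[has_md, , drop = FALSE]

  # fast vectorized path: fully aligned reads without N calls; reads with N
  # bases go through the scalar walk so no-calls are excluded
  has_n <- !is.na(aln$seq) & grepl("N", aln$seq, fixed = TRUE)
  allm <- grepl("^[0-9]+M$", aln$cigar) & !has_n
  cyc <- vector("list", nrow(aln))
  aligned <- integer(nrow(aln))
  ok <- rep(TRUE, nrow(aln))

  if (any(allm)) {
    pos <- md_positions_allm(aln$md[allm], aln$read_length[allm])
    rev_allm <- aln$strand[allm] == "reverse"
    len_allm <- aln$read_length[allm]
    cyc[allm] <- Map(function(p, rv, len) {
      if (rv && length(p)) sort(len - 1L - p) else p
    }, pos, rev_allm, len_allm)
    aligned[allm] <- len_allm
  }

  for (i in which(!allm)) {
    prof <- tryCatch(
      extract_mismatches(aln$cigar[i], aln$md[i], aln$strand[i],
                         aln$read_length[i], seq = aln$seq[i]),
      error = function(e) NULL
    )
    if (is.null(prof)) {
      ok[i] <- FALSE
      dropped["md_parse_error"] <- dropped["md_parse_error"] + 1L
    } else {
      cyc[[i]] <- prof$cycle_positions
      aligned[i] <- prof$aligned_bases
    }
  }

  zero <- ok & aligned == 0L
  dropped["no_aligned_bases"] <- sum(zero)
  keep <- ok & !zero

  aln <- aln[keep, , drop = FALSE]
  cyc <- cyc[keep]
  aligned <- aligned[keep]

  n_mismatch <- lengths(cyc)
  rate <- n_mismatch / aligned
  meanq <- vapply(aln$qual, function(q) {
    if (is.na(q) || q == "*") NA_real_ else mean(as.integer(charToRaw(q)) - 33L)
  }, numeric(1), USE.NAMES = FALSE)

  out <- tibble::tibble(
    sample_id = aln$sample_id,
    qname = aln$qname,
    mate = aln$mate,
    strand = aln$strand,
    fragment_length = fragment_length(aln$tlen, spec),
    read_length = aln$read_length,
    aligned_bases = aligned,
    n_mismatch = n_mismatch,
    mismatch_rate = rate,
    mean_phred = meanq,
    lq_mismatch = rate > spec$mismatch_cutoff,
    lq_phred = ifelse(is.na(meanq), NA, meanq < spec$phred_cutoff),
    cycles = cyc,
    all_m = grepl("^[0-9]+M$", aln$cigar),
    cigar = aln$cigar,
    md = aln$md
  )
  attr(out, "extraction_log") <- tibble::tibble(
    record_class = names(dropped),
    count = as.integer(dropped)
  )
  out
}

#' Positional mismatch profile for one mate and fragment-length window
#'
#' Per-cycle substitution rates (substitutions over aligned coverage) for
#' reads of one mate whose fragment length falls inside a closed length
#' window, e.g. short fragments 200--400 bp versus long fragments
#' 600--1000 bp. Cycles whose aligned coverage is below
#' `spec$min_cycle_coverage` are masked (`rate = NA`).
#'
#' @param reads Per-read quality tibble from [read_quality_table()].
#' @param mate `"R1"` or `"R2"`.
#' @param window Closed fragment-length window `c(lo, hi)`, or `"short"` /
#'   `"long"` for the windows in `spec`.
#' @param spec A [stratum_spec()].
#' @return Tibble: `group`, `cycle` (0-based), `coverage`, `mismatches`,
#'   `rate` (`NA` where masked).
#' @export
positional_profile <- function(reads, mate = c("R1", "R2"), window = "short",
                               spec = stratum_spec()) {
  mate <- match.arg(mate)
  if (is.character(window)) {
    window <- switch(match.arg(window, c("short", "long")),
                     short = spec$short_window, long = spec$long_window)
  }
  label <- sprintf("%s[%d,%d]", mate, window[1], window[2])
  sel <- reads$mate == mate & !is.na(reads$fragment_length) &
    reads$fragment_length >= window[1] & reads$fragment_length <= window[2]
  sub <- reads[sel, , drop = FALSE]
  max_len <- if (nrow(sub)) max(sub$read_length) else 0L
  if (max_len == 0L) {
    return(tibble::tibble(group = character(0), cycle = integer(0),
                          coverage = integer(0), mismatches = integer(0),
                          rate = numeric(0)))
  }

  mism <- tabulate(unlist(sub$cycles) + 1L, nbins = max_len)
  # coverage: an all-M read covers every cycle below its length; clipped or
  # gapped reads have their aligned cycles re-derived from CIGAR + MD
  cover <- tabulate(sub$read_length[sub$all_m], nbins = max_len)
  cover <- rev(cumsum(rev(cover)))
  for (i in which(!sub$all_m)) {
    prof <- extract_mismatches(sub$cigar[i], sub$md[i], sub$strand[i],
                               sub$read_length[i])
    add <- tabulate(prof$aligned_cycles + 1L, nbins = max_len)
    cover <- cover + add
  }

  rate <- ifelse(cover >= spec$min_cycle_coverage & cover > 0L,
                 mism / cover, NA_real_)
  tibble::tibble(
    group = label,
    cycle = 0:(max_len - 1L),
    coverage = as.integer(cover),
    mismatches = as.integer(mism),
    rate = rate
  )
}

#' Centered rolling mean for profile plotting
#'
#' @param x Numeric vector (may contain `NA`).
#' @param window Odd window width (default 5).
#' @return Smoothed vector of the same length; endpoints use the available
#'   part of the window. For display only -- analyses use raw rates.
#' @export
rolling_mean <- function(x, window = 5L) {
  if (window %% 2L != 1L) stop("window must be odd")
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}
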