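#' Random single-alignment cases for parser validation
#'
#' Generates alignment records with randomly placed soft clips, insertions,
#' deletions and substitutions on both strands, each carrying the read
#' sequence, the exact reference slice its CIGAR consumes, an MD tag built
#' with [compute_md()], and the true injected substitution cycles. Intended
#' for exercising [extract_mismatches()] against
#' [mismatches_by_comparison()] and against the recorded truth.
#'
#' @param n Number of cases.
#' @param seed Integer seed.
#' @param read_length Read length of every case.
#' @param sub_rate Per-base substitution probability within matched segments.
#' @param p_clip Probability of a soft clip at each read end.
#' @param p_indel Probability of opening an indel between match runs.
#' @param genome_length Length of the private reference the cases align to.
#' @return Tibble: `seq`, `ref_slice`, `cigar`, `strand`, `md`,
#'   `truth_cycles` (list of 0-based cycle positions), `read_length`.
#' @export
random_alignments <- function(n, seed = 1L, read_length = 80L, sub_rate = 0.02,
                              p_clip = 0.3, p_indel = 0.4,
                              genome_length = 5000L) {
  reference <- generate_reference(genome_length, derive_seed(seed, 0L))
  set.seed(derive_seed(seed, 1L))
  bases <- c("A", "C", "G", "T")
  alt <- list(A = c("C","G","T"), C = c("A","G","T"),
              G = c("A","C","T"), T = c("A","C","G"))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rl <- read_length
    clip5 <- if (stats::runif(1) < p_clip) sample.int(10L, 1L) else 0L
    clip3 <- if (stats::runif(1) < p_clip) sample.int(10L, 1L) else 0L
    m_budget <- rl - clip5 - clip3

    # alternate M runs with occasional I/D, always starting and ending on M
    ops <- character(0); lens <- integer(0)
    remaining <- m_budget
    repeat {
      run <- min(remaining, sample(5:40, 1L))
      ops <- c(ops, "M"); lens <- c(lens, run)
      remaining <- remaining - run
      if (remaining <= 0L) break
      if (stats::runif(1) < p_indel) {
        if (stats::runif(1) < 0.5) {
          ins <- min(remaining, sample.int(3L, 1L))
          if (ins < remaining) {     # insertion must not swallow the last M
            ops <- c(ops, "I"); lens <- c(lens, ins)
            remaining <- remaining - ins
          }
        } else {
          ops <- c(ops, "D"); lens <- c(lens, sample.int(3L, 1L))
        }
      }
    }
    cigar <- paste0(
      if (clip5) paste0(clip5, "S") else "",
      paste0(lens, ops, collapse = ""),
      if (clip3) paste0(clip3, "S") else ""
    )

    ref_span <- sum(lens[ops %in% c("M", "D")])
    start <- sample.int(genome_length - ref_span, 1L)
    slice <- substr(reference, start, start + ref_span - 1L)

    # build the read by walking the CIGAR over the slice
    read <- character(rl)
    if (clip5) read[seq_len(clip5)] <- sample(bases, clip5, replace = TRUE)
    rpos <- clip5; gpos <- 0L
    truth_pos <- integer(0)
    for (k in seq_along(ops)) {
      if (ops[k] == "M") {
        seg <- strsplit(substr(slice, gpos + 1L, gpos + lens[k]), "")[[1]]
        hit <- which(stats::runif(lens[k]) < sub_rate)
        for (h in hit) seg[h] <- sample(alt[[seg[h]]], 1L)
        read[rpos + seq_len(lens[k])] <- seg
        truth_pos <- c(truth_pos, rpos + hit - 1L)
        rpos <- rpos + lens[k]; gpos <- gpos + lens[k]
      } else if (ops[k] == "I") {
        read[rpos + seq_len(lens[k])] <- sample(bases, lens[k], replace = TRUE)
        rpos <- rpos + lens[k]
      } else {
        gpos <- gpos + lens[k]
      }
    }
    if (clip3) read[rpos + seq_len(clip3)] <- sample(bases, clip3, replace = TRUE)
    seq <- paste(read, collapse = "")

    strand <- sample(c("forward", "reverse"), 1L)
    rows[[i]] <- tibble::tibble(
      seq = seq,
      ref_slice = slice,
      cigar = cigar,
      strand = strand,
      md = compute_md(seq, slice, cigar),
      truth_cycles = list(sort(to_cycle_coordinate(truth_pos, strand, rl))),
      read_length = rl
    )
  }
  dplyr::bind_rows(rows)
}

#' Compare the MD route against the comparison route over many cases
#'
#' Runs [extract_mismatches()] (CIGAR + MD walk) and
#' [mismatches_by_comparison()] (direct read-vs-reference comparison) on each
#' case and reports whether the substitution cycle sets and aligned-base
#' counts agree exactly.
#'
#' @param cases Tibble from [random_alignments()].
#' @return Tibble: per-case logicals `cycles_equal`, `aligned_equal`,
#'   `truth_equal` (MD route versus the generator's injected truth).
#' @export
parser_agreement <- function(cases) {
  out <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    a <- extract_mismatches(cases$cigar[i], cases$md[i], cases$strand[i],
                            cases$read_length[i], seq = cases$seq[i])
    b <- mismatches_by_comparison(cases$seq[i], cases$ref_slice[i],
                                  cases$cigar[i], cases$strand[i])
    out[[i]] <- tibble::tibble(
      cycles_equal = identical(a$cycle_positions, b$cycle_positions),
      aligned_equal = a$aligned_bases == b$aligned_bases,
      truth_equal = identical(a$cycle_positions,
                              as.integer(cases$truth_cycles[[i]]))
    )
  }
  dplyr::bind_rows(out)
}
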