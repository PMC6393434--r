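# handcrafted SAM fixtures built in code; coordinates are 1-based SAM

sam_header <- function(ref_len = 1000L) {
  c("@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:ref\tLN:", ref_len))
}

sam_record <- function(qname, flag, pos, cigar, seq, qual = NULL, tlen = 200L,
                       md = NULL, pnext = pos + 100L) {
  if (is.null(qual)) qual <- paste(rep("?", nchar(seq)), collapse = "")
  fields <- c(qname, flag, "ref", pos, 60L, cigar, "=", pnext, tlen, seq, qual)
  if (!is.null(md)) fields <- c(fields, paste0("MD:Z:", md))
  paste(fields, collapse = "\t")
}

write_sam <- function(lines, path = tempfile(fileext = ".sam")) {
  writeLines(lines, path)
  path
}

# a minimal mixed SAM: 2 passing records (a proper 99/147 pair), 1 secondary,
# 1 not-properly-paired, 1 duplicate-flagged proper record
mixed_sam <- function() {
  write_sam(c(
    sam_header(),
    sam_record("pair1", 99L, 11L, "10M", "ACGTACGTAC", tlen = 200L, md = "10"),
    sam_record("pair1", 147L, 201L, "10M", "ACGTACGTAC", tlen = -200L, md = "10"),
    sam_record("sec1", 355L, 31L, "10M", "ACGTACGTAC", tlen = 200L, md = "10"),
    sam_record("oneend", 97L, 41L, "10M", "ACGTACGTAC", tlen = 0L, md = "10"),
    sam_record("dup1", 1123L, 51L, "10M", "ACGTACGTAC", tlen = 150L, md = "10")
  ))
}

# a per-read quality tibble built by hand for stratification tests;
# one row per read, pairs share qname and fragment_length
manual_reads <- function(frag_len, lq_r1, lq_r2, sample_id = "manual") {
  n <- length(frag_len)
  tibble::tibble(
    sample_id = sample_id,
    qname = rep(sprintf("p%03d", seq_len(n)), times = 2L),
    mate = rep(c("R1", "R2"), each = n),
    strand = rep(c("forward", "reverse"), each = n),
    fragment_length = rep(as.integer(frag_len), times = 2L),
    read_length = 100L,
    aligned_bases = 100L,
    n_mismatch = as.integer(c(lq_r1, lq_r2)) * 2L,
    mismatch_rate = c(lq_r1, lq_r2) * 0.02,
    mean_phred = 35,
    lq_mismatch = as.logical(c(lq_r1, lq_r2)),
    lq_phred = FALSE,
    cycles = replicate(2L * n, integer(0), simplify = FALSE),
    all_m = TRUE,
    cigar = "100M",
    md = "100"
  )
}

default_spec <- stratum_spec()
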