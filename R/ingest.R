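#' Load paired-end alignments from SAM/BAM with the profiling filter contract
#'
#' Reads all records from a SAM or BAM file and keeps exactly those that are
#' mapped, primary (neither secondary nor supplementary) and properly paired;
#' every excluded record is tallied in a filter log instead of being returned.
#' Fragment length analysis needs concordant pairs, and restricting to primary
#' alignments avoids double counting, so this contract is applied before any
#' quality metric is computed.
#'
#' @param path Path to a SAM (`.sam`) or BAM (`.bam`) file with a valid
#'   header. SAM input is converted in a temporary directory via
#'   [Rsamtools::asBam()].
#' @param sample_id Sample label attached to every returned record; defaults
#'   to the file name without extension (one input file = one sequenced
#'   library).
#' @param keep_duplicates Keep records flagged as PCR/optical duplicates
#'   (default `TRUE`); set `FALSE` to filter and count them.
#' @param reference Optional reference FASTA path used to compute MD tags for
#'   records that lack them.
#' @return A tibble with one row per passing record: `sample_id`, `qname`,
#'   `mate` (`"R1"`/`"R2"`), `strand` (`"forward"`/`"reverse"`), `pos`
#'   (1-based leftmost), `cigar`, `tlen`, `md` (NA if absent), `seq`, `qual`
#'   (NA if absent), `read_length`. The filter log is attached as attribute
#'   `"filter_log"`, a tibble with columns `record_class`, `count` in which
#'   `passed + filtered classes` sums to the records in the file.
#' @export
load_alignments <- function(path, sample_id = NULL, keep_duplicates = TRUE,
                            reference = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  }

  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("failed to read SAM file ", path, ": ",
                               conditionMessage(e))
    )
  }

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "isize", "seq", "qual"),
    tag = "MD"
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]

  flag <- res$flag
  n <- length(flag)
  bit <- function(mask) bitwAnd(flag, mask) != 0L

  unmapped <- bit(0x4)
  secondary <- bit(0x100)
  supplementary <- bit(0x800)
  duplicate <- bit(0x400)
  proper <- bit(0x2)
  r1 <- bit(0x40)
  r2 <- bit(0x80)
  bad_mate <- !(r1 != r2)          # exactly one of 0x40/0x80 must be set

  # precedence for the filter tally; each record lands in exactly one class
  class_of <- rep("passed", n)
  class_of[!keep_duplicates & duplicate] <- "duplicate"
  class_of[!proper] <- "not_proper"
  class_of[supplementary] <- "supplementary"
  class_of[secondary] <- "secondary"
  class_of[unmapped] <- "unmapped"
  class_of[bad_mate] <- "bad_mate_flags"

  keep <- class_of == "passed"
  classes <- c("passed", "unmapped", "secondary", "supplementary",
               "not_proper", "duplicate", "bad_mate_flags")
  log <- tibble::tibble(
    record_class = classes,
    count = vapply(classes, function(cl) sum(class_of == cl), integer(1),
                   USE.NAMES = FALSE)
  )

  seqs <- as.character(res$seq[keep])
  seqs[seqs == "*" | !nzchar(seqs)] <- NA_character_
  quals <- as.character(res$qual[keep])
  # a missing QUAL ("*" in SAM, 0xff-filled in BAM) surfaces as "*" or as an
  # all-space string; spaces are outside the legal Phred+33 range
  quals[quals == "*" | !nzchar(quals) | grepl("^ +$", quals)] <- NA_character_
  md <- if (!is.null(res$tag$MD)) as.character(res$tag$MD)[keep] else rep(NA_character_, sum(keep))

  read_length <- nchar(seqs)
  no_seq <- which(is.na(seqs))
  if (length(no_seq)) {
    read_length[no_seq] <- vapply(res$cigar[keep][no_seq], cigar_query_length,
                                  integer(1), USE.NAMES = FALSE)
  }

  aln <- tibble::tibble(
    sample_id = sample_id,
    qname = res$qname[keep],
    mate = ifelse(r1[keep], "R1", "R2"),
    strand = ifelse(bit(0x10)[keep], "reverse", "forward"),
    pos = res$pos[keep],
    cigar = res$cigar[keep],
    tlen = res$isize[keep],
    md = md,
    seq = seqs,
    qual = quals,
    read_length = read_length
  )

  if (!is.null(reference) && anyNA(aln$md)) {
    aln <- fill_md_from_reference(aln, reference)
  }

  attr(aln, "filter_log") <- log
  aln
}

# compute MD for records lacking one, from a reference FASTA
fill_md_from_reference <- function(aln, reference) {
  ref <- Biostrings::readDNAStringSet(reference)
  refseq <- as.character(ref[[1]])
  need <- which(is.na(aln$md))
  for (i in need) {
    cg <- parse_cigar(aln$cigar[i])
    span <- sum(cg$lens[cg$ops %in% c("M", "D", "N", "=", "X")])
    slice <- substr(refseq, aln$pos[i], aln$pos[i] + span - 1L)
    aln$md[i] <- compute_md(aln$seq[i], slice, aln$cigar[i])
  }
  aln
}

#' Retrieve the filter log of a loaded alignment table
#'
#' @param aln Tibble returned by [load_alignments()].
#' @return Tibble with columns `record_class`, `count`.
#' @export
filter_log <- function(aln) {
  log <- attr(aln, "filter_log")
  if (is.null(log)) stop("object carries no filter log")
  log
}

#' Write a filter log as TSV
#'
#' @param aln Tibble returned by [load_alignments()], or a filter-log tibble.
#' @param path Output TSV path.
#' @export
write_filter_log <- function(aln, path) {
  log <- if (is.data.frame(aln) && all(c("record_class", "count") %in% names(aln))) {
    aln
  } else {
    filter_log(aln)
  }
  readr::write_tsv(log, path)
  invisible(path)
}
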