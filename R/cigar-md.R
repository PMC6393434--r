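#' Parse a CIGAR string into operations and lengths
#'
#' @param cigar A single CIGAR string, e.g. `"5S50M2D45M"`.
#' @return A list with integer vector `lens` and character vector `ops`.
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    stop("CIGAR is absent ('*'); record is unaligned")
  }
  m <- gregexpr("\\d+|[MIDNSHP=X]", cigar)[[1]]
  tok <- regmatches(cigar, list(m))[[1]]
  if (length(tok) == 0L || length(tok) %% 2L != 0L) {
    stop("malformed CIGAR: ", cigar)
  }
  idx <- seq(1L, length(tok), by = 2L)
  lens <- suppressWarnings(as.integer(tok[idx]))
  ops <- tok[idx + 1L]
  if (anyNA(lens) || any(!ops %in% c("M", "I", "D", "N", "S", "H", "P", "=", "X"))) {
    stop("malformed CIGAR: ", cigar)
  }
  list(lens = lens, ops = ops)
}

# read-string length implied by a CIGAR (ops that consume query bases)
cigar_query_length <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$lens[cg$ops %in% c("M", "I", "S", "=", "X")])
}

#' Convert a read-string position to a sequencing-cycle index
#'
#' SAM stores the SEQ of reverse-strand alignments reverse-complemented, so
#' position `p` in the stored string corresponds to sequencing cycle
#' `read_length - 1 - p`. Forward-strand positions are already in cycle order.
#' All coordinates are 0-based.
#'
#' @param pos Integer vector of 0-based read-string positions.
#' @param strand `"forward"` or `"reverse"`.
#' @param read_length Read length in bases.
#' @return Integer vector of 0-based cycle indices.
#' @examples
#' to_cycle_coordinate(0, "reverse", 100)  # 99
#' @export
to_cycle_coordinate <- function(pos, strand, read_length) {
  strand <- match.arg(strand, c("forward", "reverse"))
  if (any(pos < 0L | pos >= read_length)) {
    stop("position out of range [0, read_length)")
  }
  if (strand == "forward") as.integer(pos) else as.integer(read_length - 1L - pos)
}

# tokenize an MD tag value into numbers, mismatch bases and ^-deletions
md_tokens <- function(md) {
  m <- gregexpr("\\^[A-Za-z]+|[A-Za-z]|[0-9]+", md)[[1]]
  regmatches(md, list(m))[[1]]
}

#' Extract substitution positions from CIGAR + MD
#'
#' Walks the CIGAR and MD tag of one alignment record and reports the
#' sequencing-cycle positions of substituted bases together with the number of
#' read bases under alignment-match (`M`/`=`/`X`) operations. Soft-clipped and
#' inserted read bases are excluded from both the substitution set and the
#' aligned-base count; deletions consume reference only. If the read sequence
#' is supplied, read bases called `N` are additionally excluded from both the
#' numerator and the denominator (no-calls are not substitutions).
#'
#' @param cigar CIGAR string of the record.
#' @param md MD tag value (without the `MD:Z:` prefix).
#' @param strand `"forward"` or `"reverse"`; reverse-strand positions are
#'   mapped back to sequencing order.
#' @param read_length Read length; defaults to the query length implied by the
#'   CIGAR.
#' @param seq Optional read sequence (stored orientation) used to exclude `N`
#'   bases.
#' @return A list of class `mismatch_profile` with elements
#'   `cycle_positions` (sorted 0-based integer cycle indices),
#'   `aligned_bases`, `read_length`, and `aligned_cycles` (integer vector of
#'   cycle indices covered by alignment-match operations, for per-cycle
#'   coverage).
#' @seealso [mismatches_by_comparison()] for the MD-free route that compares
#'   the read against a reference slice directly.
#' @export
extract_mismatches <- function(cigar, md, strand = "forward", read_length = NULL,
                               seq = NULL) {
  strand <- match.arg(strand, c("forward", "reverse"))
  cg <- parse_cigar(cigar)
  qlen <- sum(cg$lens[cg$ops %in% c("M", "I", "S", "=", "X")])
  if (is.null(read_length)) read_length <- qlen
  if (qlen != read_length) {
    stop("CIGAR query length (", qlen, ") disagrees with read_length (", read_length, ")")
  }

  # 0-based read-string positions covered by alignment-match ops, in order
  rpos <- 0L
  m_positions <- integer(0)
  for (k in seq_along(cg$ops)) {
    op <- cg$ops[k]
    len <- cg$lens[k]
    if (op %in% c("M", "=", "X")) {
      m_positions <- c(m_positions, rpos + seq_len(len) - 1L)
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      rpos <- rpos + len
    }
    # D, N, H, P consume no read bases
  }

  tok <- md_tokens(md)
  i <- 0L                       # consumed aligned positions
  mm <- integer(0)              # mismatch read-string positions
  for (t in tok) {
    first <- substr(t, 1L, 1L)
    if (first == "^") next      # deletion: consumes reference only
    if (first %in% c("0","1","2","3","4","5","6","7","8","9")) {
      i <- i + as.integer(t)
    } else {
      if (i + 1L > length(m_positions)) {
        stop("MD tag walks past aligned length (cigar ", cigar, ", md ", md, ")")
      }
      mm <- c(mm, m_positions[i + 1L])
      i <- i + 1L
    }
  }
  if (i != length(m_positions)) {
    stop("MD tag length (", i, ") disagrees with aligned bases (",
         length(m_positions), ") for cigar ", cigar)
  }

  if (!is.null(seq) && !is.na(seq) && seq != "*") {
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    is_n <- bases[m_positions + 1L] %in% c("N", "n")
    mm <- setdiff(mm, m_positions[is_n])
    m_positions <- m_positions[!is_n]
  }

  structure(list(
    cycle_positions = sort(to_cycle_coordinate(mm, strand, read_length)),
    aligned_bases = length(m_positions),
    read_length = as.integer(read_length),
    aligned_cycles = sort(to_cycle_coordinate(m_positions, strand, read_length))
  ), class = "mismatch_profile")
}

#' Identify substitutions by direct read-vs-reference comparison
#'
#' MD-free counterpart of [extract_mismatches()]: walks the CIGAR and compares
#' read bases against the corresponding reference bases. Used when alignments
#' lack MD tags (with a reference FASTA available) and as an independent
#' cross-check of the MD route. Positions where the read or the reference base
#' is `N` are excluded from both the substitution set and the aligned-base
#' count.
#'
#' @param seq Read sequence as stored in the SAM record.
#' @param ref_slice Reference bases spanned by the alignment (exactly the
#'   reference bases the CIGAR consumes).
#' @param cigar CIGAR string.
#' @param strand `"forward"` or `"reverse"`.
#' @return A `mismatch_profile` list, as for [extract_mismatches()].
#' @export
mismatches_by_comparison <- function(seq, ref_slice, cigar, strand = "forward") {
  strand <- match.arg(strand, c("forward", "reverse"))
  cg <- parse_cigar(cigar)
  read <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ref <- strsplit(toupper(ref_slice), "", fixed = TRUE)[[1]]
  rlen <- length(read)
  ref_consumed <- sum(cg$lens[cg$ops %in% c("M", "D", "N", "=", "X")])
  if (ref_consumed != length(ref)) {
    stop("ref_slice length (", length(ref), ") disagrees with CIGAR reference span (",
         ref_consumed, ")")
  }

  rpos <- 0L; gpos <- 0L
  mm <- integer(0); aligned <- integer(0)
  for (k in seq_along(cg$ops)) {
    op <- cg$ops[k]; len <- cg$lens[k]
    if (op %in% c("M", "=", "X")) {
      rb <- read[rpos + seq_len(len)]
      gb <- ref[gpos + seq_len(len)]
      ok <- rb != "N" & gb != "N"
      here <- (rpos + seq_len(len) - 1L)[ok]
      aligned <- c(aligned, here)
      mm <- c(mm, here[rb[ok] != gb[ok]])
      rpos <- rpos + len; gpos <- gpos + len
    } else if (op %in% c("I", "S")) {
      rpos <- rpos + len
    } else if (op %in% c("D", "N")) {
      gpos <- gpos + len
    }
  }

  structure(list(
    cycle_positions = sort(to_cycle_coordinate(mm, strand, rlen)),
    aligned_bases = length(aligned),
    read_length = rlen,
    aligned_cycles = sort(to_cycle_coordinate(aligned, strand, rlen))
  ), class = "mismatch_profile")
}

#' Build an MD tag from a read, a reference slice and a CIGAR
#'
#' Follows the SAM optional-field convention also used by `samtools calmd`:
#' match-run lengths separated by mismatched reference bases and `^`-prefixed
#' deleted reference runs, with a (possibly zero) match count before every
#' event and at the end. A read base differing from the reference (including
#' `N`) is reported as a mismatch.
#'
#' @inheritParams mismatches_by_comparison
#' @return The MD tag value as a single string.
#' @examples
#' compute_md("ACGT", "AGGT", "4M")      # "1G2"
#' compute_md("ACGT", "ACTGT", "2M1D2M") # "2^T2"
#' @export
compute_md <- function(seq, ref_slice, cigar) {
  cg <- parse_cigar(cigar)
  read <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ref <- strsplit(toupper(ref_slice), "", fixed = TRUE)[[1]]
  qlen <- sum(cg$lens[cg$ops %in% c("M", "I", "S", "=", "X")])
  ref_consumed <- sum(cg$lens[cg$ops %in% c("M", "D", "N", "=", "X")])
  if (qlen != length(read)) {
    stop("read length (", length(read), ") disagrees with CIGAR query span (", qlen, ")")
  }
  if (ref_consumed != length(ref)) {
    stop("ref_slice length (", length(ref), ") disagrees with CIGAR reference span (",
         ref_consumed, ")")
  }

  out <- character(0)
  run <- 0L
  rpos <- 0L; gpos <- 0L
  for (k in seq_along(cg$ops)) {
    op <- cg$ops[k]; len <- cg$lens[k]
    if (op %in% c("M", "=", "X")) {
      for (j in seq_len(len)) {
        if (read[rpos + j] == ref[gpos + j]) {
          run <- run + 1L
        } else {
          out <- c(out, as.character(run), ref[gpos + j])
          run <- 0L
        }
      }
      rpos <- rpos + len; gpos <- gpos + len
    } else if (op %in% c("I", "S")) {
      rpos <- rpos + len
    } else if (op %in% c("D", "N")) {
      if (op == "D") {
        out <- c(out, as.character(run), paste0("^", paste(ref[gpos + seq_len(len)], collapse = "")))
        run <- 0L
      }
      gpos <- gpos + len
    }
  }
  paste(c(out, as.character(run)), collapse = "")
}

# Fast MD builder for all-M alignments given known 0-based mismatch offsets
# and the reference bases at those offsets. Vectorized over records.
md_from_positions <- function(read_length, positions, ref_bases) {
  n <- length(positions)
  if (n == 0L) return(as.character(read_length))
  o <- order(positions)
  p <- positions[o]
  b <- ref_bases[o]
  runs <- diff(c(-1L, p)) - 1L
  paste0(paste0(runs, b, collapse = ""), read_length - p[n] - 1L)
}
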