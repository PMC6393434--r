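#' Fragment-length stratification and quality thresholds
#'
#' Bundles the constants of the analysis: the low-quality cutoffs (aligned-base
#' mismatch rate above 0.01, or mean Phred below 30), the long-fragment
#' definition (strictly above 500 nt), the accepted insert-size range
#' (1--1000 bp, matching concordant-pair alignment bounds), the half-open
#' fragment-length bins used for stratified summaries, and the closed
#' short/long windows used for positional error profiles.
#'
#' @param bin_edges Strictly increasing integer bin edges; bins are half-open
#'   `[lo, hi)`.
#' @param long_cutoff A fragment is "long" when its length is strictly greater
#'   than this (bases).
#' @param short_window,long_window Closed fragment-length windows `[lo, hi]`
#'   selecting reads for the positional mismatch profiles.
#' @param min_insert,max_insert Valid absolute template-length range; pairs
#'   outside it carry no usable fragment length and are excluded.
#' @param mismatch_cutoff A read is low quality when its aligned-base mismatch
#'   rate is strictly above this.
#' @param phred_cutoff Alternative definition: mean Phred strictly below this.
#' @param min_stratum_reads Stratum cells with fewer reads are masked (`NA`).
#' @param min_cycle_coverage Profile cycles with fewer aligned bases are
#'   masked.
#' @return An object of class `stratum_spec`.
#' @export
stratum_spec <- function(bin_edges = seq(0L, 1000L, by = 100L),
                         long_cutoff = 500L,
                         short_window = c(200L, 400L),
                         long_window = c(600L, 1000L),
                         min_insert = 1L,
                         max_insert = 1000L,
                         mismatch_cutoff = 0.01,
                         phred_cutoff = 30,
                         min_stratum_reads = 100L,
                         min_cycle_coverage = 1000L) {
  bin_edges <- as.integer(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0L)) {
    stop("bin_edges must be strictly increasing with at least two values")
  }
  if (length(short_window) != 2L || length(long_window) != 2L ||
      short_window[1] > short_window[2] || long_window[1] > long_window[2]) {
    stop("windows must be [lo, hi] with lo <= hi")
  }
  if (min_insert < 1L || max_insert <= min_insert) {
    stop("need 1 <= min_insert < max_insert")
  }
  structure(list(
    bin_edges = bin_edges,
    long_cutoff = as.integer(long_cutoff),
    short_window = as.integer(short_window),
    long_window = as.integer(long_window),
    min_insert = as.integer(min_insert),
    max_insert = as.integer(max_insert),
    mismatch_cutoff = mismatch_cutoff,
    phred_cutoff = phred_cutoff,
    min_stratum_reads = as.integer(min_stratum_reads),
    min_cycle_coverage = as.integer(min_cycle_coverage)
  ), class = "stratum_spec")
}

#' @export
print.stratum_spec <- function(x, ...) {
  cat("stratum_spec\n")
  cat("  bins:          ", paste(x$bin_edges, collapse = ","), " (half-open)\n", sep = "")
  cat("  long fragment: > ", x$long_cutoff, " nt\n", sep = "")
  cat("  insert range:  [", x$min_insert, ", ", x$max_insert, "]\n", sep = "")
  cat("  low quality:   mismatch rate > ", x$mismatch_cutoff,
      " or mean Phred < ", x$phred_cutoff, "\n", sep = "")
  invisible(x)
}

#' Fragment length from the SAM template-length field
#'
#' The alignment-derived fragment (insert) length is `|TLEN|`. Values of zero
#' or outside the accepted insert range carry no usable length and are
#' returned as `NA` (the pair is excluded and counted, not an error).
#'
#' @param tlen Integer vector of signed SAM TLEN values.
#' @param spec A [stratum_spec()].
#' @return Integer vector of fragment lengths with `NA` for invalid entries.
#' @export
fragment_length <- function(tlen, spec = stratum_spec()) {
  len <- abs(as.integer(tlen))
  len[len < spec$min_insert | len > spec$max_insert] <- NA_integer_
  len
}

#' Assign fragment lengths to half-open length strata
#'
#' @param length Integer vector of valid fragment lengths.
#' @param spec A [stratum_spec()].
#' @return A tibble with `stratum` (factor of `"[lo,hi)"` labels, plus an
#'   `"overflow"` level for lengths outside the binned range), `stratum_lo`,
#'   `stratum_hi`, and `is_long` (`length > long_cutoff`, strictly).
#' @export
assign_stratum <- function(length, spec = stratum_spec()) {
  edges <- spec$bin_edges
  labels <- sprintf("[%d,%d)", edges[-length(edges)], edges[-1])
  idx <- findInterval(length, edges, rightmost.closed = FALSE)
  inside <- !is.na(idx) & idx >= 1L & idx < length(edges)
  stratum <- rep(NA_character_, length(length))
  stratum[inside] <- labels[idx[inside]]
  stratum[!inside & !is.na(length)] <- "overflow"
  tibble::tibble(
    stratum = factor(stratum, levels = c(labels, "overflow")),
    stratum_lo = ifelse(inside, edges[pmax(idx, 1L)], NA_integer_),
    stratum_hi = ifelse(inside, edges[pmin(idx + 1L, length(edges))], NA_integer_),
    is_long = length > spec$long_cutoff
  )
}

#' Per-sample summary of low-quality read content and long-fragment content
#'
#' Aggregates the per-read quality table of one sample into the quantities the
#' cross-sample analysis works with: the fraction of pairs with a long
#' fragment, the fraction of low-quality reads per mate, and their R2 minus R1
#' difference. Fractions are computed over pairs with a valid fragment length
#' (invalid template lengths are excluded from numerator and denominator).
#'
#' @param reads Per-read quality tibble from [read_quality_table()] for a
#'   single sample.
#' @param spec A [stratum_spec()].
#' @param lq Which low-quality definition drives `frac_lq_*`:
#'   `"mismatch"` (aligned-base mismatch rate above the cutoff; default) or
#'   `"phred"` (mean Phred below the cutoff).
#' @return One-row tibble: `sample_id`, `n_pairs`, `frac_long`, `frac_lq_r1`,
#'   `frac_lq_r2`, `lq_diff`.
#' @export
summarize_sample <- function(reads, spec = stratum_spec(), lq = c("mismatch", "phred")) {
  lq <- match.arg(lq)
  if (length(unique(reads$sample_id)) > 1L) {
    stop("summarize_sample expects reads of a single sample")
  }
  valid <- reads[!is.na(reads$fragment_length), , drop = FALSE]
  if (nrow(valid) == 0L) stop("empty sample: no reads with a valid fragment length")
  lq_col <- if (lq == "mismatch") valid$lq_mismatch else valid$lq_phred

  pair_len <- valid[valid$mate == "R1", , drop = FALSE]
  # fall back to counting distinct templates when R1 records are absent
  if (nrow(pair_len) == 0L) pair_len <- valid[!duplicated(valid$qname), , drop = FALSE]
  n_pairs <- nrow(pair_len)
  frac_long <- mean(pair_len$fragment_length > spec$long_cutoff)

  is_r1 <- valid$mate == "R1"
  frac_lq_r1 <- mean(lq_col[is_r1])
  frac_lq_r2 <- mean(lq_col[!is_r1])

  tibble::tibble(
    sample_id = valid$sample_id[1],
    n_pairs = n_pairs,
    frac_long = frac_long,
    frac_lq_r1 = frac_lq_r1,
    frac_lq_r2 = frac_lq_r2,
    lq_diff = frac_lq_r2 - frac_lq_r1
  )
}

#' Low-quality fractions per fragment-length stratum
#'
#' @inheritParams summarize_sample
#' @return Long tibble: `sample_id`, `mate`, `stratum`, `stratum_lo`,
#'   `stratum_hi`, `n_reads`, `n_lq`, `frac_lq` (`NA`-masked where `n_reads`
#'   is below `spec$min_stratum_reads`).
#' @export
stratum_table <- function(reads, spec = stratum_spec(), lq = c("mismatch", "phred")) {
  lq <- match.arg(lq)
  valid <- reads[!is.na(reads$fragment_length), , drop = FALSE]
  st <- assign_stratum(valid$fragment_length, spec)
  lq_col <- if (lq == "mismatch") valid$lq_mismatch else valid$lq_phred
  df <- tibble::tibble(
    sample_id = valid$sample_id,
    mate = valid$mate,
    stratum = st$stratum,
    stratum_lo = st$stratum_lo,
    stratum_hi = st$stratum_hi,
    is_lq = lq_col
  )
  out <- df |>
    dplyr::group_by(.data$sample_id, .data$mate, .data$stratum, .drop = FALSE) |>
    dplyr::summarise(
      stratum_lo = .data$stratum_lo[1],
      stratum_hi = .data$stratum_hi[1],
      n_reads = dplyr::n(),
      n_lq = sum(.data$is_lq),
      .groups = "drop"
    )
  # .drop = FALSE keeps empty strata but crosses them with NA lo/hi; restore
  edges <- spec$bin_edges
  labels <- sprintf("[%d,%d)", edges[-length(edges)], edges[-1])
  lo <- c(edges[-length(edges)], NA_integer_)
  hi <- c(edges[-1], NA_integer_)
  m <- match(as.character(out$stratum), c(labels, "overflow"))
  out$stratum_lo <- lo[m]
  out$stratum_hi <- hi[m]
  out$n_lq[is.na(out$n_lq)] <- 0L
  out$frac_lq <- ifelse(out$n_reads >= spec$min_stratum_reads,
                        out$n_lq / out$n_reads, NA_real_)
  out
}

#' Samples-by-strata matrix of low-quality fractions for one mate
#'
#' Arranges per-stratum low-quality fractions as a matrix with one row per
#' sample and one column per fragment-length stratum, the layout of a
#' stratified quality heatmap. Cells below the minimum read count are `NA`.
#'
#' @param strata Long tibble from [stratum_table()], possibly covering many
#'   samples (rows bound together).
#' @param mate `"R1"` or `"R2"`.
#' @param drop_overflow Drop the overflow stratum column (default `TRUE`).
#' @return Numeric matrix, rownames = sample ids, colnames = stratum labels.
#' @export
stratum_matrix <- function(strata, mate = c("R1", "R2"), drop_overflow = TRUE) {
  mate <- match.arg(mate)
  sub <- strata[strata$mate == mate, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for mate ", mate)
  wide <- sub |>
    dplyr::select("sample_id", "stratum", "frac_lq") |>
    tidyr::pivot_wider(names_from = "stratum", values_from = "frac_lq")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  if (drop_overflow && "overflow" %in% colnames(m)) {
    m <- m[, colnames(m) != "overflow", drop = FALSE]
  }
  m
}
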