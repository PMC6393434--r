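#' Spearman rank correlation coefficient
#'
#' Computed as the Pearson correlation of mid-ranks (ties receive average
#' ranks), which handles tied observations exactly.
#'
#' @param x,y Numeric vectors of equal length, at least 2, neither constant.
#' @return The rank correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(rank(x), rank(y))
}

# all permutations of 1..n as an n! x n matrix (n <= 8 kept small on purpose)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

#' Spearman correlation test
#'
#' Two-sided test of rank association. For `n <= exact_n_max` (default 8) the
#' p-value is the exact permutation probability
#' `P(|rho_perm| >= |rho_obs|)` over all `n!` reorderings of one vector;
#' for larger `n` the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom is
#' used. A perfect correlation under the t formula is reported at the exact
#' permutation floor `2 / n!`.
#'
#' @param x,y Numeric vectors, length at least 3.
#' @param alpha Significance level (default 0.05).
#' @param exact_n_max Largest n for exact permutation enumeration.
#' @param comparison Optional label carried into the result row.
#' @return One-row tibble: `comparison`, `rho`, `p_value`, `n`,
#'   `significant` (`p_value < alpha`).
#' @export
spearman_test <- function(x, y, alpha = 0.05, exact_n_max = 8L,
                          comparison = NA_character_) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations for a correlation test")
  rho <- spearman_rho(x, y)

  if (n <= exact_n_max) {
    rx <- rank(x); ry <- rank(y)
    xc <- rx - mean(rx)
    sx <- sqrt(sum(xc^2))
    perms <- all_permutations(n)
    yc <- ry - mean(ry)
    sy <- sqrt(sum(yc^2))
    # rho for permutation p of y is sum_i xc[i] * yc[p[i]] / (sx * sy)
    rho_perm <- (matrix(yc[t(perms)], ncol = n, byrow = TRUE) %*% xc) / (sx * sy)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-12) {
    p <- 2 / factorial(n)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }

  tibble::tibble(
    comparison = comparison,
    rho = rho,
    p_value = p,
    n = n,
    significant = p < alpha
  )
}

#' Cross-sample association of long-fragment content with low-quality reads
#'
#' Runs the three Spearman tests of the analysis over per-sample summaries:
#' the proportion of long fragments against (1) the proportion of low-quality
#' R1 reads, (2) the proportion of low-quality R2 reads, and (3) the R2 minus
#' R1 difference of low-quality proportions. No multiple-testing correction is
#' applied across the three rows.
#'
#' @param summaries Tibble of per-sample rows from [summarize_sample()]
#'   (bound together), needing columns `frac_long`, `frac_lq_r1`,
#'   `frac_lq_r2`, `lq_diff` and at least 3 rows.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with exactly three rows and columns `comparison`, `rho`,
#'   `p_value`, `n`, `significant`.
#' @export
correlation_table <- function(summaries, alpha = 0.05) {
  if (nrow(summaries) < 3L) {
    stop("need at least 3 sample summaries, got ", nrow(summaries))
  }
  dplyr::bind_rows(
    spearman_test(summaries$frac_long, summaries$frac_lq_r1, alpha,
                  comparison = "frac_long vs frac_lq_r1"),
    spearman_test(summaries$frac_long, summaries$frac_lq_r2, alpha,
                  comparison = "frac_long vs frac_lq_r2"),
    spearman_test(summaries$frac_long, summaries$lq_diff, alpha,
                  comparison = "frac_long vs lq_diff")
  )
}
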