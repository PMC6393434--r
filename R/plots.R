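need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting needs the ggplot2 package")
  }
}

#' Density of low-quality read fractions, R1 versus R2
#'
#' @param summaries Per-sample summaries from [summarize_sample()].
#' @return A ggplot object.
#' @export
plot_lq_density <- function(summaries) {
  need_ggplot()
  long <- tidyr::pivot_longer(summaries, c("frac_lq_r1", "frac_lq_r2"),
                              names_to = "mate", values_to = "frac_lq")
  long$mate <- ifelse(long$mate == "frac_lq_r1", "R1", "R2")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frac_lq, colour = .data$mate)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "fraction of low-quality reads", y = "density")
}

#' Excess of low-quality R2 reads versus long-fragment content
#'
#' @param summaries Per-sample summaries.
#' @return A ggplot object.
#' @export
plot_lq_scatter <- function(summaries) {
  need_ggplot()
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$frac_long, y = .data$lq_diff)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of fragments > 500 nt",
                  y = "low-quality fraction, R2 - R1")
}

#' Stratified low-quality heatmap (samples by fragment-length bins)
#'
#' @param strata Long stratum table from [stratum_table()], many samples.
#' @param mate `"R1"` or `"R2"`.
#' @return A ggplot object.
#' @export
plot_stratum_heatmap <- function(strata, mate = c("R1", "R2")) {
  need_ggplot()
  mate <- match.arg(mate)
  sub <- strata[strata$mate == mate & !is.na(strata$stratum_lo), , drop = FALSE]
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$stratum, y = .data$sample_id,
                                    fill = .data$frac_lq)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "fragment-length stratum", y = NULL,
                  fill = "LQ fraction", title = mate)
}

#' Positional mismatch profiles with optional rolling-mean smoothing
#'
#' @param profiles Tibble binding [positional_profile()] outputs (column
#'   `group` distinguishes them).
#' @param smooth_window Odd rolling-mean width for the displayed line, or
#'   `NULL` for raw rates.
#' @return A ggplot object.
#' @export
plot_positional_profiles <- function(profiles, smooth_window = 5L) {
  need_ggplot()
  if (!is.null(smooth_window)) {
    profiles <- profiles |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(rate = rolling_mean(.data$rate, smooth_window)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$cycle, y = .data$rate,
                                         colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sequencing cycle", y = "mismatch rate")
}
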