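# ggplot2 displays for the package's result tables. Each autoplot mirrors
# the field's standard presentation: coefficient dot plots with CI bars for
# CSC/AASC, ranked bar plots for tAI, overlay of data and fitted curve for
# decay fits.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a codon stability coefficient table
#'
#' Dot plot of per-codon CSCs ordered within amino acid, with 95% CI bars
#' and points colored by significance tier.
#'
#' @param object A `csc_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.csc_table <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$amino_acid, .data$csc)
  df$codon <- factor(df$codon, levels = df$codon)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$csc,
                                   color = .data$tier)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_color_manual(
      values = c(stabilizing = "#2166AC", destabilizing = "#B2182B",
                 ns = "grey50"), na.value = "grey80") +
    ggplot2::facet_grid(~amino_acid, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "codon stability coefficient (Pearson R)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot an amino acid stabilization coefficient table
#'
#' @param object An `aasc_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.aasc_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$aa <- factor(df$aa, levels = df$aa[order(df$aasc)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa, y = .data$aasc,
                                   color = .data$tier)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(
      values = c(stabilizing = "#2166AC", destabilizing = "#B2182B",
                 ns = "grey50"), na.value = "grey80") +
    ggplot2::labs(x = "amino acid",
                  y = "amino acid stabilization coefficient (Pearson R)") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot a tAI table
#'
#' Ranked bar plot of per-codon tAI values colored by the median-rule
#' optimality call, with the median marked.
#'
#' @param object A `tai_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tai_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$codon <- factor(df$codon, levels = df$codon[order(-df$tai)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$tai,
                                   fill = .data$optimal)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = median(df$tai), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#7B3294", `FALSE` = "#008837"),
                               labels = c(`TRUE` = "optimal", `FALSE` = "non-optimal"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "tRNA adaptation index") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot decay trajectories with their fitted curves
#'
#' @param tc A `decay_timecourse`.
#' @param estimates Tibble from [fit_halflives()].
#' @param ids Transcripts to show (default: the first 6).
#' @param doubling_time Doubling time used in the fits.
#' @return A ggplot object.
#' @export
plot_decay_fits <- function(tc, estimates, ids = NULL, doubling_time = 15) {
  stopifnot(inherits(tc, "decay_timecourse"))
  if (is.null(ids)) ids <- head(unique(tc$abundance$transcript_id), 6L)
  obs <- dplyr::filter(tc$abundance, .data$transcript_id %in% ids)
  est <- dplyr::filter(estimates, .data$transcript_id %in% ids, .data$fit_ok)
  tgrid <- seq(0, max(tc$timepoints), length.out = 100L)
  dil <- if (is.finite(doubling_time)) log(2) / doubling_time else 0
  curves <- tidyr::crossing(est[, c("transcript_id", "decay_rate")],
                            time = tgrid) |>
    dplyr::mutate(abundance = 100 * exp(-(.data$decay_rate + dil) * .data$time))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time, y = .data$abundance)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = curves, color = "#B2182B") +
    ggplot2::facet_wrap(~transcript_id) +
    ggplot2::labs(x = "chase time (h)", y = "abundance (% of t0)") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot stratified half-life distributions
#'
#' Box-style summary (median and interquartile box) of the per-bin
#' half-life distributions from [stratify_halflives()], annotated with the
#' per-bin n.
#'
#' @param strat Result of [stratify_halflives()].
#' @return A ggplot object.
#' @export
plot_stratified <- function(strat) {
  df <- strat$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q1,
                                        ymax = .data$q3),
                           fill = "grey85", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(y = .data$q3, label = .data$n),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "covariate bin", y = "half-life (h)",
                  subtitle = sprintf("Kruskal-Wallis p = %.3g", strat$p_value)) +
    ggplot2::theme_minimal(base_size = 10)
}
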