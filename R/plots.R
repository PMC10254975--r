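#' Quantile-quantile plot of association p-values
#'
#' Observed versus expected -log10 p-values under the uniform null, with
#' the genomic inflation factor in the subtitle.
#'
#' @param p Vector of p-values, or a `moderated_fit`.
#' @return A ggplot object.
#' @export
plot_qq <- function(p) {
  if (inherits(p, "moderated_fit")) p <- p$table$p
  lambda <- genomic_inflation(pmax(p, .Machine$double.xmin))
  n <- length(p)
  df <- tibble::tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(p))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = "Association QQ plot",
      subtitle = sprintf("genomic inflation factor λ = %.2f", lambda)
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a moderated association scan
#'
#' @param mod A `moderated_fit` (or its `tidy()` tibble).
#' @param fdr_cutoff Highlighting threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(mod, fdr_cutoff = 0.05) {
  tab <- if (inherits(mod, "moderated_fit")) mod$table else mod
  tab$significant <- tab$fdr < fdr_cutoff
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$coef,
                                    y = -log10(.data$fdr),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "coefficient (exposed vs unexposed)",
                  y = expression(-log[10](FDR))) +
    ggplot2::theme_minimal()
}

#' Plot rotation gene set test results
#'
#' Bar chart of -log10 FDR per set and hypothesis.
#'
#' @param object A `roast_result` from [roast_all_sets()].
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.roast_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "set",
                  dplyr::starts_with("FDR.")),
    cols = dplyr::starts_with("FDR."),
    names_to = "hypothesis", names_prefix = "FDR\\.",
    values_to = "fdr"
  )
  long <- long[!is.na(long$fdr), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$set,
                                     y = -log10(.data$fdr),
                                     fill = .data$hypothesis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](FDR))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
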