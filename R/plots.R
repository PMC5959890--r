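#' QQ plot of GWAS p-values
#'
#' Observed versus expected -log10 p-values under the uniform null, with
#' the genomic inflation factor in the subtitle.
#'
#' @param p Vector of p-values.
#' @return A ggplot object.
#' @export
qq_plot <- function(p) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  p <- sort(p[is.finite(p) & p > 0 & p <= 1])
  df <- data.frame(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(p)
  )
  lam <- genomic_inflation(p = p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  subtitle = sprintf("lambda = %.3f", lam)) +
    ggplot2::theme_minimal()
}

#' Manhattan plot
#'
#' @param stats Table with `chr`, `bp` and a p-value column.
#' @param sig_line Genome-wide significance line (default 5e-8).
#' @param suggestive_line Suggestive line (default 1e-5).
#' @return A ggplot object.
#' @export
manhattan_plot <- function(stats, sig_line = 5e-8, suggestive_line = 1e-5) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  p <- get_pcol(stats)
  df <- data.frame(chr = factor(stats$chr), bp = stats$bp, logp = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bp, y = .data$logp,
                                   colour = .data$chr)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(sig_line), colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(suggestive_line),
                        colour = "blue") +
    ggplot2::facet_grid(~ chr, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}
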