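#' Plot a fitted ITC isotherm
#'
#' Observed per-injection heats against molar ratio with the fitted
#' one-site curve overlaid.
#'
#' @param x A `one_site_fit` with a `fitted` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot one_site_fit
#' @export
autoplot.one_site_fit <- function(x, ...) {
  if (is.null(x$fitted)) abort("fit did not converge; nothing to plot")
  df <- x$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_uJ), shape = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$heat_uJ), colour = "firebrick") +
    ggplot2::labs(x = "Molar ratio (ligand / macromolecule)",
                  y = "Injection heat (µJ)",
                  title = sprintf("One-site fit: Kd = %.3g M, n = %.2f",
                                  x$params$Kd, x$params$n)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Conservation profile plot
#'
#' Information content (bits) per reference position, a bar-style stand-in
#' for a sequence logo; signature positions can be highlighted.
#'
#' @param ic Tibble from [information_content()].
#' @param highlight Integer positions to mark (e.g. the signature).
#' @return A ggplot object.
#' @export
plot_information_content <- function(ic, highlight = integer()) {
  ic$highlighted <- ic$position %in% highlight
  ggplot2::ggplot(ic, ggplot2::aes(x = .data$position, y = .data$ic_bits,
                                   fill = .data$highlighted)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "darkcyan")) +
    ggplot2::labs(x = "Reference position", y = "Information content (bits)") +
    ggplot2::theme_minimal()
}

#' Class / phylum rollup plot
#'
#' @param counts Tibble from [rollup()].
#' @return A ggplot object.
#' @export
plot_rollup <- function(counts) {
  key <- setdiff(names(counts), "n")[1]
  counts[[key]] <- factor(counts[[key]], levels = rev(counts[[key]]))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$n, y = .data[[key]])) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "Proteins", y = NULL) +
    ggplot2::theme_minimal()
}
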