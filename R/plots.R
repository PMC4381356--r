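# ggplot2 views of the result objects.

#' Volcano plot of a differential expression result
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  d <- as_tibble(object)
  th <- attr(object, "thresholds")
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fc, -log10(.data$p),
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-th[["lfc"]], th[["lfc"]]),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", unchanged = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = paste(attr(object, "contrast")[2L], "vs",
                                attr(object, "contrast")[1L])) +
    ggplot2::theme_minimal()
}

#' Fold change versus Splicing Index Ratio for tested bins
#'
#' @param object A `splicing_result`.
#' @param ... Unused.
#' @return A ggplot, faceted by bin family.
#' @export
autoplot.splicing_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fc, .data$log2_sir,
                                  colour = .data$altered)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~table) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "log2 FC (bin density)", y = "log2 Splicing Index Ratio") +
    ggplot2::theme_minimal()
}

#' Representation-factor dot plot
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$rf, .data$category_id,
                                  size = .data$k, colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "representation factor", y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}

#' Per-position nucleotide frequencies and representation factors
#'
#' Foreground frequencies are drawn as stacked bars per position
#' (a pictogram-style summary); cells whose representation factor departs
#' from 1 at `p <= 0.05` are outlined.
#'
#' @param object A `site_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.site_matrix <- function(object, ...) {
  d <- as_tibble(object)
  d$flag <- !is.na(d$p) & d$p <= 0.05
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$fg_freq,
                                  fill = .data$nucleotide)) +
    ggplot2::geom_col(ggplot2::aes(linetype = .data$flag), colour = "black",
                      linewidth = 0.2, width = 0.85) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "blank"),
                                   guide = "none") +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255c99",
                                          G = "#f7b32b", T = "#d62839")) +
    ggplot2::labs(x = "position", y = "frequency",
                  title = paste(attr(object, "site_type"), "site")) +
    ggplot2::theme_minimal()
}
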