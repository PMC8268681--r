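#' Volcano plot of differential isoform usage
#'
#' Each point is one testable isoform: usage change (dIF) against
#' significance (-log10 q); members of called switch pairs are highlighted.
#'
#' @param object A `switch_fit` from [detect_switches()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.switch_fit <- function(object, ...) {
  t <- dplyr::filter(object$tests, !is.na(.data$q_value))
  members <- unique(c(object$pairs$up_isoform, object$pairs$down_isoform))
  t$switch_member <- t$transcript_id %in% members
  ggplot2::ggplot(t, ggplot2::aes(x = .data$dIF,
                                  y = -log10(.data$q_value),
                                  colour = .data$switch_member)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$params$dIF_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$params$q_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "switch pair member") +
    ggplot2::labs(
      x = "dIF (isoform fraction change)",
      y = expression(-log[10] ~ "q"),
      title = paste("Differential isoform usage:", object$contrast[[1]],
                    "vs", object$contrast[[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of consequence-category asymmetries
#'
#' The fraction of switch genes per consequence category, the visual
#' summary of which structural changes dominate among up-regulated
#' isoforms.
#'
#' @param summary Output of [summarize_consequences()].
#' @return A ggplot object.
#' @export
plot_consequence_summary <- function(summary) {
  s <- dplyr::filter(summary, .data$genes_affected + .data$genes_opposite > 0)
  s$signif <- s$asymmetry_p < 0.05
  ggplot2::ggplot(s, ggplot2::aes(x = .data$fraction_of_genes,
                                  y = stats::reorder(.data$category,
                                                     .data$fraction_of_genes),
                                  fill = .data$signif)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               name = "asymmetry p < 0.05") +
    ggplot2::labs(x = "fraction of genes", y = NULL,
                  title = "Consequences of isoform switches") +
    ggplot2::theme_minimal()
}

#' Jaccard co-occurrence plot
#'
#' Mutated-sample fraction against the Jaccard index per switched isoform;
#' isoforms whose index is significant against the length-matched null
#' (z above the threshold) are highlighted. Strong switch-mutation
#' associations sit in the upper right.
#'
#' @param results Output of [jaccard_zscore()].
#' @return A ggplot object.
#' @export
plot_jaccard <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$j,
                                        y = .data$mutated_fraction,
                                        colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 name = "z > threshold") +
    ggplot2::labs(x = "Jaccard index (switch vs mutation samples)",
                  y = "fraction of mutated samples",
                  title = "Switch-mutation co-occurrence") +
    ggplot2::theme_minimal()
}
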