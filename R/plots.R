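# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an enrichment result
#'
#' Mean control vs mean treatment abundance on log10 axes (a floor of half
#' the smallest nonzero abundance stands in for zeros so control-absent
#' entities stay visible), coloured by filter outcome.
#'
#' @param object an `enrichment_result`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.enrichment_result <- function(object, ...) {
  tab <- tidy(object)
  floor_val <- min(c(tab$mean_treatment[tab$mean_treatment > 0],
                     tab$mean_control[tab$mean_control > 0])) / 2
  tab <- tab |>
    dplyr::mutate(
      mt = pmax(.data$mean_treatment, floor_val),
      mc = pmax(.data$mean_control, floor_val),
      outcome = ifelse(.data$passes, "pass", .data$fail_reason)
    )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mc, y = .data$mt,
                                    colour = .data$outcome)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "mean control abundance", y = "mean treatment abundance",
      colour = NULL,
      title = paste0("Subtractive ", attr(object, "level"), " filter (fold >= ",
                     signif(attr(object, "fold_threshold"), 3), ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a residue composition
#' @param object a `residue_composition`
#' @param ... unused
#' @return a ggplot bar chart of pS/pT/pY percentages
#' @export
autoplot.residue_composition <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$residue, y = .data$pct,
                                    fill = .data$residue)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "phospho-acceptor residue", y = "% of sites") +
    ggplot2::theme_minimal()
}

#' Plot residue composition across hop bands
#'
#' Stacked percentage bars per cumulative hop band, showing how the
#' phosphotyrosine share changes with distance from the seed protein.
#'
#' @param hopcomp output of [hop_composition()]
#' @param band `"cumulative"` (default) or `"exact"`
#' @return a ggplot
#' @export
plot_hop_composition <- function(hopcomp, band = "cumulative") {
  tab <- hopcomp |>
    dplyr::filter(.data$band == !!band) |>
    tidyr::pivot_longer(dplyr::all_of(c("pS", "pT", "pY")),
                        names_to = "residue", values_to = "pct") |>
    dplyr::mutate(residue = sub("^p", "", .data$residue))
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$hop), y = .data$pct,
                                    fill = .data$residue)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = paste0("hop band (", band, ")"), y = "% of sites",
                  fill = "residue") +
    ggplot2::theme_minimal()
}

#' Plot enriched terms
#' @param object an `enriched_terms` tibble
#' @param top number of terms to show (default 15)
#' @param ... unused
#' @return a ggplot of -log10 corrected p per term
#' @export
autoplot.enriched_terms <- function(object, top = 15, ...) {
  tab <- tibble::as_tibble(object) |>
    dplyr::slice_min(.data$p_corrected, n = top, with_ties = FALSE)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$neg_log10_p_corrected,
    y = stats::reorder(.data$name, .data$neg_log10_p_corrected),
    fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ "corrected P"), y = NULL,
                  fill = "significant") +
    ggplot2::theme_minimal()
}
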