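# ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gene model architecture
#'
#' Draws the N-terminal, repeat units and C-terminal as scaled boxes, the
#' familiar schematic of spidroin architecture.
#'
#' @param object A `gene_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gene_model <- function(object, ...) {
  td <- tidy(object)
  td$class <- dplyr::case_when(td$region == "n_term" ~ "N-terminal",
                               td$region == "c_term" ~ "C-terminal",
                               TRUE ~ "repeat")
  ggplot2::ggplot(td, ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                   ymin = 0, ymax = 1,
                                   fill = .data$class)) +
    ggplot2::geom_rect(color = "grey20", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`N-terminal` = "#E69F00",
                                          `repeat` = "grey85",
                                          `C-terminal` = "#56B4E9")) +
    ggplot2::labs(x = "ORF position (nt)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}

#' Plot a positional conservation profile
#'
#' Per-column bars colored by conservation band (full / majority /
#' minority identity), with domain annotations drawn underneath when
#' present.
#'
#' @param object A `positional_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.positional_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$band <- cut(df$frac_identical, c(-Inf, 1 / 3, 2 / 3, 0.999, Inf),
                 labels = c("low", "minority", "majority", "full"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$column,
                                        y = .data$frac_identical,
                                        fill = .data$band)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(full = "#1B9E77",
                                          majority = "#E6C229",
                                          minority = "#D95F02",
                                          low = "#A6761D")) +
    ggplot2::labs(x = "alignment column", y = "fraction identical",
                  fill = NULL) +
    ggplot2::theme_minimal()
  domains <- attr(object, "domains")
  if (!is.null(domains)) {
    p <- p + ggplot2::geom_rect(
      data = domains, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start + 0.5, xmax = .data$end + 0.5),
      ymin = -0.12, ymax = -0.04, fill = "grey40") +
      ggplot2::geom_text(
        data = domains, inherit.aes = FALSE,
        ggplot2::aes(x = (.data$start + .data$end) / 2,
                     label = .data$label),
        y = -0.2, size = 2.6)
  }
  p
}

#' Heatmap of a pairwise identity matrix
#'
#' @param m An [identity_matrix()].
#' @return A ggplot.
#' @export
plot_identity_heatmap <- function(m) {
  stopifnot(inherits(m, "identity_matrix"))
  df <- tidy(m)
  lv <- rownames(m)
  df$id_a <- factor(df$id_a, levels = lv)
  df$id_b <- factor(df$id_b, levels = rev(lv))
  ggplot2::ggplot(df, ggplot2::aes(.data$id_a, .data$id_b,
                                   fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(df$identity), 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% identity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
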