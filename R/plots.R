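#' Plot the entropy table by condition
#'
#' Boxplots of per-recording median entropy for the four behavioral
#' conditions, faceted by region and side.
#'
#' @param object An `entropy_tbl` (see [entropy_table()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.entropy_tbl <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    state = factor(.data$state, c("rest", "cycling")),
    eyes = factor(.data$eyes, c("open", "closed")),
    region = factor(.data$region, c("F", "C", "P", "O"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$median_entropy,
                                   fill = .data$eyes)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_grid(ggplot2::vars(.data$side),
                        ggplot2::vars(.data$region)) +
    ggplot2::labs(x = NULL, y = "median entropy (nats)", fill = "eyes") +
    ggplot2::theme_minimal()
}

#' Plot per-segment entropies of one recording
#'
#' @param object An `rme_entropy` (see [median_entropy()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rme_entropy <- function(object, ...) {
  ggplot2::ggplot(object$segments,
                  ggplot2::aes(x = .data$index, y = .data$S)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$median_S, linetype = 2) +
    ggplot2::labs(x = "segment", y = "S_max (nats)") +
    ggplot2::theme_minimal()
}

#' Topographic tile map of median entropy
#'
#' Tabular stand-in for an interpolated scalp map: one tile per channel
#' position, faceted by condition; the scientific content is the ordering of
#' the 32 cell values.
#'
#' @param topo Output of [topo_summary()].
#' @param value Column to map to fill (`"median_entropy"` or
#'   `"mean_entropy"`).
#' @return A ggplot object.
#' @export
plot_topo <- function(topo, value = "median_entropy") {
  df <- dplyr::mutate(
    topo,
    region = factor(.data$region, c("F", "C", "P", "O")),
    side = factor(.data$side, c("left", "right")),
    state = factor(.data$state, c("rest", "cycling")),
    eyes = factor(.data$eyes, c("open", "closed"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$side, y = .data$region,
                                   fill = .data[[value]])) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(c("F", "C", "P", "O"))) +
    ggplot2::facet_grid(ggplot2::vars(.data$state),
                        ggplot2::vars(.data$eyes)) +
    ggplot2::scale_fill_viridis_c(name = "entropy\n(nats)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
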