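#' Plot a precision-recall point for one or more evaluations
#'
#' @param object A `binding_eval`, or a tibble of [glance()]d evaluations
#'   (columns `recall`, `precision`, optionally `complex`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binding_eval <- function(object, ...) {
  plot_precision_recall(glance(object))
}

#' @rdname autoplot.binding_eval
#' @param data Tibble with `recall` and `precision` columns (one row per
#'   receptor/agonist complex; an optional `complex` column labels points).
#' @export
plot_precision_recall <- function(data) {
  data <- as_tibble(data)
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_point(size = 3, alpha = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
  if ("complex" %in% names(data)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$complex),
                                nudge_y = 0.04, size = 3)
  }
  p
}

#' Plot a residue-residue contact map
#'
#' @param cm A `contact_map`.
#' @return A ggplot tile plot over sequence numbers.
#' @export
plot_contact_map <- function(cm) {
  df <- as_tibble(cm)
  both <- bind_rows(
    select(df, i = "seqnum_i", j = "seqnum_j", "min_dist"),
    select(df, i = "seqnum_j", j = "seqnum_i", "min_dist")
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$i, y = .data$j,
                                     fill = .data$min_dist)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "min side-chain\ndistance (Å)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Residue", y = "Residue") +
    ggplot2::theme_minimal()
}

#' Plot rewiring involvement per generic position
#'
#' @param object A `rewiring_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of involvement counts.
#' @export
autoplot.rewiring_report <- function(object, ...) {
  inv <- object$involvement
  ggplot2::ggplot(inv, ggplot2::aes(
    x = stats::reorder(.data$generic, -.data$count), y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Generic position",
                  y = "Rewired pairs involving position") +
    ggplot2::theme_minimal()
}

#' Plot conservation percentages at generic positions
#'
#' @param data A tibble binding [conservation_at()] rows.
#' @return A ggplot bar chart.
#' @export
plot_conservation <- function(data) {
  data <- as_tibble(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$generic,
                                     y = .data$percentage)) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "Generic position", y = "Conservation (%)") +
    ggplot2::theme_minimal()
}
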