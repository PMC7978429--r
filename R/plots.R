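# ggplot2 displays for the main result types.

#' Plot a moment-arm curve
#'
#' @param object A `moment_arm_curve` from [sweep_rom()] (rows from several
#'   sweeps may be bound together).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moment_arm_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta_deg, y = .data$moment_arm_mm,
                                       colour = .data$mtu)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_grid(dplyr::vars(.data$joint), dplyr::vars(.data$dof)) +
    ggplot2::labs(x = "joint angle (deg)", y = "moment arm (mm)",
                  colour = "MTU") +
    ggplot2::theme_minimal()
}

#' Plot ancestral state estimates with confidence bands
#'
#' @param object An `ace_table` from [ace_all()] (or a tidied `ace_fit`).
#' @param node_order Node display order.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ace_table <- function(object, node_order = c(main_line_nodes(), "Dromaeosauridae"),
                               ...) {
  d <- object |>
    dplyr::filter(.data$node %in% node_order) |>
    dplyr::mutate(node = factor(.data$node, levels = node_order))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$node, y = .data$estimate,
                                  group = .data$mtu, colour = .data$mtu)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci95_lo, ymax = .data$ci95_hi,
                                      fill = .data$mtu), alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(dplyr::vars(.data$joint, .data$dof),
                        dplyr::vars(.data$tree), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean normalized moment arm (ACE)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot summed moment-arm ratio series across nodes
#'
#' @param object A `ratio_series` (rows from several hypotheses/tree
#'   variants may be bound together).
#' @param node_order Node display order.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ratio_series <- function(object, node_order = c(main_line_nodes(), "Dromaeosauridae"),
                                  ...) {
  d <- object |>
    dplyr::filter(.data$node %in% node_order) |>
    dplyr::mutate(node = factor(.data$node, levels = node_order))
  mapping <- if ("tree" %in% names(d)) {
    ggplot2::aes(x = .data$node, y = .data$ratio, group = .data$tree,
                 colour = .data$tree)
  } else {
    ggplot2::aes(x = .data$node, y = .data$ratio, group = 1)
  }
  ggplot2::ggplot(d, mapping) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(dplyr::vars(.data$hypothesis), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "ratio of summed |ACE| moment arms") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
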