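#' Volcano plot of a DEG table
#'
#' @param object A `deg_table` from [call_degs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(object, ...) {
  th <- attr(object, "thresholds") %||% thresholds()
  df <- as_tibble(object) |>
    mutate(neg_log10_p = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, .data$neg_log10_p, colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#27ae60", ns = "grey70")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * th$lfc_threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(th$p_threshold), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value", colour = NULL)
}

#' Quadrant sizes of a regulon partition
#'
#' @param object A `regulon_partition` from [classify_degs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regulon_partition
#' @export
autoplot.regulon_partition <- function(object, ...) {
  df <- as_tibble(object) |> count(.data$quadrant)
  ggplot2::ggplot(df, ggplot2::aes(.data$quadrant, .data$n)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::labs(
      x = NULL, y = "genes",
      title = sprintf("DEGs by binding (%s mode)", attr(object, "mode"))
    )
}

#' Accessibility labels of ChIP units
#'
#' @param object An `accessibility_summary` from [chip_da_overlap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accessibility_summary
#' @export
autoplot.accessibility_summary <- function(object, ...) {
  df <- tibble(
    label = c("increased", "decreased", "unchanged"),
    n = c(object$n_increased, object$n_decreased, object$n_unchanged)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$n, fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(
      increased = "#c0392b", decreased = "#2980b9", unchanged = "grey70"
    )) +
    ggplot2::labs(x = "chromatin accessibility", y = "binding units")
}

#' Per-quadrant TF-target coverage
#'
#' @param object A `tf_contribution` from [tf_contribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tf_contribution
#' @export
autoplot.tf_contribution <- function(object, ...) {
  ggplot2::ggplot(object$quadrants,
                  ggplot2::aes(.data$quadrant, .data$pct_covered)) +
    ggplot2::geom_col(fill = "#8e44ad") +
    ggplot2::geom_hline(yintercept = object$overall$pct_covered, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "% DEGs covered by core-TF targets")
}
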