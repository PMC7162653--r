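# Convenience ggplot2 output for the main result types.

#' @describeIn connection_probability plot estimates with exact intervals.
#' @param object a `cp_table` from [connection_probability()].
#' @param ... unused.
#' @export
autoplot.cp_table <- function(object, ...) {
  object$label <- interaction(
    object[, setdiff(names(object),
                     c("k", "n", "p_hat", "ci_low", "ci_high", "label")),
           drop = FALSE],
    sep = " ", drop = TRUE)
  if (length(levels(object$label)) == 0) object$label <- "all"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$label, y = .data$p_hat)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "Connection probability",
                  caption = "Error bars: 95% Clopper-Pearson intervals") +
    ggplot2::theme_minimal()
}

#' @describeIn log_ratio_table heatmap of smoothed log2 ratios by connection
#'   type (requires `pre_layer`/`post_layer` columns).
#' @param object a `log_ratio_table`.
#' @param ... unused.
#' @export
autoplot.log_ratio_table <- function(object, ...) {
  if (!all(c("pre_layer", "post_layer") %in% names(object))) {
    abort("Heatmap needs pre_layer/post_layer columns.")
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$post_layer,
                                       y = .data$pre_layer,
                                       fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$log2_ratio,
                      ifelse(.data$significant, "*", "")))) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "Postsynaptic layer", y = "Presynaptic layer",
                  fill = "log2 ratio\n(related / unrelated)") +
    ggplot2::theme_minimal()
}

#' @describeIn power_grid power as a function of fold change, one curve per
#'   lineage count, with the inferred-fold-change trace overlaid when
#'   supplied.
#' @param object a `power_grid` tibble.
#' @param trace optional [inferred_fc_trace()] result drawn as points.
#' @param ... unused.
#' @export
autoplot.power_grid <- function(object, trace = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$fc, y = .data$power,
                                    group = .data$n_lineages,
                                    colour = factor(.data$n_lineages))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::labs(x = "Fold change (same-RGC vs unrelated)",
                  y = "Power (two-sided)", colour = "Lineages N") +
    ggplot2::theme_minimal()
  if (!is.null(trace)) {
    p <- p + ggplot2::geom_point(data = trace, colour = "red", size = 2)
  }
  p
}

#' Plot mapped query cells on the reference embedding
#'
#' @param positions a tibble from [map_cells_knn()], optionally joined with
#'   the `precision` column of [mapping_precision_bootstrap()].
#' @param embedding the reference embedding (`cell_id`, `dim1`, `dim2`).
#' @return a ggplot object: reference cells in grey, query cells sized by
#'   mapping precision when available (more precise = larger).
#' @export
plot_mapping <- function(positions, embedding) {
  p <- ggplot2::ggplot(embedding, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::geom_point(colour = "grey70", size = 0.5)
  if ("precision" %in% names(positions)) {
    p <- p + ggplot2::geom_point(
      data = positions,
      ggplot2::aes(size = pmax(0.5, 3 - .data$precision / 5)),
      colour = "black", show.legend = FALSE)
  } else {
    p <- p + ggplot2::geom_point(data = positions, colour = "black")
  }
  p + ggplot2::labs(x = "Embedding 1", y = "Embedding 2") +
    ggplot2::theme_minimal()
}
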