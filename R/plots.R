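#' Plot a shift function
#'
#' Decile distance D(q) with its bootstrap confidence band: positive-slope
#' curves (negative D in the lower deciles, positive in the upper) indicate
#' greater male spread.
#'
#' @param object A `brainvar_shift` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.brainvar_shift <- function(object, ...) {
  tbl <- object$table
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$q, y = .data$D)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$sig), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "CI excludes 0") +
    ggplot2::labs(x = "quantile q", y = "D(q) = Q_m(q) - Q_f(q)",
                  subtitle = paste0("classification: ", object$classification)) +
    ggplot2::theme_minimal()
}

#' Plot per-measure log variance ratios
#'
#' @param object A `brainvar_vartest` result.
#' @param ... Unused.
#' @return A ggplot: measures ordered by log VR, filled by FDR significance.
#' @export
autoplot.brainvar_vartest <- function(object, ...) {
  tbl <- tidy(object)
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = stats::reorder(.data$measure_id, .data$log_vr), y = .data$log_vr,
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~ .data$measure_class, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log variance ratio (male / female)",
                  fill = "FDR significant") +
    ggplot2::theme_minimal()
}

#' Plot an anatomical-correlation difference matrix
#'
#' Heatmap of the male-minus-female correlation difference; edges passing
#' the permutation test are outlined.
#'
#' @param object A `brainvar_homogeneity` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.brainvar_homogeneity <- function(object, ...) {
  e <- object$edges
  ggplot2::ggplot(e, ggplot2::aes(x = .data$region_i, y = .data$region_j,
                                  fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = e[e$sig, ], colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(low = "firebrick", high = "steelblue",
                                  name = "M - F") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}
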