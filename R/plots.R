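#' Plot an abundance table
#'
#' Horizontal bar chart of read densities, facetted by domain when the table
#' was normalised within domains.
#'
#' @param object An `abundance_table` from [aggregate_taxa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot abundance_table
#' @export
autoplot.abundance_table <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = stats::reorder(.data$taxon, .data$density),
                 y = .data$density)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Read density (%)",
      title = sprintf("%s-level read density", attr(object, "rank"))
    ) +
    ggplot2::theme_minimal()
  if ("domain" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~domain, scales = "free_y")
  }
  p
}

#' Plot a qPCR standard curve
#'
#' @param object A `standard_curve` with an underlying fit (from
#'   [fit_standard_curve()]), or a parametric curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::labs(
      x = "log10(gene copies)", y = "Ct",
      subtitle = sprintf("slope %.4f, efficiency %.1f%%%s",
                         object$slope, object$efficiency_percent,
                         if (is.na(object$r_squared)) "" else
                           sprintf(", R² = %.4f", object$r_squared))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$model)) {
    df <- object$model$model
    names(df) <- c("ct", "log10_copies")
    p <- p + ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = .data$log10_copies, y = .data$ct),
      colour = "steelblue"
    )
  }
  p
}

#' Plot mock-community ratios per cycle arm
#'
#' Grouped bars of the normalised post-PCR clone ratios (mean over
#' replicates, with standard-error bars), with the input mixture ratio as a
#' reference point per clone.
#'
#' @param object A `mock_community_sim` from [simulate_mock_community()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mock_community_sim
#' @export
autoplot.mock_community_sim <- function(object, ...) {
  summ <- summarise_mock_ratios(object)
  ggplot2::ggplot(
    summ,
    ggplot2::aes(x = .data$clone, y = .data$ratio_mean,
                 fill = factor(.data$cycles))
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ratio_mean - .data$ratio_se,
                   ymax = .data$ratio_mean + .data$ratio_se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$ratio_initial),
                        shape = 4, size = 2, show.legend = FALSE) +
    ggplot2::labs(x = "Clone", y = "Normalised ratio (min clone = 1)",
                  fill = "PCR cycles",
                  caption = "x = input mixture ratio") +
    ggplot2::theme_minimal()
}

#' Plot per-taxon primer mismatch ratios
#'
#' @param summary Output of [taxon_mismatch_ratio()].
#' @param orientation Which ratio column to plot:
#'   `"reads_per_event"` or `"events_per_read"`.
#' @return A ggplot object.
#' @export
plot_mismatch_ratios <- function(summary,
                                 orientation = c("reads_per_event",
                                                 "events_per_read")) {
  orientation <- match.arg(orientation)
  col <- paste0("ratio_", orientation)
  df <- summary[!is.na(summary[[col]]), , drop = FALSE]
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = stats::reorder(.data$taxon, .data[[col]]),
                 y = .data[[col]])
  ) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = if (orientation == "reads_per_event") {
        "Reads with primer site per mismatch/indel event"
      } else {
        "Mismatch/indel events per read with events"
      }
    ) +
    ggplot2::theme_minimal()
}
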