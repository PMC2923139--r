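# Plotting helpers (ggplot2).

#' Plot the organism confidence-score curves
#'
#' One curve per full-name length `L`, showing the base score assigned to a
#' longest match of `l` words (no co-occurrence bonus): linear from 40
#' points at `l = 1` to 100 points at `l = L`.
#'
#' @param L Integer vector of full-name lengths (default 2:10).
#' @return A ggplot object.
#' @export
plot_confidence_curves <- function(L = 2:10) {
  grid <- tidyr::crossing(L = as.integer(L), l = 1:max(L))
  grid <- dplyr::filter(grid, .data$l <= .data$L)
  grid <- dplyr::mutate(grid, cs = organism_confidence(.data$L, .data$l))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$l, y = .data$cs,
                                     colour = factor(.data$L), group = .data$L)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = 1:max(L)) +
    ggplot2::labs(x = "matched variant length l (words)",
                  y = "confidence score (points)",
                  colour = "organism name\nlength L") +
    ggplot2::theme_minimal()
}

#' Bar chart of detection metrics
#'
#' @param object A `prx_detection_eval`.
#' @param ... Unused.
#' @return A ggplot object showing precision, recall (percent) and
#'   F-measure (scaled to percent for display).
#' @export
autoplot.prx_detection_eval <- function(object, ...) {
  df <- tibble::tibble(
    metric = factor(c("precision", "recall", "F-measure"),
                    levels = c("precision", "recall", "F-measure")),
    value = c(object$precision, object$recall, 100 * object$f_measure)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}

#' Bar chart of rule firings in a refinement
#'
#' @param object A `prx_refinement`.
#' @param ... Unused.
#' @return A ggplot object of firing counts per rule.
#' @export
autoplot.prx_refinement <- function(object, ...) {
  df <- dplyr::count(object$trace, .data$rule)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rule, y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "rule", y = "firings") +
    ggplot2::theme_minimal()
}

#' Per-document phase counts of a pipeline run
#'
#' @param object A `prx_run`.
#' @param ... Unused.
#' @return A ggplot object: candidates vs surviving sequences per document.
#' @export
autoplot.prx_run <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$counts[, c("paper_id", "candidates", "sequences")],
    cols = c("candidates", "sequences"),
    names_to = "phase", values_to = "n"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$paper_id, y = .data$n, fill = .data$phase)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
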