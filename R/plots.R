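#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_col
#'   geom_point labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a PMF profile with its 1-sigma band
#'
#' @param object A `pmf_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot(d, aes(x = .data$x, y = .data$G))
  if (any(is.finite(d$sigma)))
    p <- p + geom_ribbon(aes(ymin = .data$G - .data$sigma,
                             ymax = .data$G + .data$sigma),
                         fill = "grey80")
  p + geom_line(colour = "purple4") +
    labs(x = "COM separation (nm)", y = "G (kJ/mol)",
         title = sprintf("PMF, dG_binding = %.1f kJ/mol", object$dg_binding)) +
    theme_minimal()
}

#' Plot cluster populations
#'
#' @param object A `cluster_assignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_assignment <- function(object, ...) {
  ggplot(tidy(object), aes(x = factor(.data$cluster), y = .data$population)) +
    geom_col(fill = "steelblue") +
    labs(x = "cluster (1 = most populated)", y = "fractional population",
         title = sprintf("RMSD-cutoff clustering (%.2f nm)", object$cutoff)) +
    theme_minimal()
}

#' Plot a salt-bridge contact series
#'
#' @param series A `contact_series` from [salt_bridge_series()].
#' @param exist_cut Threshold line to draw, nm.
#' @return A ggplot of minimum distance vs frame, one line per pair.
#' @export
plot_contacts <- function(series, exist_cut = 1.0) {
  ggplot(as_tibble(series),
         aes(x = .data$time, y = .data$min_distance, colour = .data$pair)) +
    geom_line() +
    ggplot2::geom_hline(yintercept = exist_cut, linetype = 2) +
    labs(x = "time (ns)", y = "minimum distance (nm)",
         title = "salt-bridge monitors (dashed: existence threshold)") +
    theme_minimal()
}
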