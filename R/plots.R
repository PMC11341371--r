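# ggplot2 visualisations for the main result types.

#' Plot a per-base attention profile
#'
#' @param object A `base_attention_profile`.
#' @param threshold Optional horizontal reference line (e.g. the
#'   region-calling threshold).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot base_attention_profile
#' @export
autoplot.base_attention_profile <- function(object, threshold = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$normalized)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = sprintf("%s position (bp)", object$role),
                  y = "normalized attention") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "grey40")
  }
  p
}

#' Plot the metric trace of a fine-tuned classifier
#'
#' @param object An `epi_classifier`.
#' @param ... Unused.
#' @return A ggplot of per-epoch validation metrics.
#' @method autoplot epi_classifier
#' @export
autoplot.epi_classifier <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("auroc", "aupr", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "validation metric") +
    ggplot2::theme_minimal()
}

#' Plot the loss breakdown of a domain-adversarial run
#'
#' @param object An `epi_dann`.
#' @param ... Unused.
#' @return A ggplot of `L_class`, `L_domain` and `L_total` per step.
#' @method autoplot epi_dann
#' @export
autoplot.epi_dann <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("L_class", "L_domain", "L_total"),
                            names_to = "term", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "loss") +
    ggplot2::theme_minimal()
}

#' Plot a position weight matrix as a probability heat map
#'
#' @param object A `pwm`.
#' @param ... Unused.
#' @return A ggplot tile map (positions by base).
#' @method autoplot pwm
#' @export
autoplot.pwm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$base,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#d7301f", limits = c(0, 1)) +
    ggplot2::labs(title = object$consensus, x = "position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the positional density of high-attention regions
#'
#' @param density Tibble from [position_density()].
#' @param tss Optional 0-based TSS offset to mark (promoter windows
#'   place it at the upstream-extent position, 1,500 by default).
#' @return A ggplot.
#' @export
plot_position_density <- function(density, tss = NULL) {
  p <- ggplot2::ggplot(density, ggplot2::aes(x = .data$midpoint, y = .data$count)) +
    ggplot2::geom_col(width = diff(range(density$midpoint)) / max(1L, nrow(density)),
                      fill = "#31a354") +
    ggplot2::facet_wrap(~role, scales = "free_x") +
    ggplot2::labs(x = "element position (bp)", y = "regions") +
    ggplot2::theme_minimal()
  if (!is.null(tss)) {
    p <- p + ggplot2::geom_vline(xintercept = tss, linetype = 2, colour = "grey40")
  }
  p
}
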