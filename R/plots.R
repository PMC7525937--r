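#' Plot an ordination
#'
#' Scatter plot of two ordination axes, optionally coloured by group, with
#' explained-variance fractions in the axis labels.
#'
#' @param object A `cmf_ordination` object.
#' @param groups Optional vector of group labels parallel to the genomes.
#' @param axes Length-2 integer vector of axes to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cmf_ordination <- function(object, groups = NULL, axes = c(1L, 2L), ...) {
  stopifnot(length(axes) == 2L, all(axes <= ncol(object$scores)))
  d <- tibble(
    x = object$scores[, axes[1]], y = object$scores[, axes[2]],
    group = if (is.null(groups)) "all" else as.character(groups)
  )
  lab <- function(a) sprintf("PC%d (%.1f%%)", a, 100 * object$explained_variance[a])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = lab(axes[1]), y = lab(axes[2]),
                  title = paste(object$method, "ordination")) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7) +
      ggplot2::labs(colour = "group")
  }
}

#' Adherence distribution by group
#'
#' Box-and-jitter plot of per-genome adherence percentages per source
#' group.
#'
#' @param report An adherence report tibble.
#' @return A ggplot object.
#' @export
plot_adherence <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$source_group,
                                       y = .data$adherence_percent,
                                       fill = .data$source_group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = NULL, y = "adherence to core set (%)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Per-gene missingness profile plot
#'
#' Bar plot of the percentage of genomes lacking each core function, in
#' reference order.
#'
#' @param profile A missingness profile from [missing_profile()].
#' @param highlight_above Draw a reference line at this missingness percent.
#' @return A ggplot object.
#' @export
plot_missing_profile <- function(profile, highlight_above = 50) {
  d <- mutate(profile, key = factor(.data$key, levels = .data$key))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$key, y = .data$pct_missing)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_hline(yintercept = highlight_above, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "core function", y = "genomes lacking the function (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
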