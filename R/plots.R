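#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory fit
#'
#' Scatter of per-bin methylation differences with the fitted regression
#' line: x is the old - young baseline, y the treated-group response; the
#' slope encodes the mixing coefficient (see [fit_trajectory()]).
#'
#' @param object A `trajectory_fit`.
#' @param alpha Point transparency.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trajectory_fit
#' @export
autoplot.trajectory_fit <- function(object, alpha = 0.3, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = alpha, size = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(
      x = paste0("methylation difference (", object$x_def, ")"),
      y = paste0("methylation difference (", object$y_def, ")"),
      title = sprintf("slope %.4f, PCC %.3f, lambda %.3f",
                      object$slope, object$pcc, object$lambda_hat)
    ) +
    ggplot2::theme_minimal()
}

#' Distribution of bin methylation levels per group
#'
#' Density view of the per-group bin methylation; on data emulating the
#' emulated five-group design the mass concentrates near 0 and in 0.8-1.0 in every
#' group.
#'
#' @param bin_levels Wide bin-by-sample tibble ([bin_methylation()]).
#' @param sample_sheet Sample sheet.
#' @return A ggplot object.
#' @export
plot_bin_distribution <- function(bin_levels, sample_sheet) {
  grp <- group_levels(bin_levels, sample_sheet)
  long <- grp |>
    dplyr::select("region", dplyr::all_of(unique(sample_sheet$group))) |>
    tidyr::pivot_longer(-"region", names_to = "group", values_to = "level")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level,
                                     fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4, bounds = c(0, 1)) +
    ggplot2::facet_wrap(~group) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "bin methylation level", y = "density") +
    ggplot2::theme_minimal()
}

#' MA-style plot of the young/old expression contrast
#'
#' @param summary Output of [expression_summary()].
#' @return A ggplot object.
#' @export
plot_expression_ma <- function(summary) {
  ma <- dplyr::filter(summary$ma, is.finite(.data$log2fc))
  ggplot2::ggplot(ma, ggplot2::aes(x = log2(.data$mean_expr + 1),
                                   y = .data$log2fc)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "red") +
    ggplot2::labs(x = "log2 mean expression (young/old)",
                  y = "log2 fold change (old / young)") +
    ggplot2::theme_minimal()
}
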