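#' Plot the flank-distance coverage profile
#'
#' Mean depth (line) and the fraction of flank regions keeping minimum
#' coverage (secondary line, scaled to the depth axis) against distance
#' from the exon-intron boundary.
#'
#' @param profile Output of [flank_coverage_profile()].
#' @param min_depth Threshold annotated on the plot (default 50).
#' @return A ggplot object.
#' @export
plot_coverage_profile <- function(profile, min_depth = 50) {
  scale <- max(profile$mean_depth)
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_depth), colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fraction_ge_min * scale),
                       colour = "red") +
    ggplot2::geom_hline(yintercept = min_depth, linetype = "dotted") +
    ggplot2::scale_y_continuous(
      name = "mean depth (reads)",
      sec.axis = ggplot2::sec_axis(~ . / scale,
                                   name = sprintf("fraction of flanks >= %dX", min_depth))
    ) +
    ggplot2::labs(x = "distance from exon boundary (bp)") +
    ggplot2::theme_minimal()
}

#' @rdname call_cnv
#' @param object A `cnv_call` object.
#' @method autoplot cnv_call
#' @export
autoplot.cnv_call <- function(object, ...) {
  r <- object$ratios |>
    arrange(.data$gene, .data$exon_index) |>
    mutate(idx = row_number(),
           significant = (.data$fold_change > object$params$gain_fc |
                            .data$fold_change < object$params$loss_fc) &
             .data$p_value < object$params$alpha)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$idx, y = .data$log2_ratio,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_grid(~ gene, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(x = "exon (panel order)", y = "log2 ratio vs reference normals",
                  title = object$test_sample) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname characterize_noise
#' @param object A `noise_profile` object.
#' @param dp_min,vf_exonic Threshold lines to draw (defaults 50, 0.20).
#' @method autoplot noise_profile
#' @export
autoplot.noise_profile <- function(object, dp_min = 50, vf_exonic = 0.20, ...) {
  ggplot2::ggplot(object$calls,
                  ggplot2::aes(x = .data$VF, y = .data$DP,
                               colour = .data$reproducible,
                               shape = .data$region_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = dp_min, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = vf_exonic, linetype = "dotted") +
    ggplot2::labs(x = "allele frequency (VF)", y = "coverage depth (DP)") +
    ggplot2::theme_minimal()
}
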