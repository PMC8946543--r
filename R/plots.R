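#' Intensity heatmap of one nuclear plane
#'
#' A 2-D raster of one channel on one z-plane of a cropped nucleus: the
#' flat stand-in for an interactive 3-D surface plot, showing where in the
#' nucleus a signal peaks.
#'
#' @param crop a `nucleus_crop` from [crop_nucleus()].
#' @param channel_role channel to display.
#' @param z plane index; defaults to the mid-plane of the mask.
#' @return A ggplot.
#' @export
plot_intensity_surface <- function(crop, channel_role, z = NULL) {
  ch <- stack_channel(crop$stack, channel_role)
  if (is.null(z)) {
    z <- floor(stats::median(which(apply(crop$mask, 1, any))))
  }
  m <- ch[z, , ]
  df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$intensity <- m[cbind(df$y, df$x)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s, z-plane %d", channel_role, z),
      x = "x (px)", y = "y (px)", fill = "intensity"
    ) +
    ggplot2::theme_minimal()
}

#' Peripheral-versus-central profile plot
#'
#' Boxplots of per-nucleus peripheral and central mean intensities, one
#' panel per channel, split by genotype.
#'
#' @param profiles the `profiles` tibble of a [run_pipeline()] result
#'   (rows with `vector_kind == "pooled"` are used).
#' @return A ggplot.
#' @export
plot_profiles <- function(profiles) {
  df <- dplyr::filter(profiles, .data$vector_kind == "pooled")
  df <- tidyr::pivot_longer(
    df,
    c("peripheral_mean", "central_mean"),
    names_to = "region", values_to = "mean_intensity"
  )
  df$region <- ifelse(
    df$region == "peripheral_mean", "peripheral", "central"
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$genotype, .data$mean_intensity, fill = .data$region)
  ) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::facet_wrap(~channel_role, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "mean intensity (a.u.)", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Colocalization coefficient plot
#'
#' Distribution of a chosen coefficient per pairing and genotype.
#'
#' @param coloc the `coloc` tibble of a [run_pipeline()] result.
#' @param coefficient one of `"m1"`, `"m2"`, `"rho"`, `"tau"`.
#' @return A ggplot.
#' @export
plot_coloc <- function(coloc, coefficient = c("m1", "m2", "rho", "tau")) {
  coefficient <- match.arg(coefficient)
  ggplot2::ggplot(
    coloc,
    ggplot2::aes(
      .data$pairing, .data[[coefficient]],
      fill = .data$genotype
    )
  ) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = NULL, y = coefficient, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
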