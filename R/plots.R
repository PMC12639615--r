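#' Plot a two-channel image pair
#'
#' Renders the protein and DNA channels side by side as intensity rasters.
#'
#' @param object an `image_pair`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot image_pair
#' @export
autoplot.image_pair <- function(object, ...) {
  to_df <- function(img, channel) {
    tibble(
      row = rep(seq_len(nrow(img)), ncol(img)),
      col = rep(seq_len(ncol(img)), each = nrow(img)),
      intensity = as.vector(img),
      channel = channel
    )
  }
  d <- dplyr::bind_rows(to_df(object$protein, "protein"), to_df(object$dna, "DNA stain"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity")
}

#' Plot a fitted FRAP recovery curve
#'
#' Normalized percent recovery versus time since bleach, with the fitted
#' single-exponential overlaid and the half-time marked.
#'
#' @param object a `frap_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot frap_fit
#' @export
autoplot.frap_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t_post)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "firebrick") +
    ggplot2::geom_vline(xintercept = object$t_half, linetype = "dashed") +
    ggplot2::labs(
      x = "time since bleach (s)", y = "recovery (%)",
      title = sprintf("t1/2 = %.2f s, plateau = %.1f%%, R2 = %.3f",
                      object$t_half, object$plateau, object$r_squared)
    )
}

#' Plot an intensity line profile
#'
#' @param profile tibble from [intensity_profile()].
#' @return a ggplot with both channel profiles along the sampled segment.
#' @export
plot_profile <- function(profile) {
  d <- tidyr::pivot_longer(profile, c("protein", "dna"),
                           names_to = "channel", values_to = "intensity")
  xvar <- if ("distance_um" %in% names(d)) "distance_um" else "distance"
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]], y = .data$intensity,
                                  color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (xvar == "distance_um") "distance (µm)" else "distance (px)",
      y = "intensity"
    )
}

#' Plot per-condition relative luciferase activities
#'
#' Replicate points with per-condition mean +/- SEM, the conventional
#' presentation of dual-luciferase results relative to the empty-vector
#' control.
#'
#' @param activities output of [relative_activity()].
#' @return a ggplot.
#' @export
plot_relative_activity <- function(activities) {
  summ <- reporter_summary(activities)
  ggplot2::ggplot(activities, ggplot2::aes(x = .data$condition, y = .data$relative_activity)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(y = .data$mean_relative_activity,
                   ymin = .data$mean_relative_activity - .data$sem,
                   ymax = .data$mean_relative_activity + .data$sem),
      color = "firebrick"
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "relative luciferase activity")
}

#' Plot the variant-by-readout call matrix
#'
#' Tile matrix of standardized calls across all readouts per variant, the
#' summary view used to synthesize functional subgroups.
#'
#' @param profiles classified profiles (see [assign_subgroup()]).
#' @return a ggplot.
#' @export
plot_call_matrix <- function(profiles) {
  d <- profiles |>
    tidyr::pivot_longer(dplyr::any_of(profile_call_cols),
                        names_to = "readout", values_to = "call")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$readout, y = .data$variant, fill = .data$call)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}
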