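#' Plot a profile map as a heatmap
#'
#' @param object a [profile_map()].
#' @param ... unused.
#' @return A ggplot: positions on y, profiles on x, intensity as fill.
#' @export
autoplot.profile_map <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$profile, y = .data$position,
                                 fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity (a.u.)") +
    ggplot2::labs(x = "profile", y = "normalized position (a.u.)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot an average profile with its SD band
#'
#' @param object a `profile_summary` from [summarize_map()].
#' @param window optional membrane window `c(start, end)` to shade.
#' @param ... unused.
#' @return A ggplot of mean intensity versus normalized position.
#' @export
autoplot.profile_summary <- function(object, window = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0), ymax = .data$mean + .data$sd),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "normalized position (a.u.)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect",
      xmin = window[1], xmax = window[2], ymin = -Inf, ymax = Inf,
      alpha = 0.15, fill = "firebrick"
    )
  }
  p
}

#' Plot a force-distance curve
#'
#' @param object a [force_curve()].
#' @param ... unused.
#' @return A ggplot of force versus piezo height, colored by segment.
#' @export
autoplot.force_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$height_um, y = .data$force_pN,
                                       color = .data$segment)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "piezo height (µm)", y = "force (pN)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a work histogram with its fitted Gaussian
#'
#' @param object a `gaussian_hist_fit` from [fit_gaussian_histogram()].
#' @param ... unused.
#' @return A ggplot of bin counts with the fitted curve overlaid.
#' @export
autoplot.gaussian_hist_fit <- function(object, ...) {
  df <- object$histogram
  grid <- tibble(
    mid = seq(min(df$mid), max(df$mid), length.out = 200)
  ) |>
    mutate(count = object$amplitude *
             exp(-(.data$mid - object$mu)^2 / (2 * object$sigma^2)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "grey70", width = diff(df$mid[1:2]) * 0.9) +
    ggplot2::geom_line(data = grid, color = "firebrick") +
    ggplot2::labs(x = "value", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot detected blobs over the PLA image
#'
#' @param image a [fluor_image()].
#' @param blobs tibble from [detect_blobs()].
#' @return A ggplot raster of the image with blob circles overlaid.
#' @export
plot_blob_overlay <- function(image, blobs) {
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  df <- tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    intensity = as.numeric(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(
      data = blobs, shape = 1, color = "red", size = 3
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
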