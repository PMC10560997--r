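#' Plot an image sample
#'
#' Raster view of the image with optional mask contours.
#'
#' @param object an [image_sample].
#' @param show_mask overlay the segmentation mask?
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.image_sample <- function(object, show_mask = TRUE, ...) {
  d <- dim(object$image)
  df <- tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    intensity = as.vector(if (length(d) == 3) object$image[, , 1] else object$image)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$sample_id, x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (show_mask && !is.null(object$mask) && any(object$mask > 0)) {
    dfm <- df
    dfm$class <- as.vector(object$mask)
    p <- p + ggplot2::geom_contour(
      data = dfm, ggplot2::aes(z = .data$class), colour = "red",
      breaks = seq(0.5, max(object$mask) + 0.5, by = 1), linewidth = 0.3)
  }
  p
}

#' Plot a training history
#'
#' Loss trajectories (generator auxiliary, adversarial and discriminator
#' means) over iterations, smoothed per epoch.
#'
#' @param object a `train_history` tibble (e.g. `fit$history`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.train_history <- function(object, ...) {
  df <- tibble::as_tibble(object[, c("epoch", "iter", "gen_aux", "gen_adv")]) |>
    tidyr::pivot_longer(c("gen_aux", "gen_adv"),
                        names_to = "term", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$iter, .data$loss, colour = .data$term)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "iteration", y = "loss", colour = NULL)
}

#' Plot out-of-distribution score separation
#'
#' @param object a tibble from [ood_scores()].
#' @param ... unused.
#' @return A ggplot object: score densities by domain tag.
#' @export
plot_ood_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$score, fill = .data$domain_tag)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "mean predictive disagreement", fill = NULL)
}

#' Plot a per-pixel uncertainty map
#'
#' @param u H x W matrix (e.g. the trace of the disagreement part of the
#'   second moment).
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_uncertainty_map <- function(u, title = "predictive uncertainty") {
  d <- dim(u)
  df <- tibble(row = rep(seq_len(d[1]), d[2]),
               col = rep(seq_len(d[2]), each = d[1]),
               u = as.vector(u))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$u)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "u") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
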