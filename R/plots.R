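## Diagnostic plots.

#' Plot a digitized landmark configuration
#'
#' Tracing-style scatter of the landmarks of one subject with the SN
#' line and the rotated X/Y reference axes overlaid.
#'
#' @param landmarks Landmark tibble.
#' @param subject Subject to plot (default: the first).
#' @param rotation_deg X-axis rotation (degrees).
#' @return A ggplot object.
#' @export
plot_landmark_set <- function(landmarks, subject = NULL, rotation_deg = 7) {
  validate_landmark_tbl(landmarks)
  if (is.null(subject)) subject <- landmarks$subject_id[1]
  one <- landmarks[landmarks$subject_id == subject, ]
  if (!nrow(one)) stop("no landmarks for subject ", subject, call. = FALSE)
  pts <- landmark_points(one)
  cs <- build_coordinate_system(pts$S, pts$N, inferior = pts$Me,
                                rotation_deg = rotation_deg)
  span <- max(dist(cbind(one$x_mm, one$y_mm)))
  axis_df <- tibble::tibble(
    x = cs$origin[1] + c(-0.2, -0.2) * span * c(cs$x_hat[1], cs$y_hat[1]),
    y = cs$origin[2] + c(-0.2, -0.2) * span * c(cs$x_hat[2], cs$y_hat[2]),
    xend = cs$origin[1] + c(1.1, 0.9) * span * c(cs$x_hat[1], cs$y_hat[1]),
    yend = cs$origin[2] + c(1.1, 0.9) * span * c(cs$x_hat[2], cs$y_hat[2]),
    axis = c("X-axis", "Y-axis"))
  ggplot2::ggplot(one, ggplot2::aes(x = .data$x_mm, y = .data$y_mm)) +
    ggplot2::geom_segment(data = axis_df,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linetype = .data$axis),
                          colour = "grey50", inherit.aes = FALSE) +
    ggplot2::annotate("segment", x = pts$S[1], y = pts$S[2],
                      xend = pts$N[1], yend = pts$N[2], colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$landmark),
                       nudge_x = 0.02 * span, hjust = 0, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", linetype = NULL,
                  title = paste("Subject", subject)) +
    ggplot2::theme_minimal()
}

#' Plot cohort feature prevalence
#'
#' Bar chart of the per-feature record percentages of a cohort summary.
#'
#' @param object A `tmj_cohort_summary` (from [summarize_cohort()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmj_cohort_summary <- function(object, ...) {
  feat <- object$features
  feat$feature <- factor(feat$feature, levels = rev(feat$feature))
  ggplot2::ggplot(feat, ggplot2::aes(x = .data$pct, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "% of condylar records", y = NULL,
                  title = sprintf("%d records from %d patients",
                                  object$n_records, object$n_patients)) +
    ggplot2::theme_minimal()
}
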