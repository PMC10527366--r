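#' Plot a contour pair with its reference and detected protrusions
#'
#' Depth runs downward, as on the B-scan: the skin surface on top, the
#' DEJ below it, the flat-DEJ reference estimator dashed, and detected
#' protrusion intervals shaded.
#'
#' @param contours A single-image contour tibble.
#' @param rules A [grading_rules()] object used for detection.
#' @return A ggplot object.
#' @export
plot_contours <- function(contours, rules = grading_rules()) {
  validate_contours(contours)
  if (length(unique(contours$image_id)) != 1) {
    rlang::abort("plot_contours() takes a single image.")
  }
  p_um <- contours$lateral_pitch_um[[1]]
  ref <- estimate_reference(contours)
  prot <- detect_protrusions(contours, ref,
                             min_depth_um = rules$min_depth_um,
                             margin_um = rules$margin_um,
                             keep_truncated = rules$keep_truncated,
                             smooth_window_um = rules$smooth_window_um)
  df <- dplyr::left_join(contours, ref, by = c("image_id", "x")) |>
    dplyr::mutate(pos_um = .data$x * p_um)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_um))
  if (nrow(prot) > 0) {
    shade <- dplyr::mutate(prot,
                           xmin = .data$start_x * p_um,
                           xmax = .data$end_x * p_um)
    gg <- gg + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    )
  }
  gg +
    ggplot2::geom_line(ggplot2::aes(y = .data$surface_um,
                                    colour = "skin surface")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$dej_um, colour = "DEJ")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$reference_um,
                                    colour = "flat-DEJ reference"),
                       linetype = "dashed") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(values = c(
      "skin surface" = "steelblue", "DEJ" = "darkgreen",
      "flat-DEJ reference" = "firebrick")) +
    ggplot2::labs(x = "lateral position (um)", y = "depth (um)",
                  colour = NULL,
                  title = unique(contours$image_id))
}

#' Heatmap of a grade contingency table
#'
#' @param object A `grade_table`.
#' @param ... Unused.
#' @return A ggplot object: visual grade by automated grade, cell counts
#'   printed.
#' @method autoplot grade_table
#' @export
autoplot.grade_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$automated, y = .data$visual,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(pro_levels())) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "automated PRO score", y = "visual PRO score",
                  fill = "lesions")
}

#' Morphometrics by PRO grade
#'
#' Boxplots of undulation index, protrusion count and maximum protrusion
#' depth stratified by grade — the standard display of how each metric
#' increases across the ordinal scale.
#'
#' @param metrics Tibble with columns `undulation_index`,
#'   `n_protrusions`, `max_depth_um` and a grade column.
#' @param grade Unquoted name of the grade column (default `pro_grade`).
#' @return A ggplot object faceted by metric (free y scales).
#' @export
plot_metrics_by_grade <- function(metrics, grade = pro_grade) {
  long <- metrics |>
    dplyr::mutate(.grade = {{ grade }}) |>
    dplyr::select(".grade", "undulation_index", "n_protrusions",
                  "max_depth_um") |>
    tidyr::pivot_longer(-".grade", names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(metric = factor(
      .data$metric,
      levels = c("undulation_index", "n_protrusions", "max_depth_um"),
      labels = c("undulation index", "number of protrusions",
                 "max protrusion depth (um)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.grade, y = .data$value,
                                     fill = .data$.grade)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c("PRO I" = "#74c476",
                                          "PRO II" = "#fd8d3c",
                                          "PRO III" = "#de2d26")) +
    ggplot2::labs(x = NULL, y = NULL)
}
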