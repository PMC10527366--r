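#' Grading rules and detection thresholds
#'
#' Bundles every tunable threshold of the pipeline. The PRO II / PRO III
#' discrimination follows the morphology of the grades: a hemispherical bud
#' has a depth of about half its width, so a protrusion is called "spiky"
#' (PRO III) when it is either deep in absolute terms
#' (`depth >= spike_depth_um`) or deeper than hemispherical in proportion
#' (`depth / ledge_width >= spike_aspect`). PRO I requires no detected
#' protrusion at all.
#'
#' @param min_depth_um Noise floor for protrusion detection (um). Default
#'   5 um, roughly four axial pixels at 1.3 um pitch.
#' @param spike_depth_um Absolute depth at which a protrusion counts as a
#'   spiky/filiform elongation (um). Default 60.
#' @param spike_aspect Depth-to-ledge-width ratio above which a protrusion
#'   counts as spiky. Default 0.5 (hemispherical).
#' @param margin_um Margin added on each side of a protrusion interval
#'   when measuring depth (um). Default 10.
#' @param max_rule_fraction Minimum share of a lesion's images a grade must
#'   reach to count for the lesion-maximum rule. Default 0.10.
#' @param smooth_window_um Moving-average window (um) applied before
#'   crossing detection; 0 disables (default).
#' @param keep_truncated Count protrusions truncated by the image edge?
#'   Default `TRUE`.
#' @return A list of class `grading_rules`.
#' @examples
#' grading_rules()
#' @export
grading_rules <- function(min_depth_um = 5, spike_depth_um = 60,
                          spike_aspect = 0.5, margin_um = 10,
                          max_rule_fraction = 0.10, smooth_window_um = 0,
                          keep_truncated = TRUE) {
  stopifnot(
    min_depth_um > 0, spike_depth_um > 0, spike_aspect > 0, margin_um >= 0,
    max_rule_fraction > 0, max_rule_fraction <= 1, smooth_window_um >= 0
  )
  structure(
    list(
      min_depth_um = min_depth_um,
      spike_depth_um = spike_depth_um,
      spike_aspect = spike_aspect,
      margin_um = margin_um,
      max_rule_fraction = max_rule_fraction,
      smooth_window_um = smooth_window_um,
      keep_truncated = keep_truncated
    ),
    class = "grading_rules"
  )
}

#' @export
print.grading_rules <- function(x, ...) {
  cat("PRO grading rules\n")
  cat(sprintf("  detection floor:   %g um\n", x$min_depth_um))
  cat(sprintf("  spike depth:       %g um\n", x$spike_depth_um))
  cat(sprintf("  spike aspect:      %g (depth / ledge width)\n", x$spike_aspect))
  cat(sprintf("  depth margin:      %g um\n", x$margin_um))
  cat(sprintf("  max-rule fraction: %g\n", x$max_rule_fraction))
  cat(sprintf("  smoothing window:  %g um\n", x$smooth_window_um))
  cat(sprintf("  keep truncated:    %s\n", x$keep_truncated))
  invisible(x)
}

#' Grade images on the PRO I-III scale
#'
#' Applies the per-image grading rule to a metrics tibble from
#' [compute_image_metrics()]: PRO I when no protrusion was detected;
#' PRO III when any protrusion is deep (`depth >= spike_depth_um`) or
#' steeper than hemispherical (`depth / ledge_width >= spike_aspect`);
#' PRO II otherwise (hemispherical buds).
#'
#' @param metrics Tibble from [compute_image_metrics()] (must carry the
#'   `protrusions` list-column).
#' @param rules A [grading_rules()] object; should be the same one used to
#'   compute the metrics.
#' @return `metrics` with an added ordered-factor column `pro_grade`.
#' @export
classify_images <- function(metrics, rules = grading_rules()) {
  if (!"protrusions" %in% names(metrics)) {
    rlang::abort("`metrics` must carry the `protrusions` list-column; use compute_image_metrics().")
  }
  grade1 <- purrr::map_int(metrics$protrusions, function(p) {
    if (nrow(p) == 0) return(1L)
    aspect <- p$depth_um / p$ledge_width_um
    spiky <- p$depth_um >= rules$spike_depth_um | aspect >= rules$spike_aspect
    if (any(spiky)) 3L else 2L
  })
  dplyr::mutate(metrics, pro_grade = pro_grade(grade1))
}

#' Lesion-level grade aggregation
#'
#' `aggregate_average()` is the average rule: the arithmetic mean of the
#' ordinal grade values over a lesion's images, rounded half-up to the
#' nearest grade. `aggregate_max10()` is the robust maximum rule: the
#' highest grade present in at least `fraction` (default 10%) of the
#' images; grades rarer than that are treated as artifacts or outliers.
#'
#' @param grades Non-empty vector coercible by [pro_grade()].
#' @param fraction Minimum share of images for a grade to qualify for the
#'   maximum rule (a share exactly equal to `fraction` qualifies).
#' @return A length-1 PRO grade factor.
#' @examples
#' aggregate_average(pro_grade(c(1, 2)))            # PRO II (half-up)
#' aggregate_max10(pro_grade(rep(c(3, 1), c(10, 90))))  # PRO III
#' @export
aggregate_average <- function(grades) {
  g <- pro_grade(grades)
  if (length(g) == 0 || anyNA(g)) {
    rlang::abort("`grades` must be a non-empty vector of PRO grades.")
  }
  m <- mean(as.integer(g))
  pro_grade(max(1L, min(3L, as.integer(floor(m + 0.5)))))
}

#' @rdname aggregate_average
#' @export
aggregate_max10 <- function(grades, fraction = 0.10) {
  g <- pro_grade(grades)
  if (length(g) == 0 || anyNA(g)) {
    rlang::abort("`grades` must be a non-empty vector of PRO grades.")
  }
  stopifnot(fraction > 0, fraction <= 1)
  share <- as.numeric(table(g)) / length(g)
  qual <- which(share >= fraction - 1e-12)
  if (length(qual) == 0) {
    # Unreachable with 3 grades and fraction <= 1/3; modal fallback,
    # ties broken toward the higher grade.
    counts <- as.numeric(table(g))
    qual <- which(counts == max(counts))
  }
  pro_grade(max(qual))
}

#' Score a lesion from its per-image metrics
#'
#' Grades every image, applies both lesion-level aggregation rules, and
#' averages the morphometrics over the lesion's images. `metrics` must
#' carry a `lesion_id` column (join your manifest first); several lesions
#' can be scored in one call.
#'
#' @param metrics Tibble from [compute_image_metrics()] with an added
#'   `lesion_id` column (and optionally a precomputed `pro_grade`).
#' @param rules A [grading_rules()] object.
#' @return A tibble with one row per lesion: `lesion_id`, `n_images`,
#'   `average_grade`, `max10_grade`, `mean_undulation_index`,
#'   `mean_n_protrusions`, `mean_max_depth_um`.
#' @export
score_lesions <- function(metrics, rules = grading_rules()) {
  if (!"lesion_id" %in% names(metrics)) {
    rlang::abort("`metrics` must carry a `lesion_id` column.")
  }
  if (!"pro_grade" %in% names(metrics)) {
    metrics <- classify_images(metrics, rules)
  }
  metrics |>
    dplyr::group_by(.data$lesion_id) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      average_grade = aggregate_average(.data$pro_grade),
      max10_grade = aggregate_max10(.data$pro_grade,
                                    fraction = rules$max_rule_fraction),
      mean_undulation_index = mean(.data$undulation_index),
      mean_n_protrusions = mean(.data$n_protrusions),
      mean_max_depth_um = mean(.data$max_depth_um),
      .groups = "drop"
    )
}

#' Continuous protrusion score (experimental)
#'
#' A continuous severity composite combining the three per-image
#' morphometrics: a weighted sum of `max_depth / depth_norm_um`,
#' `(undulation_index - 1) / undulation_norm` and
#' `n_protrusions / count_norm`, each weight defaulting to 1/3. The
#' three-level PRO scale compresses a biological continuum; this score is
#' a finer-grained alternative, but it has no validated thresholds yet,
#' so the output column is explicitly named `cps_experimental`.
#'
#' @param metrics Tibble from [compute_image_metrics()].
#' @param weights Length-3 non-negative weights for (depth, undulation,
#'   count), in that order.
#' @param depth_norm_um,undulation_norm,count_norm Positive normalising
#'   constants mapping each component to a comparable unitless scale.
#' @return `metrics` with an added `cps_experimental` column (>= 0; 0 for
#'   a flat image).
#' @export
continuous_protrusion_score <- function(metrics, weights = rep(1 / 3, 3),
                                        depth_norm_um = 100,
                                        undulation_norm = 0.5,
                                        count_norm = 5) {
  stopifnot(length(weights) == 3, all(weights >= 0),
            depth_norm_um > 0, undulation_norm > 0, count_norm > 0)
  dplyr::mutate(
    metrics,
    cps_experimental =
      weights[1] * .data$max_depth_um / depth_norm_um +
      weights[2] * (.data$undulation_index - 1) / undulation_norm +
      weights[3] * .data$n_protrusions / count_norm
  )
}
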