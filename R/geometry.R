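#' Flat-DEJ reference estimator
#'
#' Protrusions are defined against an estimate of where a flat DEJ would
#' lie: the skin surface contour offset downward by the image's mean
#' epidermal thickness (the per-column average of `dej_um - surface_um`).
#'
#' @param contours A contour tibble (see [contour_pair()]), one or more
#'   images.
#' @return A tibble with columns `image_id`, `x`, `reference_um` and
#'   `mean_epidermal_thickness_um` (constant within an image).
#' @examples
#' cp <- contour_pair(rep(0, 40), rep(100, 40))
#' estimate_reference(cp)
#' @export
estimate_reference <- function(contours) {
  validate_contours(contours)
  contours |>
    dplyr::group_by(.data$image_id) |>
    dplyr::mutate(
      mean_epidermal_thickness_um = mean(.data$dej_um - .data$surface_um),
      reference_um = .data$surface_um + .data$mean_epidermal_thickness_um
    ) |>
    dplyr::ungroup() |>
    dplyr::select("image_id", "x", "reference_um",
                  "mean_epidermal_thickness_um")
}

#' Undulation index of the DEJ
#'
#' The polyline arc length of the DEJ contour divided by the straight-line
#' width of the imaged area, `(W - 1) * lateral_pitch`. Equals 1 only for a
#' perfectly flat DEJ and grows with roughness of the junction.
#'
#' @inheritParams estimate_reference
#' @return A tibble with columns `image_id`, `undulation_index`.
#' @examples
#' flat <- contour_pair(rep(0, 30), rep(100, 30))
#' undulation_index(flat)   # exactly 1
#' @export
undulation_index <- function(contours) {
  validate_contours(contours)
  contours |>
    dplyr::arrange(.data$image_id, .data$x) |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      undulation_index =
        sum(sqrt(.data$lateral_pitch_um[-1]^2 + diff(.data$dej_um)^2)) /
        ((dplyr::n() - 1) * .data$lateral_pitch_um[[1]]),
      .groups = "drop"
    )
}

#' Depth of a protrusion interval
#'
#' The depth of a protrusion is the difference between the highest and
#' lowest points of the DEJ within the interval bounded by the two
#' estimator crossings, expanded by a small margin (default 10 um) on each
#' side and clipped at the image edges.
#'
#' @param dej_um Numeric vector of DEJ depths for one image.
#' @param start_x,end_x Interval bounds as 0-based (possibly fractional)
#'   column positions, `start_x < end_x`.
#' @param lateral_pitch_um Lateral pitch in um per column.
#' @param margin_um Margin added on each side of the interval (um).
#' @return Depth in um (max minus min of the DEJ over the expanded
#'   interval).
#' @export
protrusion_depth <- function(dej_um, start_x, end_x, lateral_pitch_um = 1.1,
                             margin_um = 10) {
  stopifnot(start_x < end_x)
  w <- length(dej_um)
  lo <- max(0, floor(start_x - margin_um / lateral_pitch_um))
  hi <- min(w - 1, ceiling(end_x + margin_um / lateral_pitch_um))
  seg <- dej_um[(lo:hi) + 1]
  max(seg) - min(seg)
}

# Detect protrusions on a single image's vectors. x is implicit 0-based.
detect_one_image <- function(dej, reference, lateral_pitch, min_depth_um,
                             margin_um, keep_truncated, smooth_window_um) {
  w <- length(dej)
  d_det <- dej
  if (smooth_window_um > 0) {
    k <- max(1L, as.integer(round(smooth_window_um / lateral_pitch)))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > 1L) {
      kern <- rep(1 / k, k)
      pad <- (k - 1L) %/% 2L
      padded <- c(rep(dej[1], pad), dej, rep(dej[w], pad))
      d_det <- as.numeric(stats::filter(padded, kern, sides = 2))[pad + seq_len(w)]
    }
  }
  e <- d_det - reference
  above <- e > 0
  empty <- tibble::tibble(
    start_x = numeric(), end_x = numeric(), ledge_width_um = numeric(),
    depth_um = numeric(), truncated = logical()
  )
  if (!any(above)) return(empty)
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(j) {
    i0 <- run_start[j]   # 1-based first column above
    i1 <- run_end[j]     # 1-based last column above
    trunc_l <- i0 == 1L
    trunc_r <- i1 == w
    if (trunc_l) {
      xs <- 0
    } else {
      e0 <- e[i0 - 1L]   # <= 0
      e1 <- e[i0]        # > 0
      xs <- (i0 - 2L) + (-e0) / (e1 - e0)
    }
    if (trunc_r) {
      xe <- w - 1
    } else {
      e0 <- e[i1]        # > 0
      e1 <- e[i1 + 1L]   # <= 0
      xe <- (i1 - 1L) + e0 / (e0 - e1)
    }
    depth <- protrusion_depth(dej, xs, xe, lateral_pitch, margin_um)
    tibble::tibble(
      start_x = xs, end_x = xe,
      ledge_width_um = (xe - xs) * lateral_pitch,
      depth_um = depth,
      truncated = trunc_l || trunc_r
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$depth_um >= min_depth_um, , drop = FALSE]
  if (!keep_truncated) out <- out[!out$truncated, , drop = FALSE]
  if (nrow(out) == 0) empty else out
}

#' Detect DEJ protrusions against the flat-DEJ estimator
#'
#' A protrusion is a maximal lateral interval where the DEJ lies deeper
#' than the reference estimator. Interval bounds are the two crossing
#' points where the DEJ crosses the estimator, located with sub-column
#' precision by linear interpolation between adjacent columns; the ledge
#' width is the lateral distance between them. Intervals whose depth (see
#' [protrusion_depth()]) falls below `min_depth_um` are discarded as noise;
#' intervals abutting an image edge are flagged `truncated` and kept by
#' default.
#'
#' @inheritParams estimate_reference
#' @param reference Optional precomputed output of [estimate_reference()];
#'   computed internally when `NULL`.
#' @param min_depth_um Detection threshold in um (default 5, about four
#'   axial pixels): minimum depth for an interval to count.
#' @param margin_um Margin used by the depth measurement (default 10 um).
#' @param keep_truncated Keep intervals touching an image edge?
#' @param smooth_window_um Optional moving-average window (um) applied to
#'   the DEJ before crossing detection; 0 (default) disables smoothing.
#'   Depths are always measured on the raw contour.
#' @return A tibble with one row per protrusion: `image_id`, `protrusion`
#'   (1-based rank by `start_x`), `start_x`, `end_x` (0-based fractional
#'   column positions), `ledge_width_um`, `depth_um`, `truncated`.
#' @examples
#' cp <- contour_pair(rep(0, 200),
#'                    100 + 40 * pmax(0, cos(pi * (0:199 - 100) / 60))^2)
#' detect_protrusions(cp)
#' @export
detect_protrusions <- function(contours, reference = NULL, min_depth_um = 5,
                               margin_um = 10, keep_truncated = TRUE,
                               smooth_window_um = 0) {
  validate_contours(contours)
  if (is.null(reference)) reference <- estimate_reference(contours)
  df <- dplyr::inner_join(
    dplyr::arrange(contours, .data$image_id, .data$x),
    dplyr::arrange(reference, .data$image_id, .data$x),
    by = c("image_id", "x")
  )
  if (nrow(df) != nrow(contours)) {
    rlang::abort("`reference` is not aligned with `contours`.")
  }
  df |>
    dplyr::group_by(.data$image_id) |>
    dplyr::group_modify(function(g, key) {
      out <- detect_one_image(
        g$dej_um, g$reference_um, g$lateral_pitch_um[[1]],
        min_depth_um, margin_um, keep_truncated, smooth_window_um
      )
      out$protrusion <- seq_len(nrow(out))
      dplyr::select(out, "protrusion", dplyr::everything())
    }) |>
    dplyr::ungroup()
}

#' Per-image protrusion morphometrics
#'
#' Composes the reference estimator, protrusion detection, depth
#' measurement and undulation index into one record per image: the three
#' metrics used to quantify basal growth (undulation index, protrusion
#' count, maximum protrusion depth) plus the detected protrusions
#' themselves as a nested list-column.
#'
#' @inheritParams estimate_reference
#' @param rules A [grading_rules()] object supplying the detection
#'   thresholds (`min_depth_um`, `margin_um`, smoothing, edge handling).
#' @return A tibble with one row per image: `image_id`,
#'   `undulation_index`, `n_protrusions`, `max_depth_um` (0 when no
#'   protrusions), `mean_epidermal_thickness_um` and a `protrusions`
#'   list-column of per-protrusion tibbles.
#' @examples
#' flat <- contour_pair(rep(0, 50), rep(100, 50))
#' compute_image_metrics(flat)
#' @export
compute_image_metrics <- function(contours, rules = grading_rules()) {
  validate_contours(contours)
  ref <- estimate_reference(contours)
  prot <- detect_protrusions(
    contours, ref,
    min_depth_um = rules$min_depth_um,
    margin_um = rules$margin_um,
    keep_truncated = rules$keep_truncated,
    smooth_window_um = rules$smooth_window_um
  )
  ui <- undulation_index(contours)
  thick <- ref |>
    dplyr::distinct(.data$image_id, .data$mean_epidermal_thickness_um)
  prot_nested <- prot |>
    tidyr::nest(protrusions = -"image_id")
  ui |>
    dplyr::left_join(thick, by = "image_id") |>
    dplyr::left_join(prot_nested, by = "image_id") |>
    dplyr::mutate(
      protrusions = purrr::map(.data$protrusions, function(p) {
        if (is.null(p)) {
          tibble::tibble(
            protrusion = integer(), start_x = numeric(), end_x = numeric(),
            ledge_width_um = numeric(), depth_um = numeric(),
            truncated = logical()
          )
        } else {
          p
        }
      }),
      n_protrusions = purrr::map_int(.data$protrusions, nrow),
      max_depth_um = purrr::map_dbl(
        .data$protrusions,
        function(p) if (nrow(p) == 0) 0 else max(p$depth_um)
      )
    ) |>
    dplyr::select("image_id", "undulation_index", "n_protrusions",
                  "max_depth_um", "mean_epidermal_thickness_um",
                  "protrusions")
}
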