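#' Pipeline configuration
#'
#' A flat list of every tunable parameter of the scoring pipeline, with
#' the documented defaults. Configurations round-trip losslessly through
#' YAML or JSON ([read_pipeline_config()] / [write_pipeline_config()]),
#' and every report embeds the resolved configuration so a run can be
#' reproduced exactly.
#'
#' @param lateral_pitch_um,axial_pitch_um Sampling pitches (um); defaults
#'   1.1 and 1.3, the standard LC-OCT resolution.
#' @inheritParams grading_rules
#' @param kappa_ci `"asymptotic"` or `"bootstrap"` confidence intervals
#'   for the weighted kappa.
#' @param conf_level Confidence level for all intervals.
#' @param seed Integer seed used by every stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(lateral_pitch_um = 1.1, axial_pitch_um = 1.3,
                            min_depth_um = 5, spike_depth_um = 60,
                            spike_aspect = 0.5, margin_um = 10,
                            max_rule_fraction = 0.10, smooth_window_um = 0,
                            keep_truncated = TRUE,
                            kappa_ci = "asymptotic", conf_level = 0.95,
                            seed = 1L) {
  stopifnot(lateral_pitch_um > 0, axial_pitch_um > 0,
            kappa_ci %in% c("asymptotic", "bootstrap"),
            conf_level > 0, conf_level < 1)
  rules <- grading_rules(
    min_depth_um = min_depth_um, spike_depth_um = spike_depth_um,
    spike_aspect = spike_aspect, margin_um = margin_um,
    max_rule_fraction = max_rule_fraction,
    smooth_window_um = smooth_window_um, keep_truncated = keep_truncated
  )
  structure(
    c(list(lateral_pitch_um = lateral_pitch_um,
           axial_pitch_um = axial_pitch_um),
      unclass(rules),
      list(kappa_ci = kappa_ci, conf_level = conf_level,
           seed = as.integer(seed))),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("dejpro pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

config_rules <- function(config) {
  grading_rules(
    min_depth_um = config$min_depth_um,
    spike_depth_um = config$spike_depth_um,
    spike_aspect = config$spike_aspect,
    margin_um = config$margin_um,
    max_rule_fraction = config$max_rule_fraction,
    smooth_window_um = config$smooth_window_um,
    keep_truncated = config$keep_truncated
  )
}

#' Read and write pipeline configurations
#'
#' The on-disk format is YAML (`.yml`/`.yaml`) or JSON (`.json`), chosen
#' by file extension. Only documented fields are accepted; unknown keys
#' raise an error rather than being silently dropped.
#'
#' @param path File path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    rlang::abort(sprintf("Unsupported config format '.%s'.", ext))
  )
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown config field(s): %s.",
                         paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  ext <- tolower(tools::file_ext(path))
  vals <- unclass(config)
  switch(ext,
    yml = ,
    yaml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    rlang::abort(sprintf("Unsupported config format '.%s'.", ext))
  )
  invisible(path)
}

#' Read a lesion manifest
#'
#' The manifest maps images to lesions and carries the expert grades and
#' manual quality exclusions: columns `lesion_id`, `image_id`, optional
#' `source` (path to a contour CSV or mask image), optional
#' `expert_average_grade` and `expert_max_grade`, optional logical
#' `exclude` with `exclude_reason`. Image ids must be unique and every
#' lesion must retain at least one non-excluded image.
#'
#' @param path Manifest CSV path.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(df)
}

#' @param manifest A manifest data frame.
#' @rdname read_manifest
#' @export
validate_manifest <- function(manifest) {
  need <- c("lesion_id", "image_id")
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Manifest lacks column(s): %s.",
                         paste(missing, collapse = ", ")))
  }
  manifest <- tibble::as_tibble(manifest)
  if (!"exclude" %in% names(manifest)) manifest$exclude <- FALSE
  manifest$exclude <- isTRUE_vec(manifest$exclude)
  if (!"exclude_reason" %in% names(manifest)) {
    manifest$exclude_reason <- NA_character_
  }
  if (anyDuplicated(manifest$image_id) > 0) {
    rlang::abort("Manifest image_id values must be unique.")
  }
  bad <- manifest |>
    dplyr::group_by(.data$lesion_id) |>
    dplyr::summarise(all_excluded = all(.data$exclude), .groups = "drop") |>
    dplyr::filter(.data$all_excluded)
  if (nrow(bad) > 0) {
    rlang::abort(sprintf(
      "Lesion(s) with no non-excluded image: %s.",
      paste(bad$lesion_id, collapse = ", ")))
  }
  manifest
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

read_source_contours <- function(source, image_id, config) {
  ext <- tolower(tools::file_ext(source))
  if (ext %in% c("png", "tif", "tiff")) {
    extract_contours(read_mask(source),
                     axial_pitch_um = config$axial_pitch_um,
                     lateral_pitch_um = config$lateral_pitch_um,
                     image_id = image_id)
  } else if (ext == "csv") {
    read_contours_csv(source, lateral_pitch_um = config$lateral_pitch_um)
  } else {
    rlang::abort(sprintf("Unsupported source format '.%s'.", ext))
  }
}

#' Score a manifest of images into per-image metrics and lesion scores
#'
#' The scoring half of the pipeline: resolves each manifest row to a
#' contour pair (from in-memory `contours`, or by reading the row's
#' `source` file), computes the per-image morphometrics and PRO grade,
#' and aggregates to lesion scores. Excluded images are skipped with
#' their reason; an unreadable or invalid image is recorded as a per-row
#' error and the run continues; a lesion left with no scorable image is
#' recorded as a lesion-level error. Outputs are deterministic for a
#' given configuration, and re-running writes byte-identical CSVs.
#'
#' @param manifest A manifest tibble (see [read_manifest()]).
#' @param config A [pipeline_config()].
#' @param contours Optional contour tibble covering the manifest's
#'   image ids; when `NULL`, each row's `source` file is read.
#' @param out_dir Optional output directory; when given,
#'   `image_metrics.csv` and `lesion_scores.csv` are written there.
#' @return A list with `image_metrics`, `lesion_scores`, `skipped`
#'   (excluded rows), `errors` (per-row and per-lesion failures) and the
#'   resolved `config`.
#' @export
run_score <- function(manifest, config = pipeline_config(),
                      contours = NULL, out_dir = NULL) {
  manifest <- validate_manifest(manifest)
  rules <- config_rules(config)
  skipped <- manifest |>
    dplyr::filter(.data$exclude) |>
    dplyr::select("lesion_id", "image_id", "exclude_reason")
  if (nrow(skipped) > 0) {
    rlang::inform(sprintf("Skipping %d excluded image(s).", nrow(skipped)))
  }
  active <- dplyr::filter(manifest, !.data$exclude)
  errors <- tibble::tibble(lesion_id = character(), image_id = character(),
                           error = character())
  metrics_rows <- list()
  for (i in seq_len(nrow(active))) {
    row <- active[i, ]
    res <- tryCatch({
      cp <- if (!is.null(contours)) {
        found <- dplyr::filter(contours, .data$image_id == row$image_id)
        if (nrow(found) == 0) {
          rlang::abort(sprintf("No contours supplied for image '%s'.",
                               row$image_id))
        }
        found
      } else {
        if (!"source" %in% names(row) || is.na(row$source)) {
          rlang::abort("Manifest row has no `source` and no contours were supplied.")
        }
        src <- read_source_contours(row$source, row$image_id, config)
        dplyr::filter(src, .data$image_id == row$image_id)
      }
      m <- compute_image_metrics(cp, rules)
      classify_images(m, rules)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rlang::inform(sprintf("Image '%s' failed: %s", row$image_id,
                            conditionMessage(res)))
      errors <- dplyr::bind_rows(errors, tibble::tibble(
        lesion_id = row$lesion_id, image_id = row$image_id,
        error = conditionMessage(res)))
    } else {
      res$lesion_id <- row$lesion_id
      metrics_rows[[length(metrics_rows) + 1]] <- res
    }
  }
  image_metrics <- dplyr::bind_rows(metrics_rows)
  if (nrow(image_metrics) > 0) {
    image_metrics <- dplyr::arrange(image_metrics, .data$lesion_id,
                                    .data$image_id)
    lesion_scores <- score_lesions(image_metrics, rules) |>
      dplyr::arrange(.data$lesion_id)
  } else {
    lesion_scores <- tibble::tibble()
  }
  dead <- setdiff(unique(active$lesion_id), unique(image_metrics$lesion_id))
  if (length(dead) > 0) {
    errors <- dplyr::bind_rows(errors, tibble::tibble(
      lesion_id = dead, image_id = NA_character_,
      error = "No scorable image left for this lesion."))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(
      dplyr::select(image_metrics, "image_id", "lesion_id",
                    "undulation_index", "n_protrusions", "max_depth_um",
                    "pro_grade"),
      file.path(out_dir, "image_metrics.csv"), progress = FALSE)
    readr::write_csv(lesion_scores, file.path(out_dir, "lesion_scores.csv"),
                     progress = FALSE)
  }
  list(image_metrics = image_metrics, lesion_scores = lesion_scores,
       skipped = skipped, errors = errors, config = config)
}

#' Evaluate automated lesion scores against expert grades
#'
#' The evaluation half of the pipeline: builds the visual-vs-automated
#' contingency tables for both aggregation rules (average and
#' robust-maximum), with percent agreement, per-class recall, over/under
#' rates and the linearly weighted kappa for each. The report embeds the
#' resolved configuration and package version.
#'
#' @param lesion_scores Tibble with one row per lesion carrying
#'   `average_grade` and `max10_grade` (from [run_score()] or
#'   [score_lesions()]) plus the expert columns `expert_average_grade`
#'   and `expert_max_grade`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes `report.json`
#'   and a text rendering `report.txt` of both tables.
#' @return A list of class `dejpro_report` with elements `average` and
#'   `max10` (each `table`, `stats`, `kappa`), `config`, `version`.
#' @export
run_evaluate <- function(lesion_scores, config = pipeline_config(),
                         out_dir = NULL) {
  for (col in c("expert_average_grade", "expert_max_grade")) {
    if (!col %in% names(lesion_scores) || anyNA(lesion_scores[[col]])) {
      offending <- if (!col %in% names(lesion_scores)) {
        unique(lesion_scores$lesion_id)
      } else {
        lesion_scores$lesion_id[is.na(lesion_scores[[col]])]
      }
      rlang::abort(sprintf(
        "Missing expert grades (%s) for lesion(s): %s.",
        col, paste(offending, collapse = ", ")))
    }
  }
  one <- function(expert, automated) {
    tab <- grade_table(expert, automated)
    kap <- tryCatch(
      weighted_kappa(tab, ci_method = config$kappa_ci,
                     conf_level = config$conf_level, seed = config$seed),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "kappa_undefined")
    )
    list(table = tab, stats = agreement_stats(tab), kappa = kap)
  }
  report <- list(
    average = one(lesion_scores$expert_average_grade,
                  lesion_scores$average_grade),
    max10 = one(lesion_scores$expert_max_grade, lesion_scores$max10_grade),
    config = config,
    version = as.character(utils::packageVersion("dejpro"))
  )
  class(report) <- "dejpro_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format(report), file.path(out_dir, "report.txt"))
  }
  report
}

report_to_list <- function(report) {
  side <- function(s) {
    kap <- if (inherits(s$kappa, "kappa_undefined")) {
      list(undefined = TRUE, reason = s$kappa$message)
    } else {
      k <- s$kappa
      list(kappa = k$kappa, conf.low = k$conf.low, conf.high = k$conf.high,
           p.value = k$p.value, weighting = k$weighting,
           ci_method = k$ci_method)
    }
    list(counts = unclass(s$table), stats = as.list(s$stats), kappa = kap)
  }
  list(average = side(report$average), max10 = side(report$max10),
       config = unclass(report$config), version = report$version)
}

#' @export
format.dejpro_report <- function(x, ...) {
  side <- function(s, title) {
    kap_line <- if (inherits(s$kappa, "kappa_undefined")) {
      sprintf("  weighted kappa undefined: %s", s$kappa$message)
    } else {
      sprintf("  weighted kappa = %.3f [%.3f, %.3f], p = %.3g",
              s$kappa$kappa, s$kappa$conf.low, s$kappa$conf.high,
              s$kappa$p.value)
    }
    c(format_grade_table(s$table, title),
      sprintf("  agreement = %.1f%%, over = %.1f%%, under = %.1f%%",
              100 * s$stats$agreement, 100 * s$stats$over_rate,
              100 * s$stats$under_rate),
      kap_line, "")
  }
  c(side(x$average, "Average-rule PRO score: visual vs automated"),
    side(x$max10, "Max-10%-rule PRO score: visual vs automated"),
    sprintf("dejpro %s", x$version))
}

#' @export
print.dejpro_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Simulate a phantom lesion dataset on disk
#'
#' Samples lesion-level true grades (exact largest-remainder allocation of
#' `grade_probs`), draws each lesion's per-image grades from a mixture
#' concentrated on the lesion grade (`prob_modal` at the lesion grade, the
#' remainder split over adjacent grades), generates one contour phantom
#' per image, and writes `contours.csv` plus a `manifest.csv` whose expert
#' grades are the aggregation rules applied to the true image grades.
#' Re-running with the same seed regenerates the dataset byte-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()]; supplies pitches and the seed.
#' @param n_lesions Number of lesions.
#' @param images_per_lesion Length-2 inclusive range of images per lesion.
#' @param grade_probs Marginal distribution of lesion grades.
#' @param prob_modal Probability that an image shows its lesion's grade.
#' @param noise_sd_um Contour noise level passed to the phantoms.
#' @param seed Seed; defaults to `config$seed`.
#' @return Invisibly, a list with `contours`, `manifest` and per-image
#'   `truth`.
#' @export
run_simulate <- function(out_dir = NULL, config = pipeline_config(),
                         n_lesions = 12, images_per_lesion = c(6, 12),
                         grade_probs = c(21, 48, 11) / 80,
                         prob_modal = 0.8, noise_sd_um = 2,
                         seed = config$seed) {
  stopifnot(prob_modal > 0, prob_modal <= 1)
  sim <- function() {
    raw <- grade_probs / sum(grade_probs) * n_lesions
    counts <- floor(raw)
    rem <- n_lesions - sum(counts)
    if (rem > 0) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    lesion_grade <- sample(rep(1:3, times = counts))
    all_contours <- list()
    manifest <- list()
    truth <- list()
    for (li in seq_len(n_lesions)) {
      lid <- sprintf("L%03d", li)
      g <- lesion_grade[li]
      n_img <- sample_range(images_per_lesion[1], images_per_lesion[2])
      adjacent <- intersect(c(g - 1, g + 1), 1:3)
      img_grades <- vapply(seq_len(n_img), function(i) {
        if (stats::runif(1) < prob_modal || length(adjacent) == 0) g
        else sample(adjacent, 1)
      }, numeric(1))
      for (ii in seq_len(n_img)) {
        iid <- sprintf("%s_img%03d", lid, ii)
        spec <- phantom_spec(
          grade = img_grades[ii], noise_sd_um = noise_sd_um,
          lateral_pitch_um = config$lateral_pitch_um,
          axial_pitch_um = config$axial_pitch_um
        )
        ph <- generate_phantom_impl(spec, iid)
        all_contours[[length(all_contours) + 1]] <- ph$contours
        truth[[length(truth) + 1]] <- tibble::tibble(
          lesion_id = lid, image_id = iid,
          true_grade = pro_grade(img_grades[ii]),
          true_n_protrusions = nrow(ph$truth$protrusions)
        )
      }
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        lesion_id = lid,
        image_id = sprintf("%s_img%03d", lid, seq_len(n_img)),
        source = "contours.csv",
        expert_average_grade = as.character(
          aggregate_average(pro_grade(img_grades))),
        expert_max_grade = as.character(
          aggregate_max10(pro_grade(img_grades),
                          fraction = config$max_rule_fraction)),
        exclude = FALSE, exclude_reason = NA_character_
      )
    }
    list(contours = dplyr::bind_rows(all_contours),
         manifest = dplyr::bind_rows(manifest),
         truth = dplyr::bind_rows(truth))
  }
  out <- if (!is.null(seed)) withr::with_seed(seed, sim()) else sim()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_contours_csv(out$contours, file.path(out_dir, "contours.csv"))
    readr::write_csv(out$manifest, file.path(out_dir, "manifest.csv"),
                     progress = FALSE)
    readr::write_csv(out$truth, file.path(out_dir, "truth.csv"),
                     progress = FALSE)
  }
  invisible(out)
}
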