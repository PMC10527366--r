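#' Specify a ground-truthed contour phantom
#'
#' A phantom is a synthetic surface/DEJ contour pair with known protrusion
#' geometry, used to validate the measurement pipeline end to end. The
#' surface is a low-amplitude smooth wave; the DEJ is the surface offset by
#' a base epidermal thickness, plus smooth random variation, plus a set of
#' disjoint raised-cosine downgrowths whose count, width and depth emulate
#' the target PRO grade (none for PRO I, shallow wide buds for PRO II, deep
#' narrow spikes for PRO III).
#'
#' Raised-cosine bumps have compact support, so ledge widths and estimator
#' crossings are well defined. Contour "noise" models the smooth
#' micro-undulation of a segmented DEJ (a rete-ridge-like texture), not
#' pixel noise: a random-phase sinusoid with RMS amplitude `noise_sd_um`
#' and a wavelength drawn from `noise_wavelength_um`. Its peak excursion
#' is bounded at `sqrt(2) * noise_sd_um`, so the default 5 um detection
#' floor is a true noise floor: at `noise_sd_um = 2` the texture alone can
#' never register as a protrusion.
#'
#' Grade defaults: PRO I has no protrusions; PRO II samples 1-3 bumps with
#' widths 80-180 um and depths 20-40 um, capped at a depth/width aspect of
#' 0.3 (comfortably sub-hemispherical); PRO III samples 2-5 bumps with
#' widths 40-100 um and depths 80-150 um.
#'
#' @param grade Target PRO grade (anything [pro_grade()] accepts).
#' @param n_protrusions Integer count or length-2 inclusive range; `NULL`
#'   uses the grade default.
#' @param depth_range,width_range Length-2 um ranges for sampled bump depth
#'   and width; `NULL` uses the grade default.
#' @param max_aspect Cap on sampled depth/width (applied by lowering depth);
#'   `NULL` uses the grade default (0.3 for PRO II, none otherwise).
#' @param base_thickness_um Flat epidermal thickness (um). Default 120,
#'   a typical thickened AK epidermis.
#' @param surface_depth_um Mean surface depth below the image top (um).
#' @param surface_waviness_um Amplitude of the surface wave (um).
#' @param surface_period_um Period of the surface wave; `NULL` = one period
#'   across the field.
#' @param noise_sd_um RMS amplitude of the smooth DEJ micro-undulation
#'   (um); peak amplitude is `sqrt(2)` times this.
#' @param noise_wavelength_um Length-2 range the texture wavelength is
#'   drawn from (um).
#' @param width_px Number of lateral columns. Default 1091 (about 1.2 mm at
#'   1.1 um pitch, the standard LC-OCT field).
#' @param lateral_pitch_um,axial_pitch_um Sampling pitches (um).
#' @param seed Optional integer seed; generation is bit-reproducible under
#'   a fixed seed.
#' @return A list of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec("PRO II", seed = 1)
#' ph <- generate_phantom(spec)
#' ph$truth$protrusions
#' @export
phantom_spec <- function(grade = "PRO II", n_protrusions = NULL,
                         depth_range = NULL, width_range = NULL,
                         max_aspect = NULL,
                         base_thickness_um = 120, surface_depth_um = 30,
                         surface_waviness_um = 2, surface_period_um = NULL,
                         noise_sd_um = 0, noise_wavelength_um = c(100, 200),
                         width_px = 1091, lateral_pitch_um = 1.1,
                         axial_pitch_um = 1.3, seed = NULL) {
  g <- as.integer(pro_grade(grade))
  defaults <- switch(g,
    list(n = c(0L, 0L), depth = c(0, 0), width = c(0, 0), aspect = NULL),
    list(n = c(1L, 3L), depth = c(20, 40), width = c(80, 180), aspect = 0.3),
    list(n = c(2L, 5L), depth = c(80, 150), width = c(40, 100), aspect = NULL)
  )
  if (is.null(n_protrusions)) n_protrusions <- defaults$n
  if (length(n_protrusions) == 1) n_protrusions <- rep(n_protrusions, 2)
  if (is.null(depth_range)) depth_range <- defaults$depth
  if (is.null(width_range)) width_range <- defaults$width
  if (is.null(max_aspect)) max_aspect <- defaults$aspect
  stopifnot(
    width_px >= 2, lateral_pitch_um > 0, axial_pitch_um > 0,
    base_thickness_um > 0, surface_depth_um >= 0, surface_waviness_um >= 0,
    noise_sd_um >= 0, length(noise_wavelength_um) %in% c(1, 2),
    all(noise_wavelength_um > 0),
    n_protrusions[1] >= 0, n_protrusions[1] <= n_protrusions[2],
    depth_range[1] <= depth_range[2], width_range[1] <= width_range[2]
  )
  if (g > 1 && (depth_range[1] <= 0 || width_range[1] <= 0)) {
    rlang::abort("Protruding grades need positive depth and width ranges.")
  }
  structure(
    list(
      grade = pro_grade(g), n_protrusions = as.integer(n_protrusions),
      depth_range = depth_range, width_range = width_range,
      max_aspect = max_aspect,
      base_thickness_um = base_thickness_um,
      surface_depth_um = surface_depth_um,
      surface_waviness_um = surface_waviness_um,
      surface_period_um = surface_period_um,
      noise_sd_um = noise_sd_um,
      noise_wavelength_um = if (length(noise_wavelength_um) == 1)
        rep(noise_wavelength_um, 2) else noise_wavelength_um,
      width_px = as.integer(width_px),
      lateral_pitch_um = lateral_pitch_um, axial_pitch_um = axial_pitch_um,
      seed = seed
    ),
    class = "phantom_spec"
  )
}

# sample() treats a length-1 numeric as 1:n; guard degenerate ranges.
sample_range <- function(lo, hi) {
  if (lo >= hi) lo else sample(seq(lo, hi), 1)
}

# Smooth bounded micro-undulation: random-phase sinusoid with RMS `sd`
# (peak sqrt(2) * sd) and a wavelength drawn from `wavelength_range`.
dej_texture <- function(pos_um, sd, wavelength_range) {
  if (sd == 0) return(rep(0, length(pos_um)))
  lambda <- stats::runif(1, wavelength_range[1], wavelength_range[2])
  phase <- stats::runif(1, 0, 2 * pi)
  sqrt(2) * sd * sin(2 * pi * pos_um / lambda + phase)
}

# Sample disjoint bump centers by rejection; error if packing infeasible.
place_bumps <- function(n, widths, field_um, buffer_um = 20) {
  centers <- numeric(0)
  placed_w <- numeric(0)
  for (i in seq_len(n)) {
    w <- widths[i]
    lo <- w / 2 + buffer_um
    hi <- field_um - w / 2 - buffer_um
    if (hi <= lo) {
      rlang::abort("Infeasible packing: protrusion wider than the field.")
    }
    ok <- FALSE
    for (try in 1:200) {
      c0 <- stats::runif(1, lo, hi)
      if (all(abs(c0 - centers) >= (w + placed_w) / 2 + buffer_um)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      rlang::abort("Infeasible packing: cannot place disjoint protrusions.")
    }
    centers <- c(centers, c0)
    placed_w <- c(placed_w, w)
  }
  centers
}

#' Generate a phantom contour pair with ground truth
#'
#' @param spec A [phantom_spec()].
#' @param image_id Identifier for the generated image.
#' @return A list with `contours` (a contour tibble) and `truth` (a list
#'   with the realised `grade`, a `protrusions` tibble of sampled
#'   `center_um`, `width_um`, `depth_um`, and the `spec`).
#' @export
generate_phantom <- function(spec, image_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) {
    return(withr::with_seed(spec$seed,
                            generate_phantom_impl(spec, image_id)))
  }
  generate_phantom_impl(spec, image_id)
}

generate_phantom_impl <- function(spec, image_id) {
  w <- spec$width_px
  p <- spec$lateral_pitch_um
  pos <- (seq_len(w) - 1) * p
  field <- (w - 1) * p
  period <- spec$surface_period_um %||% field
  phase <- stats::runif(1, 0, 2 * pi)
  surface <- spec$surface_depth_um +
    spec$surface_waviness_um * sin(2 * pi * pos / period + phase)
  n <- sample_range(spec$n_protrusions[1], spec$n_protrusions[2])
  if (n > 0) {
    widths <- stats::runif(n, spec$width_range[1], spec$width_range[2])
    depths <- stats::runif(n, spec$depth_range[1], spec$depth_range[2])
    if (!is.null(spec$max_aspect)) {
      depths <- pmin(depths, spec$max_aspect * widths)
    }
    centers <- place_bumps(n, widths, field)
  } else {
    widths <- depths <- centers <- numeric(0)
  }
  bump <- rep(0, w)
  for (i in seq_len(n)) {
    u <- (pos - centers[i]) / widths[i]
    inside <- abs(u) <= 0.5
    bump[inside] <- bump[inside] +
      depths[i] / 2 * (1 + cos(2 * pi * u[inside]))
  }
  noise <- dej_texture(pos, spec$noise_sd_um, spec$noise_wavelength_um)
  dej <- surface + spec$base_thickness_um + noise + bump
  ord <- order(centers)
  list(
    contours = contour_pair(surface, dej, p, image_id = image_id),
    truth = list(
      grade = spec$grade,
      protrusions = tibble::tibble(
        center_um = centers[ord], width_um = widths[ord],
        depth_um = depths[ord]
      ),
      spec = spec
    )
  )
}

#' Generate a batch of phantoms under one seed
#'
#' @param spec A [phantom_spec()] (its own `seed` is ignored here).
#' @param n Number of phantoms.
#' @param image_prefix Prefix for generated image ids.
#' @param seed Integer seed for the whole batch.
#' @return A list with `contours` (all images stacked) and `truth` (a
#'   tibble with one row per image: `image_id`, `grade`,
#'   `true_n_protrusions`, `true_max_depth_um`, nested `true_protrusions`).
#' @export
generate_phantoms <- function(spec, n, image_prefix = "phantom",
                              seed = NULL) {
  gen <- function() {
    out <- purrr::map(seq_len(n), function(i) {
      id <- sprintf("%s_%04d", image_prefix, i)
      ph <- generate_phantom_impl(spec, id)
      list(
        contours = ph$contours,
        truth = tibble::tibble(
          image_id = id,
          grade = ph$truth$grade,
          true_n_protrusions = nrow(ph$truth$protrusions),
          true_max_depth_um = if (nrow(ph$truth$protrusions) == 0) 0 else
            max(ph$truth$protrusions$depth_um),
          true_protrusions = list(ph$truth$protrusions)
        )
      )
    })
    list(
      contours = dplyr::bind_rows(purrr::map(out, "contours")),
      truth = dplyr::bind_rows(purrr::map(out, "truth"))
    )
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}

#' Rasterize a contour pair to a B-scan-like mask and image
#'
#' Produces the 3-class label mask implied by the contours (0 above skin,
#' 1 epidermis, 2 dermis) and a stylised grayscale B-scan with per-layer
#' mean intensities and multiplicative gamma speckle. The mask feeds
#' [extract_contours()] for round-trip testing: recovered contours agree
#' with the input within one axial pixel. The speckle model is stylised,
#' not a physical OCT point-spread/speckle simulation.
#'
#' @param contours A single-image contour tibble.
#' @param depth_px Number of axial rows. Default 385 (about 0.5 mm at
#'   1.3 um pitch).
#' @param axial_pitch_um Axial pitch (um per row).
#' @param layer_means Mean intensities for (above skin, epidermis, dermis).
#' @param speckle_shape Gamma shape of the multiplicative speckle; larger
#'   is smoother. `Inf` disables speckle.
#' @param seed Optional seed; speckle is reproducible under a fixed seed.
#' @return A list with `mask` (integer matrix) and `image` (numeric
#'   matrix), both `depth_px` rows by `W` columns.
#' @export
rasterize_bscan <- function(contours, depth_px = 385, axial_pitch_um = 1.3,
                            layer_means = c(0.15, 0.65, 0.40),
                            speckle_shape = 4, seed = NULL) {
  validate_contours(contours)
  if (length(unique(contours$image_id)) != 1) {
    rlang::abort("rasterize_bscan() takes a single image.")
  }
  contours <- dplyr::arrange(contours, .data$x)
  s <- contours$surface_um
  d <- contours$dej_um
  r_s <- ceiling(s / axial_pitch_um - 1e-9)
  r_d <- ceiling(d / axial_pitch_um - 1e-9)
  if (any(r_d > depth_px - 1)) {
    rlang::abort("DEJ contour exceeds the axial field depth.")
  }
  if (any(r_s < 1)) {
    rlang::abort("Surface too shallow: no background row above the skin.")
  }
  if (any(r_d <= r_s)) {
    rlang::abort("Epidermis thinner than one axial pixel at some column.")
  }
  w <- length(s)
  rows <- matrix(0:(depth_px - 1), nrow = depth_px, ncol = w)
  mask <- matrix(0L, depth_px, w)
  mask[rows >= matrix(r_s, depth_px, w, byrow = TRUE)] <- 1L
  mask[rows >= matrix(r_d, depth_px, w, byrow = TRUE)] <- 2L
  img_fun <- function() {
    base <- matrix(layer_means[mask + 1L], depth_px, w)
    if (is.finite(speckle_shape)) {
      base * matrix(
        stats::rgamma(depth_px * w, shape = speckle_shape,
                      rate = speckle_shape),
        depth_px, w
      )
    } else {
      base
    }
  }
  image <- if (!is.null(seed)) withr::with_seed(seed, img_fun()) else img_fun()
  list(mask = mask, image = image)
}

# Row-stochastic grade confusion emulating the error structure reported
# for automated average-grade PRO scoring of AK lesions: adjacent-grade
# confusions only, with PRO III the hardest to recover.
default_ai_confusion <- function() {
  rbind(
    c(14, 7, 0) / 21,
    c(10, 38, 0) / 48,
    c(0, 6, 5) / 11
  )
}

#' Specify a simulated lesion cohort
#'
#' Generates lesion-level true grades with a study-like marginal
#' distribution, plus simulated expert and automated ("AI") grades drawn
#' from row-stochastic confusion matrices conditional on the truth. The
#' default grade marginals are 21/48/11 of 80 (the PRO I/II/III mix of a
#' typical AK lesion cohort); the default AI confusion reproduces the
#' adjacent-grade error structure of automated average-rule scoring, and
#' the expert is assumed exact.
#'
#' @param n_lesions Number of lesions.
#' @param images_per_lesion Length-2 inclusive range (or single value) of
#'   images per lesion.
#' @param grade_probs Length-3 marginal distribution over PRO I-III
#'   (normalised internally).
#' @param allocation `"exact"` allocates grade counts deterministically by
#'   largest remainder then shuffles; `"multinomial"` samples them.
#' @param expert_confusion,ai_confusion 3x3 row-stochastic matrices:
#'   `P(observed grade | true grade)`.
#' @param seed Optional integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_lesions = 80, images_per_lesion = c(50, 400),
                        grade_probs = c(21, 48, 11) / 80,
                        allocation = c("exact", "multinomial"),
                        expert_confusion = diag(3),
                        ai_confusion = default_ai_confusion(),
                        seed = NULL) {
  allocation <- match.arg(allocation)
  if (length(images_per_lesion) == 1) {
    images_per_lesion <- rep(images_per_lesion, 2)
  }
  stopifnot(
    n_lesions >= 1, length(grade_probs) == 3, all(grade_probs >= 0),
    sum(grade_probs) > 0, images_per_lesion[1] >= 1,
    images_per_lesion[1] <= images_per_lesion[2],
    dim(expert_confusion) == c(3, 3), dim(ai_confusion) == c(3, 3),
    abs(rowSums(expert_confusion) - 1) < 1e-8,
    abs(rowSums(ai_confusion) - 1) < 1e-8,
    expert_confusion >= 0, ai_confusion >= 0
  )
  structure(
    list(
      n_lesions = as.integer(n_lesions),
      images_per_lesion = as.integer(images_per_lesion),
      grade_probs = grade_probs / sum(grade_probs),
      allocation = allocation,
      expert_confusion = expert_confusion,
      ai_confusion = ai_confusion,
      seed = seed
    ),
    class = "cohort_spec"
  )
}

#' Simulate a lesion cohort with paired expert and automated grades
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per lesion: `lesion_id`, `n_images`,
#'   `true_grade`, `expert_grade`, `ai_grade` (all PRO grade factors).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_lesions = 20, seed = 1))
#' grade_table(cohort$expert_grade, cohort$ai_grade)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gen <- function() {
    n <- spec$n_lesions
    if (spec$allocation == "exact") {
      raw <- spec$grade_probs * n
      counts <- floor(raw)
      rem <- n - sum(counts)
      if (rem > 0) {
        extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1
      }
      truth <- sample(rep(1:3, times = counts))
    } else {
      truth <- sample(1:3, n, replace = TRUE, prob = spec$grade_probs)
    }
    draw <- function(confusion) {
      vapply(truth, function(g) {
        sample(1:3, 1, prob = confusion[g, ])
      }, integer(1))
    }
    tibble::tibble(
      lesion_id = sprintf("L%04d", seq_len(n)),
      n_images = vapply(seq_len(n), function(i) {
        sample_range(spec$images_per_lesion[1], spec$images_per_lesion[2])
      }, numeric(1)),
      true_grade = pro_grade(truth),
      expert_grade = pro_grade(draw(spec$expert_confusion)),
      ai_grade = pro_grade(draw(spec$ai_confusion))
    )
  }
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, gen()) else gen()
}
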