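#' Build a contour tibble for one image
#'
#' The geometric substrate of the whole pipeline is a pair of single-valued
#' depth profiles per image: the skin surface and the dermo-epidermal
#' junction (DEJ), one depth value per lateral column, in micrometres.
#' Depth increases downward from the image top, so the DEJ is always
#' numerically greater than or equal to the surface.
#'
#' Contour tibbles hold one row per lateral column per image, with 0-based
#' column index `x` (matching the on-disk CSV convention), and may stack
#' several images distinguished by `image_id`.
#'
#' @param surface_um Numeric vector of surface depths (um), length >= 2.
#' @param dej_um Numeric vector of DEJ depths (um), same length.
#' @param lateral_pitch_um Lateral sampling pitch in um per column
#'   (default 1.1, the LC-OCT lateral resolution).
#' @param image_id Identifier for the image.
#' @return A tibble with columns `image_id`, `x`, `surface_um`, `dej_um`,
#'   `lateral_pitch_um`.
#' @examples
#' cp <- contour_pair(rep(20, 50), rep(120, 50))
#' undulation_index(cp)
#' @export
contour_pair <- function(surface_um, dej_um, lateral_pitch_um = 1.1,
                         image_id = "image") {
  out <- tibble::tibble(
    image_id = as.character(image_id),
    x = seq_along(surface_um) - 1L,
    surface_um = as.numeric(surface_um),
    dej_um = as.numeric(dej_um),
    lateral_pitch_um = lateral_pitch_um
  )
  validate_contours(out)
}

#' Validate a contour tibble
#'
#' Checks the invariants every downstream operation relies on: per image,
#' at least two columns with contiguous 0-based `x`, finite depths, a single
#' positive lateral pitch, and `dej_um >= surface_um` everywhere (the DEJ
#' cannot lie above the skin surface).
#'
#' @param contours A contour tibble (see [contour_pair()]).
#' @return The input, invisibly unchanged, for piping.
#' @export
validate_contours <- function(contours) {
  need <- c("image_id", "x", "surface_um", "dej_um", "lateral_pitch_um")
  missing <- setdiff(need, names(contours))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Contour tibble lacks column(s): %s.",
                         paste(missing, collapse = ", ")))
  }
  split <- dplyr::group_split(dplyr::group_by(contours, .data$image_id))
  for (g in split) {
    id <- g$image_id[[1]]
    if (nrow(g) < 2) {
      rlang::abort(sprintf("Image '%s' has fewer than 2 columns.", id))
    }
    if (!identical(sort(g$x), seq_len(nrow(g)) - 1L) &&
        !all(sort(g$x) == seq_len(nrow(g)) - 1)) {
      rlang::abort(sprintf(
        "Image '%s': x must be the contiguous 0-based indices 0..%d.",
        id, nrow(g) - 1L))
    }
    if (!all(is.finite(g$surface_um)) || !all(is.finite(g$dej_um))) {
      rlang::abort(sprintf("Image '%s' has non-finite depth values.", id))
    }
    if (length(unique(g$lateral_pitch_um)) != 1 ||
        g$lateral_pitch_um[[1]] <= 0) {
      rlang::abort(sprintf(
        "Image '%s' must carry a single positive lateral_pitch_um.", id))
    }
    if (any(g$dej_um < g$surface_um)) {
      rlang::abort(sprintf(
        "Image '%s': DEJ lies above the skin surface at some columns.", id))
    }
  }
  invisible(contours)
}

#' Extract surface and DEJ contours from a 3-class label mask
#'
#' Bridges pixelwise skin-layer segmentations (e.g., from a CNN) to the
#' contour-based geometry. The mask is a matrix with rows running down in
#' depth and values 0 = above skin, 1 = epidermis, 2 = dermis. Per column,
#' the surface is the depth of the first epidermis pixel and the DEJ the
#' depth of the first dermis pixel, converted by the axial pitch; row `r`
#' (1-based in R) sits at depth `(r - 1) * axial_pitch_um`.
#'
#' @param mask Integer matrix of labels 0/1/2, rows = depth, columns =
#'   lateral position.
#' @param axial_pitch_um Axial pitch in um per row (default 1.3).
#' @param lateral_pitch_um Lateral pitch in um per column (default 1.1).
#' @param image_id Identifier for the image.
#' @return A contour tibble (see [contour_pair()]).
#' @examples
#' mask <- rbind(matrix(0L, 10, 8), matrix(1L, 90, 8), matrix(2L, 30, 8))
#' extract_contours(mask)
#' @export
extract_contours <- function(mask, axial_pitch_um = 1.3,
                             lateral_pitch_um = 1.1, image_id = "image") {
  if (!is.matrix(mask)) rlang::abort("`mask` must be a matrix.")
  bad <- !mask %in% c(0L, 1L, 2L)
  if (any(bad)) rlang::abort("Mask labels must be 0 (above skin), 1 (epidermis) or 2 (dermis).")
  first_epi <- apply(mask == 1, 2, function(v) which(v)[1])
  first_der <- apply(mask == 2, 2, function(v) which(v)[1])
  no_epi <- which(is.na(first_epi))
  if (length(no_epi) > 0) {
    rlang::abort(sprintf(
      "Image '%s': no epidermis pixel in mask column %d (1-based).",
      image_id, no_epi[[1]]))
  }
  no_der <- which(is.na(first_der))
  if (length(no_der) > 0) {
    rlang::abort(sprintf(
      "Image '%s': no dermis pixel in mask column %d (1-based).",
      image_id, no_der[[1]]))
  }
  inverted <- which(first_der <= first_epi)
  if (length(inverted) > 0) {
    rlang::abort(sprintf(
      "Image '%s': dermis above epidermis in mask column %d (1-based).",
      image_id, inverted[[1]]))
  }
  contour_pair(
    surface_um = (first_epi - 1) * axial_pitch_um,
    dej_um = (first_der - 1) * axial_pitch_um,
    lateral_pitch_um = lateral_pitch_um,
    image_id = image_id
  )
}

#' Read a label mask from a PNG or TIFF file
#'
#' Single-channel image whose distinct pixel values are interpreted, in
#' increasing intensity order, as labels 0 (above skin), 1 (epidermis),
#' 2 (dermis). This tolerates masks stored either with raw labels
#' \{0, 1, 2\} or with scaled intensities (e.g., \{0, 127, 255\}).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An integer label matrix suitable for [extract_contours()].
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        rlang::abort("Reading PNG masks requires the 'png' package.")
      }
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        rlang::abort("Reading TIFF masks requires the 'tiff' package.")
      }
      tiff::readTIFF(path)
    },
    rlang::abort(sprintf("Unsupported mask format '.%s'.", ext))
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  u <- sort(unique(as.vector(img)))
  if (length(u) > 3) {
    rlang::abort(sprintf(
      "Mask '%s' has %d distinct values; expected at most 3 labels.",
      path, length(u)))
  }
  matrix(match(as.vector(img), u) - 1L, nrow = nrow(img))
}

#' Read and write contour CSV files
#'
#' The on-disk interchange format is one row per lateral column per image
#' with columns `image_id`, `x_index` (0-based), `surface_um`, `dej_um` and
#' optionally `lateral_pitch_um` (filled with `lateral_pitch_um` when
#' absent).
#'
#' @param path File path.
#' @param lateral_pitch_um Pitch used when the file carries none.
#' @return `read_contours_csv()` returns a contour tibble;
#'   `write_contours_csv()` returns `path` invisibly.
#' @export
read_contours_csv <- function(path, lateral_pitch_um = 1.1) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("image_id", "x_index", "surface_um", "dej_um")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Contour CSV '%s' lacks column(s): %s.",
                         path, paste(missing, collapse = ", ")))
  }
  if (!"lateral_pitch_um" %in% names(df)) {
    df$lateral_pitch_um <- lateral_pitch_um
  }
  out <- tibble::tibble(
    image_id = as.character(df$image_id),
    x = as.integer(df$x_index),
    surface_um = as.numeric(df$surface_um),
    dej_um = as.numeric(df$dej_um),
    lateral_pitch_um = as.numeric(df$lateral_pitch_um)
  )
  out <- dplyr::arrange(out, .data$image_id, .data$x)
  validate_contours(out)
  out
}

#' @param contours A contour tibble.
#' @rdname read_contours_csv
#' @export
write_contours_csv <- function(contours, path) {
  validate_contours(contours)
  out <- tibble::tibble(
    image_id = contours$image_id,
    x_index = contours$x,
    surface_um = contours$surface_um,
    dej_um = contours$dej_um,
    lateral_pitch_um = contours$lateral_pitch_um
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
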