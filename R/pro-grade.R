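#' The PRO I-III ordinal grade
#'
#' Actinic keratoses are graded by the basal growth pattern of atypical
#' keratinocytes at the dermo-epidermal junction (DEJ): PRO I shows no
#' downward protrusion (crowded basal cells only), PRO II small hemispherical
#' buds protruding into the papillary dermis, and PRO III spiky or filiform
#' elongations. `pro_grade()` builds an ordered factor with levels
#' `"PRO I" < "PRO II" < "PRO III"` from integers (1-3), roman numerals
#' (`"I"`, `"II"`, `"III"`), or full labels (`"PRO II"`).
#'
#' @param x Integer, character or factor vector of grades.
#' @return An ordered factor with levels `pro_levels()`.
#' @examples
#' pro_grade(c(1, 3, 2))
#' pro_grade(c("II", "PRO III"))
#' @export
pro_grade <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & (!x %in% 1:3)
    if (any(bad)) {
      rlang::abort(sprintf(
        "PRO grades must be 1, 2 or 3; got %s.",
        paste(unique(x[bad]), collapse = ", ")
      ))
    }
    idx <- as.integer(x)
  } else {
    lab <- toupper(trimws(as.character(x)))
    lab <- sub("^PRO[ _-]*", "", lab)
    map <- c("I" = 1L, "II" = 2L, "III" = 3L, "1" = 1L, "2" = 2L, "3" = 3L)
    idx <- unname(map[lab])
    bad <- is.na(idx) & !is.na(x)
    if (any(bad)) {
      rlang::abort(sprintf(
        "Cannot interpret %s as PRO grades.",
        paste(sQuote(unique(as.character(x)[bad])), collapse = ", ")
      ))
    }
  }
  factor(pro_levels()[idx], levels = pro_levels(), ordered = TRUE)
}

#' @rdname pro_grade
#' @export
pro_levels <- function() c("PRO I", "PRO II", "PRO III")

#' @rdname pro_grade
#' @return `pro_grade_int()` returns the grade as an integer in 1-3.
#' @export
pro_grade_int <- function(x) {
  if (is.numeric(x)) {
    as.integer(pro_grade(x))  # validates range
  } else {
    as.integer(pro_grade(x))
  }
}
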