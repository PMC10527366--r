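#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a weighted-kappa object
#'
#' @param x A [weighted_kappa()] object.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `std.error`, `statistic`
#'   (null z), `p.value`, `conf.low`, `conf.high`, `weighting`, `method`.
#' @method tidy weighted_kappa
#' @export
tidy.weighted_kappa <- function(x, ...) {
  tibble::tibble(
    estimate = x$kappa, std.error = x$se, statistic = x$statistic,
    p.value = x$p.value, conf.low = x$conf.low, conf.high = x$conf.high,
    weighting = x$weighting, method = x$ci_method
  )
}

#' @rdname tidy.weighted_kappa
#' @return `glance()` adds the weighted observed/chance proportions and n.
#' @method glance weighted_kappa
#' @export
glance.weighted_kappa <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa, conf.low = x$conf.low, conf.high = x$conf.high,
    p.value = x$p.value, p.observed = x$po, p.expected = x$pe, n = x$n
  )
}

#' Tidy a grade contingency table
#'
#' @param x A `grade_table`.
#' @param ... Unused.
#' @return One row per cell: `visual`, `automated`, `n`.
#' @method tidy grade_table
#' @export
tidy.grade_table <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    visual = pro_grade(rep(1:3, times = 3)),
    automated = pro_grade(rep(1:3, each = 3)),
    n = as.integer(m[cbind(rep(1:3, times = 3), rep(1:3, each = 3))])
  )
}

#' @rdname tidy.grade_table
#' @return `glance()` returns the [agreement_stats()] row.
#' @method glance grade_table
#' @export
glance.grade_table <- function(x, ...) {
  agreement_stats(x)
}
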