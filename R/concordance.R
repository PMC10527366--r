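#' Visual-vs-automated grade contingency table
#'
#' Builds the 3x3 table of paired lesion grades with visual (expert)
#' grades on the rows and automated grades on the columns.
#'
#' @param visual,automated Equal-length paired grade vectors (anything
#'   [pro_grade()] accepts).
#' @return A 3x3 integer matrix of class `grade_table` with dimnames
#'   `visual` x `automated`.
#' @examples
#' gt <- grade_table(c(1, 1, 2, 3), c(1, 2, 2, 3))
#' agreement_stats(gt)
#' @export
grade_table <- function(visual, automated) {
  v <- pro_grade(visual)
  a <- pro_grade(automated)
  if (length(v) != length(a)) {
    rlang::abort("`visual` and `automated` must have equal length.")
  }
  if (length(v) == 0) rlang::abort("Cannot build a table from empty input.")
  if (anyNA(v) || anyNA(a)) rlang::abort("Grades must not be missing.")
  counts <- unclass(table(visual = v, automated = a))
  structure(matrix(as.integer(counts), 3, 3,
                   dimnames = list(visual = pro_levels(),
                                   automated = pro_levels())),
            class = c("grade_table", "matrix"))
}

#' Coerce a 3x3 count matrix to a grade table
#'
#' @param x A 3x3 matrix of non-negative counts, rows = visual grade,
#'   columns = automated grade.
#' @return A `grade_table`.
#' @export
as_grade_table <- function(x) {
  if (inherits(x, "grade_table")) return(x)
  x <- as.matrix(x)
  if (!all(dim(x) == c(3, 3)) || any(x < 0) || sum(x) == 0) {
    rlang::abort("Expected a 3x3 matrix of non-negative counts with a positive total.")
  }
  structure(matrix(as.integer(round(x)), 3, 3,
                   dimnames = list(visual = pro_levels(),
                                   automated = pro_levels())),
            class = c("grade_table", "matrix"))
}

#' @export
print.grade_table <- function(x, ...) {
  cat(format_grade_table(x), sep = "\n")
  invisible(x)
}

#' Render a grade table as aligned text
#'
#' @param x A `grade_table`.
#' @param title Optional heading line.
#' @return A character vector of lines.
#' @export
format_grade_table <- function(x, title = "visual PRO score vs automated PRO score") {
  m <- unclass(x)
  wide <- max(nchar(c(pro_levels(), as.character(m))))
  fmt <- function(v) formatC(v, width = wide + 2)
  lines <- c(
    title,
    paste0(formatC("", width = 9), paste(fmt(pro_levels()), collapse = "")),
    vapply(1:3, function(i) {
      paste0(formatC(pro_levels()[i], width = 9, flag = "-"),
             paste(fmt(m[i, ]), collapse = ""))
    }, character(1)),
    sprintf("n = %d lesions", sum(m))
  )
  lines
}

#' Agreement statistics of a grade table
#'
#' Percent agreement (diagonal share), per-class recall (diagonal cell
#' over visual row total; `NA` when a grade is absent from the visual
#' margin), and the over- and under-call rates: the share of lesions the
#' automated grading placed above (overestimated) or below
#' (underestimated) the visual grade. The three shares
#' agreement + over + under always sum to 1.
#'
#' @param table A `grade_table` (or 3x3 count matrix).
#' @return A one-row tibble: `n`, `agreement`, `over_rate`, `under_rate`,
#'   `recall_pro1`, `recall_pro2`, `recall_pro3` (all rates as fractions).
#' @export
agreement_stats <- function(table) {
  m <- unclass(as_grade_table(table))
  n <- sum(m)
  row_tot <- rowSums(m)
  recall <- unname(ifelse(row_tot > 0, diag(m) / row_tot, NA_real_))
  tibble::tibble(
    n = n,
    agreement = sum(diag(m)) / n,
    over_rate = sum(m[upper.tri(m)]) / n,
    under_rate = sum(m[lower.tri(m)]) / n,
    recall_pro1 = recall[1],
    recall_pro2 = recall[2],
    recall_pro3 = recall[3]
  )
}

kappa_weights <- function(k, weighting) {
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(weighting,
    linear = 1 - d / (k - 1),
    quadratic = 1 - (d / (k - 1))^2,
    unweighted = (d == 0) * 1
  )
}

#' Weighted Cohen's kappa for ordinal grade agreement
#'
#' Chance-corrected agreement between two raters of ordinal grades, with
#' disagreement penalties proportional to grade distance. With linear
#' weights `w_ij = 1 - |i - j| / (k - 1)`,
#' `kappa = (Po_w - Pe_w) / (1 - Pe_w)` where `Po_w` is the weighted
#' observed proportion and `Pe_w` the weighted chance proportion from the
#' outer product of the margins. The confidence interval uses the
#' large-sample (Fleiss-Cohen-Everitt) variance by default, with a seeded
#' percentile bootstrap as an alternative; the p-value tests `kappa = 0`
#' with the corresponding null variance.
#'
#' @param table A `grade_table`, or any square k x k count matrix with
#'   ordered categories (rows = visual, columns = automated).
#' @param weighting `"linear"` (default), `"quadratic"` or `"unweighted"`.
#' @param ci_method `"asymptotic"` (default) or `"bootstrap"`.
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `weighted_kappa` with `tidy()` and
#'   `glance()` methods; elements include `kappa`, `se`, `conf.low`,
#'   `conf.high`, `statistic` (null z), `p.value`, `po`, `pe`, `n`.
#' @examples
#' tab <- as_grade_table(rbind(c(14, 7, 0), c(10, 38, 0), c(0, 6, 5)))
#' weighted_kappa(tab)
#' @export
weighted_kappa <- function(table, weighting = c("linear", "quadratic",
                                                "unweighted"),
                           ci_method = c("asymptotic", "bootstrap"),
                           conf_level = 0.95, n_boot = 2000, seed = NULL) {
  weighting <- match.arg(weighting)
  ci_method <- match.arg(ci_method)
  m <- if (inherits(table, "grade_table")) {
    unclass(table)
  } else {
    mm <- as.matrix(table)
    if (nrow(mm) != ncol(mm) || nrow(mm) < 2 || any(mm < 0)) {
      rlang::abort("Expected a square matrix of non-negative counts.")
    }
    mm
  }
  n <- sum(m)
  if (sum(rowSums(m) > 0) < 2 || sum(colSums(m) > 0) < 2) {
    rlang::abort(paste(
      "Weighted kappa is undefined: fewer than two distinct grades",
      "in a margin."
    ))
  }
  k <- nrow(m)
  w <- kappa_weights(k, weighting)
  p <- m / n
  r <- rowSums(p)
  c_ <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, c_))
  kappa <- (po - pe) / (1 - pe)
  # Large-sample variance of the weighted kappa estimate
  # (Fleiss, Cohen & Everitt 1969).
  wr <- as.numeric(w %*% c_)   # row-average weights against column margin
  wc <- as.numeric(r %*% w)    # column-average weights against row margin
  wsum <- outer(wr, wc, "+")
  var_hat <- (sum(p * (w * (1 - pe) - wsum * (1 - po))^2) -
                (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(0, var_hat))
  # Null variance (kappa = 0) for the significance test.
  var0 <- (sum(outer(r, c_) * (w - wsum)^2) - pe^2) / (n * (1 - pe)^2)
  z <- kappa / sqrt(max(.Machine$double.eps, var0))
  p_value <- 2 * stats::pnorm(-abs(z))
  alpha <- 1 - conf_level
  boot <- NULL
  if (ci_method == "asymptotic") {
    q <- stats::qnorm(1 - alpha / 2)
    ci <- c(kappa - q * se, kappa + q * se)
  } else {
    point_kappa <- function(tab) {
      pp <- tab / sum(tab)
      poo <- sum(w * pp)
      pee <- sum(w * outer(rowSums(pp), colSums(pp)))
      (poo - pee) / (1 - pee)
    }
    cells <- expand.grid(i = seq_len(k), j = seq_len(k))
    idx <- rep(seq_len(nrow(cells)), as.vector(m))
    boot_fun <- function() {
      vapply(seq_len(n_boot), function(b) {
        res <- idx[sample.int(n, n, replace = TRUE)]
        tab <- matrix(tabulate(res, nbins = k * k), k, k)
        point_kappa(tab)
      }, numeric(1))
    }
    boot <- if (!is.null(seed)) withr::with_seed(seed, boot_fun()) else boot_fun()
    boot <- boot[is.finite(boot)]
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  }
  ci <- pmin(1, pmax(-1, ci))
  structure(
    list(
      kappa = kappa, se = se, conf.low = ci[1], conf.high = ci[2],
      conf.level = conf_level, statistic = z, p.value = p_value,
      po = po, pe = pe, n = n, weighting = weighting,
      ci_method = ci_method, table = m, boot = boot
    ),
    class = "weighted_kappa"
  )
}

#' @export
print.weighted_kappa <- function(x, ...) {
  cat(sprintf("Weighted Cohen's kappa (%s weights)\n", x$weighting))
  cat(sprintf("  kappa = %.3f, %d%% CI [%.3f, %.3f] (%s), p = %.3g, n = %d\n",
              x$kappa, round(100 * x$conf.level), x$conf.low, x$conf.high,
              x$ci_method, x$p.value, x$n))
  invisible(x)
}

#' Spearman correlation with a Fisher-z confidence interval
#'
#' Spearman's rank correlation with average ranks for ties (ties dominate
#' when one variable is a 3-level ordinal grade), and a confidence
#' interval from the Fisher z transform with variance `1.06 / (n - 3)`.
#' The p-value uses the t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric (or ordered factor) vectors, `n >= 4`.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `rho`, `conf.low`, `conf.high`, `p.value`,
#'   `n`.
#' @export
spearman_with_ci <- function(x, y, conf_level = 0.95) {
  if (is.factor(x)) x <- as.integer(x)
  if (is.factor(y)) y <- as.integer(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4) rlang::abort("Need at least 4 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Spearman correlation is undefined for constant input.")
  }
  rho <- stats::cor(x, y, method = "spearman")
  z <- atanh(min(1 - 1e-15, max(-1 + 1e-15, rho)))
  sez <- sqrt(1.06 / (n - 3))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(c(z - q * sez, z + q * sez))
  tstat <- rho * sqrt((n - 2) / max(.Machine$double.eps, 1 - rho^2))
  tibble::tibble(
    rho = rho, conf.low = ci[1], conf.high = ci[2],
    p.value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n
  )
}

#' Welch tests between adjacent PRO grades
#'
#' Two-sided Welch two-sample t-tests of a per-lesion (or per-image)
#' metric between adjacent grade groups (PRO I vs PRO II, PRO II vs
#' PRO III), the standard check that a morphometric increases across the
#' ordinal scale. Degenerate groups (zero variance) are flagged: the
#' p-value is 1 when the means are identical and 0 otherwise, with
#' `flagged = TRUE`. No multiple-testing correction is applied by default;
#' set `adjust = "holm"` to adjust.
#'
#' @param values Numeric metric values.
#' @param grades Paired grades (anything [pro_grade()] accepts).
#' @param adjust P-value adjustment method (see [stats::p.adjust()]);
#'   `"none"` by default.
#' @return A tibble with one row per adjacent pair: `comparison`,
#'   `estimate` (mean difference, higher minus lower grade), `statistic`,
#'   `df`, `p.value`, `n1`, `n2`, `flagged`.
#' @export
group_difference_test <- function(values, grades, adjust = "none") {
  g <- pro_grade(grades)
  stopifnot(length(values) == length(g))
  pairs <- list(c(1, 2), c(2, 3))
  rows <- purrr::map(pairs, function(pr) {
    a <- values[as.integer(g) == pr[1]]
    b <- values[as.integer(g) == pr[2]]
    comparison <- paste(pro_levels()[pr], collapse = " vs ")
    if (length(a) < 2 || length(b) < 2) {
      return(tibble::tibble(
        comparison = comparison, estimate = NA_real_,
        statistic = NA_real_, df = NA_real_, p.value = NA_real_,
        n1 = length(a), n2 = length(b), flagged = TRUE
      ))
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      same <- isTRUE(all.equal(mean(a), mean(b)))
      return(tibble::tibble(
        comparison = comparison, estimate = mean(b) - mean(a),
        statistic = if (same) 0 else Inf, df = NA_real_,
        p.value = if (same) 1 else 0,
        n1 = length(a), n2 = length(b), flagged = TRUE
      ))
    }
    tt <- stats::t.test(b, a, var.equal = FALSE)
    tibble::tibble(
      comparison = comparison, estimate = unname(tt$estimate[1] - tt$estimate[2]),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = tt$p.value, n1 = length(a), n2 = length(b),
      flagged = stats::sd(a) == 0 || stats::sd(b) == 0
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p.value <- stats::p.adjust(out$p.value, method = adjust)
  out
}
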