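# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's internal code paths: runs are found by a plain
# which/diff scan, crossings by uniroot() on the linear interpolant, arc
# length by an explicit loop, and kappa by the complement-weight identity.

# Maximal runs of 0-based columns where dej lies strictly below (deeper
# than) the reference.
oracle_above_runs <- function(dej, reference) {
  above <- which(dej > reference) - 1L
  if (length(above) == 0) return(list())
  brk <- c(0L, which(diff(above) > 1L), length(above))
  lapply(seq_len(length(brk) - 1L), function(i) {
    above[(brk[i] + 1L):brk[i + 1L]]
  })
}

# Crossing of the linear interpolant of e between 0-based columns a and b.
oracle_crossing <- function(e, a, b) {
  f <- stats::approxfun(seq_along(e) - 1, e)
  stats::uniroot(f, c(a, b), tol = 1e-12)$root
}

oracle_protrusions <- function(dej, reference, pitch, min_depth = 5,
                               margin = 10) {
  runs <- oracle_above_runs(dej, reference)
  e <- dej - reference
  w <- length(dej)
  rows <- lapply(runs, function(r) {
    first <- r[1]
    last <- r[length(r)]
    xs <- if (first == 0) 0 else oracle_crossing(e, first - 1, first)
    xe <- if (last == w - 1) w - 1 else oracle_crossing(e, last, last + 1)
    lo <- max(0, floor(xs - margin / pitch))
    hi <- min(w - 1, ceiling(xe + margin / pitch))
    seg <- dej[(lo:hi) + 1]
    data.frame(start_x = xs, end_x = xe,
               ledge_width_um = (xe - xs) * pitch,
               depth_um = max(seg) - min(seg),
               truncated = first == 0 || last == w - 1,
               first_col = first, last_col = last)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(start_x = numeric(), end_x = numeric(),
                     ledge_width_um = numeric(), depth_um = numeric(),
                     truncated = logical(), first_col = integer(),
                     last_col = integer())
  }
  df[df$depth_um >= min_depth, , drop = FALSE]
}

oracle_undulation <- function(dej, pitch) {
  s <- 0
  for (i in 2:length(dej)) {
    s <- s + sqrt(pitch^2 + (dej[i] - dej[i - 1])^2)
  }
  s / ((length(dej) - 1) * pitch)
}

# Linearly weighted kappa via the complement-weight (disagreement) identity
# kappa = 1 - sum(v * p) / sum(v * r %o% c) with v = |i - j| / (k - 1).
oracle_linear_kappa <- function(m) {
  k <- nrow(m)
  v <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  p <- m / sum(m)
  1 - sum(v * p) / sum(v * outer(rowSums(p), colSums(p)))
}

# Published congruence tables for average-rule (a) and max-10%-rule (b)
# automated grading of 80 AK lesions; rows = visual grade I-III.
table1a_counts <- function() rbind(c(14, 7, 0), c(10, 38, 0), c(0, 6, 5))
table1b_counts <- function() rbind(c(5, 15, 1), c(6, 31, 11), c(0, 4, 7))

# Expand a count table into paired grade vectors (row = visual).
table_to_pairs <- function(m) {
  idx <- cbind(rep(1:3, times = 3), rep(1:3, each = 3))
  counts <- m[idx]
  list(visual = rep(idx[, 1], counts), automated = rep(idx[, 2], counts))
}

# Metrics tibble with a hand-built protrusion list, for grading tests.
make_metrics <- function(depths, widths, image_id = "img", ui = 1.1) {
  tibble::tibble(
    image_id = image_id,
    undulation_index = ui,
    n_protrusions = length(depths),
    max_depth_um = if (length(depths) == 0) 0 else max(depths),
    mean_epidermal_thickness_um = 100,
    protrusions = list(tibble::tibble(
      protrusion = seq_along(depths),
      start_x = seq_along(depths) * 100,
      end_x = seq_along(depths) * 100 + widths / 1.1,
      ledge_width_um = widths,
      depth_um = depths,
      truncated = FALSE
    ))
  )
}

# White-noise contour pair exercising many crossings.
random_rough_pair <- function(w, id = "rough", pitch = 1.1, sd = 15) {
  contour_pair(rep(0, w), 100 + stats::rnorm(w, 0, sd),
               lateral_pitch_um = pitch, image_id = id)
}
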