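test_that("reference estimator offsets the surface by mean thickness", {
  flat <- contour_pair(rep(0, 50), rep(100, 50))
  ref <- estimate_reference(flat)
  expect_equal(ref$reference_um, rep(100, 50))
  expect_equal(unique(ref$mean_epidermal_thickness_um), 100)

  # zero-mean oscillation over full periods leaves the offset untouched
  x <- 0:99
  wav <- contour_pair(rep(0, 100), 100 + 20 * sin(2 * pi * 3 * x / 100))
  refw <- estimate_reference(wav)
  expect_equal(unique(refw$mean_epidermal_thickness_um), 100,
               tolerance = 1e-12)

  # arbitrary pair: equals an independently summed mean
  set.seed(21)
  s <- runif(80, 0, 30)
  d <- s + runif(80, 40, 140)
  cp <- contour_pair(s, d)
  acc <- 0
  for (i in 1:80) acc <- acc + (d[i] - s[i])
  expect_equal(unique(estimate_reference(cp)$mean_epidermal_thickness_um),
               acc / 80)
})

test_that("reference estimator is offset-equivariant", {
  set.seed(22)
  for (rep in 1:10) {
    s <- runif(40, 0, 20)
    d <- s + runif(40, 50, 150)
    c0 <- runif(1, -30, 30)
    r1 <- estimate_reference(contour_pair(s + 40, d + 40))
    r2 <- estimate_reference(contour_pair(s + 40 + c0, d + 40 + c0))
    expect_equal(r2$reference_um, r1$reference_um + c0, tolerance = 1e-10)
    expect_equal(r2$mean_epidermal_thickness_um,
                 r1$mean_epidermal_thickness_um, tolerance = 1e-10)
  }
})

test_that("a flat DEJ yields no protrusions and unit undulation", {
  flat <- contour_pair(rep(5, 64), rep(105, 64))
  expect_equal(nrow(detect_protrusions(flat)), 0)
  expect_equal(undulation_index(flat)$undulation_index, 1.0)
  m <- compute_image_metrics(flat)
  expect_equal(m$n_protrusions, 0L)
  expect_equal(m$max_depth_um, 0)
})

test_that("a single downgrowth is detected with interpolated crossings", {
  w <- 400
  x <- 0:(w - 1)
  bump <- ifelse(abs(x - 200) <= 50,
                 40 / 2 * (1 + cos(2 * pi * (x - 200) / 100)), 0)
  cp <- contour_pair(rep(0, w), 100 + bump)
  ref <- estimate_reference(cp)
  got <- detect_protrusions(cp, ref)
  ora <- oracle_protrusions(cp$dej_um, ref$reference_um, 1.1)
  expect_equal(nrow(got), 1)
  expect_equal(nrow(ora), 1)
  expect_equal(got$start_x, ora$start_x, tolerance = 1e-8)
  expect_equal(got$end_x, ora$end_x, tolerance = 1e-8)
  expect_equal(got$ledge_width_um, ora$ledge_width_um, tolerance = 1e-8)
  expect_equal(got$depth_um, ora$depth_um, tolerance = 1e-8)
  expect_false(got$truncated)
})

test_that("a sinusoidal DEJ produces one protrusion per period", {
  w <- 600
  k <- 4
  x <- 0:(w - 1)
  cp <- contour_pair(rep(0, w), 100 + 30 * sin(2 * pi * k * x / w))
  got <- detect_protrusions(cp)
  expect_equal(nrow(got), k)
  expect_true(all(diff(got$start_x) > 0))
})

test_that("protrusion depth equals max-minus-min over the expanded slice", {
  # V-shaped protrusion descending 50 um
  w <- 200
  x <- 0:(w - 1)
  v <- pmax(0, 50 - abs(x - 100) * 2)
  cp <- contour_pair(rep(0, w), 100 + v)
  expect_equal(protrusion_depth(cp$dej_um, 80, 120, 1.1), 50)
  # flat contour: zero depth on any interval
  expect_equal(protrusion_depth(rep(100, 50), 10, 30, 1.1), 0)
  # random contour vs brute force
  set.seed(23)
  for (rep in 1:25) {
    dej <- 100 + rnorm(120, 0, 20)
    a <- runif(1, 5, 50)
    b <- a + runif(1, 2, 40)
    margin <- sample(c(0, 5, 10, 25), 1)
    lo <- max(0, floor(a - margin / 1.1))
    hi <- min(119, ceiling(b + margin / 1.1))
    seg <- dej[(lo:hi) + 1]
    expect_equal(protrusion_depth(dej, a, b, 1.1, margin),
                 max(seg) - min(seg))
  }
})

test_that("deepening a protrusion's interior never decreases its depth", {
  # for a genuine protrusion the window minimum is pinned at the crossing
  # boundary, so pushing interior columns deeper can only raise the max
  set.seed(24)
  w <- 300
  x <- 0:(w - 1)
  bump <- ifelse(abs(x - 150) <= 50,
                 30 * (1 + cos(2 * pi * (x - 150) / 100)) / 2, 0)
  cp <- contour_pair(rep(0, w), 100 + bump)
  prot <- detect_protrusions(cp)
  expect_equal(nrow(prot), 1)
  d0 <- protrusion_depth(cp$dej_um, prot$start_x, prot$end_x, 1.1)
  inner <- seq(ceiling(prot$start_x) + 2, floor(prot$end_x) - 2)
  for (col in sample(inner, 20)) {
    deeper <- cp$dej_um
    deeper[col + 1] <- deeper[col + 1] + runif(1, 0, 40)
    expect_gte(protrusion_depth(deeper, prot$start_x, prot$end_x, 1.1),
               d0 - 1e-12)
  }
})

test_that("undulation index matches analytic and brute-force values", {
  # 45 degree descent: each step equals the pitch
  p <- 1.1
  w <- 50
  cp <- contour_pair(rep(0, w), 100 + (0:(w - 1)) * p,
                     lateral_pitch_um = p)
  expect_equal(undulation_index(cp)$undulation_index, sqrt(2),
               tolerance = 1e-12)
  # sampled sinusoid vs loop-accumulated arc length
  x <- 0:299
  dej <- 150 + 25 * sin(2 * pi * x / 75)
  cp2 <- contour_pair(rep(0, 300), dej, lateral_pitch_um = p)
  expect_equal(undulation_index(cp2)$undulation_index,
               oracle_undulation(dej, p), tolerance = 1e-12)
})

test_that("undulation index is >= 1 and strictly grows under perturbation", {
  set.seed(25)
  for (rep in 1:20) {
    w <- sample(20:100, 1)
    dej <- 100 + rnorm(w, 0, 10)
    cp <- contour_pair(rep(0, w), dej)
    expect_gte(undulation_index(cp)$undulation_index, 1)
  }
  flat <- contour_pair(rep(0, 60), rep(100, 60))
  bumped <- flat
  bumped$dej_um[30] <- bumped$dej_um[30] + 0.5
  expect_gt(undulation_index(bumped)$undulation_index,
            undulation_index(flat)$undulation_index)
})

test_that("geometry is equivariant under joint pitch and depth scaling", {
  set.seed(26)
  w <- 250
  x <- 0:(w - 1)
  bump <- ifelse(abs(x - 120) <= 45,
                 35 * (1 + cos(2 * pi * (x - 120) / 90)) / 2, 0)
  dej <- 100 + bump + rnorm(w, 0, 1)
  fac <- 2.7
  cp1 <- contour_pair(rep(0, w), dej, lateral_pitch_um = 1.1)
  cp2 <- contour_pair(rep(0, w), dej * fac, lateral_pitch_um = 1.1 * fac)
  p1 <- detect_protrusions(cp1, min_depth_um = 5, margin_um = 10)
  p2 <- detect_protrusions(cp2, min_depth_um = 5 * fac,
                           margin_um = 10 * fac)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p2$ledge_width_um, p1$ledge_width_um * fac,
               tolerance = 1e-9)
  expect_equal(p2$depth_um, p1$depth_um * fac, tolerance = 1e-9)
  expect_equal(undulation_index(cp2)$undulation_index,
               undulation_index(cp1)$undulation_index, tolerance = 1e-12)
})

test_that("detected intervals are exactly the columns below the estimator", {
  set.seed(27)
  for (rep in 1:30) {
    w <- sample(60:150, 1)
    cp <- random_rough_pair(w, id = sprintf("r%02d", rep))
    ref <- estimate_reference(cp)
    # negligible floor: pure interval/column comparison
    got <- detect_protrusions(cp, ref, min_depth_um = 1e-9)
    runs <- oracle_above_runs(cp$dej_um, ref$reference_um)
    expect_equal(nrow(got), length(runs))
    for (i in seq_along(runs)) {
      first <- runs[[i]][1]
      last <- runs[[i]][length(runs[[i]])]
      if (first > 0) {
        expect_gte(got$start_x[i], first - 1)
        expect_lt(got$start_x[i], first)
      } else {
        expect_equal(got$start_x[i], 0)
        expect_true(got$truncated[i])
      }
      if (last < w - 1) {
        expect_gt(got$end_x[i], last)
        expect_lte(got$end_x[i], last + 1)
      } else {
        expect_equal(got$end_x[i], w - 1)
        expect_true(got$truncated[i])
      }
    }
  }
})

test_that("two disjoint bumps report count two and the deeper depth", {
  w <- 500
  x <- 0:(w - 1)
  b1 <- ifelse(abs(x - 120) <= 40, 30 * (1 + cos(2 * pi * (x - 120) / 80)) / 2, 0)
  b2 <- ifelse(abs(x - 350) <= 40, 60 * (1 + cos(2 * pi * (x - 350) / 80)) / 2, 0)
  cp <- contour_pair(rep(0, w), 100 + b1 + b2)
  m <- compute_image_metrics(cp)
  expect_equal(m$n_protrusions, 2L)
  ref <- estimate_reference(cp)
  ora <- oracle_protrusions(cp$dej_um, ref$reference_um, 1.1)
  expect_equal(m$max_depth_um, max(ora$depth_um), tolerance = 1e-8)
  expect_equal(m$protrusions[[1]]$depth_um, ora$depth_um, tolerance = 1e-8)
})

test_that("edge-truncated protrusions are kept and flagged, or droppable", {
  w <- 200
  x <- 0:(w - 1)
  # downgrowth running off the right edge
  ramp <- pmax(0, (x - 150) * 1.5)
  cp <- contour_pair(rep(0, w), 100 + ramp)
  got <- detect_protrusions(cp)
  expect_true(any(got$truncated))
  none <- detect_protrusions(cp, keep_truncated = FALSE)
  expect_false(any(none$truncated))
})
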