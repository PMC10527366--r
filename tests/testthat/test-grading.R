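test_that("the per-image rule maps protrusion geometry to PRO grades", {
  rules <- grading_rules()
  # no protrusions detected -> PRO I
  g0 <- classify_images(make_metrics(numeric(), numeric()), rules)
  expect_equal(as.character(g0$pro_grade), "PRO I")
  # shallow wide bud -> PRO II
  g1 <- classify_images(make_metrics(25, 80), rules)
  expect_equal(as.character(g1$pro_grade), "PRO II")
  # deep narrow spike -> PRO III (both criteria trip)
  g2 <- classify_images(make_metrics(80, 30), rules)
  expect_equal(as.character(g2$pro_grade), "PRO III")
  # aspect alone trips PRO III even below the absolute depth threshold
  g3 <- classify_images(make_metrics(30, 50), rules)
  expect_equal(as.character(g3$pro_grade), "PRO III")
})

test_that("classification is monotone in protrusion depth", {
  rules <- grading_rules()
  width <- 90
  last <- 1L
  for (depth in seq(6, 120, by = 2)) {
    g <- as.integer(
      classify_images(make_metrics(depth, width), rules)$pro_grade)
    expect_gte(g, last)
    last <- g
  }
})

test_that("average aggregation rounds the ordinal mean half-up", {
  expect_equal(as.character(aggregate_average(pro_grade(c(2, 2, 2)))),
               "PRO II")
  expect_equal(as.character(aggregate_average(pro_grade(rep(c(1, 3), c(10, 4))))),
               "PRO II")   # mean 1.571
  expect_equal(as.character(aggregate_average(pro_grade(c(1, 2)))),
               "PRO II")   # half-up at 1.5
  expect_equal(as.character(aggregate_average(pro_grade(c(2, 3)))),
               "PRO III")  # half-up at 2.5
  expect_error(aggregate_average(pro_grade(integer())), "non-empty")
})

test_that("the robust maximum needs at least the stated share of images", {
  expect_equal(as.character(aggregate_max10(pro_grade(rep(c(3, 2), c(9, 91))))),
               "PRO II")   # 9% < 10%
  expect_equal(as.character(aggregate_max10(pro_grade(rep(c(3, 1), c(10, 90))))),
               "PRO III")  # exactly 10% qualifies
  expect_equal(as.character(aggregate_max10(pro_grade(rep(1, 100)))),
               "PRO I")
  expect_error(aggregate_max10(pro_grade(integer())), "non-empty")
})

test_that("the robust maximum never returns a grade absent from the input", {
  set.seed(31)
  for (rep in 1:50) {
    g <- pro_grade(sample(1:3, sample(1:40, 1), replace = TRUE,
                          prob = runif(3)))
    out <- aggregate_max10(g)
    expect_true(out %in% g)
  }
})

test_that("removing top-grade images below the share lowers the maximum", {
  grades <- pro_grade(rep(c(3, 2), c(10, 90)))
  expect_equal(as.character(aggregate_max10(grades)), "PRO III")
  fewer <- pro_grade(rep(c(3, 2), c(9, 91)))
  expect_equal(as.character(aggregate_max10(fewer)), "PRO II")
})

test_that("lesions are scored by composing grading and both aggregations", {
  rules <- grading_rules()
  flat <- purrr::map(1:3, function(i) {
    compute_image_metrics(
      contour_pair(rep(0, 60), rep(100, 60),
                   image_id = sprintf("f%d", i)), rules)
  }) |> dplyr::bind_rows() |> dplyr::mutate(lesion_id = "L1")
  sc <- score_lesions(flat, rules)
  expect_equal(as.character(sc$average_grade), "PRO I")
  expect_equal(as.character(sc$max10_grade), "PRO I")
  expect_equal(sc$mean_n_protrusions, 0)
  expect_equal(sc$n_images, 3L)

  # 80% PRO II phantoms, 20% PRO III phantoms: max10 = III, average = II
  b <- c(
    purrr::map(1:8, ~ generate_phantom(
      phantom_spec("PRO II", seed = 300 + .x),
      image_id = sprintf("ii%d", .x))$contours),
    purrr::map(1:2, ~ generate_phantom(
      phantom_spec("PRO III", seed = 400 + .x),
      image_id = sprintf("iii%d", .x))$contours)
  ) |> dplyr::bind_rows()
  mx <- compute_image_metrics(b, rules) |> dplyr::mutate(lesion_id = "L2")
  sc2 <- score_lesions(mx, rules)
  expect_equal(as.character(sc2$max10_grade), "PRO III")
  expect_equal(as.character(sc2$average_grade), "PRO II")

  # single-image lesion: both aggregates equal the image grade
  one <- classify_images(make_metrics(80, 30), rules) |>
    dplyr::mutate(lesion_id = "L3")
  sc3 <- score_lesions(one, rules)
  expect_equal(sc3$average_grade, sc3$max10_grade)
  expect_equal(as.character(sc3$average_grade), "PRO III")
})

test_that("the continuous protrusion score is zero-anchored and linear", {
  flat <- make_metrics(numeric(), numeric(), ui = 1)
  expect_equal(continuous_protrusion_score(flat)$cps_experimental, 0)

  m1 <- tibble::tibble(image_id = "a", undulation_index = 1.2,
                       n_protrusions = 2L, max_depth_um = 50,
                       mean_epidermal_thickness_um = 100,
                       protrusions = list(tibble::tibble()))
  m2 <- dplyr::mutate(m1, undulation_index = 1.4, n_protrusions = 4L,
                      max_depth_um = 100)
  s1 <- continuous_protrusion_score(m1)$cps_experimental
  s2 <- continuous_protrusion_score(m2)$cps_experimental
  expect_equal(s2, 2 * s1)
})

test_that("the continuous protrusion score is monotone in each component", {
  base <- tibble::tibble(image_id = "a", undulation_index = 1.3,
                         n_protrusions = 3L, max_depth_um = 60,
                         mean_epidermal_thickness_um = 100,
                         protrusions = list(tibble::tibble()))
  s0 <- continuous_protrusion_score(base)$cps_experimental
  for (col in c("undulation_index", "n_protrusions", "max_depth_um")) {
    for (step in c(0.5, 1, 5)) {
      up <- base
      up[[col]] <- up[[col]] + step
      expect_gte(continuous_protrusion_score(up)$cps_experimental, s0)
    }
  }
})
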