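test_that("contingency tables count paired grades, invariant to order", {
  pairs <- table_to_pairs(table1a_counts())
  tab <- grade_table(pairs$visual, pairs$automated)
  expect_equal(unclass(tab), table1a_counts(), ignore_attr = TRUE)
  set.seed(41)
  perm <- sample(length(pairs$visual))
  tab2 <- grade_table(pairs$visual[perm], pairs$automated[perm])
  expect_identical(unclass(tab), unclass(tab2))
  expect_error(grade_table(integer(), integer()), "empty")
  expect_error(grade_table(c(1, 2), 1), "equal length")
})

test_that("agreement statistics decompose the table mass", {
  s <- agreement_stats(table1a_counts())
  expect_equal(s$agreement, 57 / 80)
  expect_equal(s$over_rate, 7 / 80)
  expect_equal(s$under_rate, 16 / 80)
  expect_equal(s$recall_pro1, 14 / 21)
  expect_equal(s$recall_pro2, 38 / 48)
  expect_equal(s$recall_pro3, 5 / 11)
  expect_equal(s$agreement + s$over_rate + s$under_rate, 1)

  ident <- agreement_stats(diag(3) * 10)
  expect_equal(ident$agreement, 1)
  expect_equal(ident$over_rate, 0)
  expect_equal(ident$under_rate, 0)

  sb <- agreement_stats(table1b_counts())
  expect_equal(sb$agreement, 43 / 80)
})

test_that("a grade absent from the visual margin flags recall undefined", {
  m <- rbind(c(5, 1, 0), c(2, 6, 0), c(0, 0, 0))
  s <- agreement_stats(m)
  expect_true(is.na(s$recall_pro3))
  expect_false(is.na(s$recall_pro1))
})

test_that("linear-weighted kappa reproduces the published tables", {
  ka <- weighted_kappa(table1a_counts())
  expect_equal(round(ka$kappa, 2), 0.51)
  expect_equal(ka$po, 68.5 / 80)
  expect_lt(ka$p.value, 0.001)
  kb <- weighted_kappa(table1b_counts())
  expect_equal(kb$kappa, (61 / 80 - 54.5 / 80) / (1 - 54.5 / 80),
               tolerance = 1e-12)
  expect_equal(round(kb$kappa, 3), 0.255)
})

test_that("kappa hits its analytic anchors", {
  expect_equal(weighted_kappa(diag(3) * 7)$kappa, 1)
  # independence table: outer product of margins gives exactly 0
  m <- outer(c(20, 50, 30), c(10, 60, 30)) / 10
  expect_equal(weighted_kappa(m)$kappa, 0, tolerance = 1e-12)
  expect_error(weighted_kappa(rbind(c(10, 0, 0), c(5, 0, 0), c(1, 0, 0))),
               "undefined")
})

test_that("kappa agrees with the complement-weight oracle on random tables", {
  set.seed(42)
  for (rep in 1:30) {
    m <- matrix(rpois(9, 8) + 1, 3, 3)
    expect_equal(weighted_kappa(m)$kappa, oracle_linear_kappa(m),
                 tolerance = 1e-12)
  }
})

test_that("linear weights on two categories reduce to unweighted kappa", {
  set.seed(43)
  for (rep in 1:20) {
    m2 <- matrix(rpois(4, 10) + 1, 2, 2)
    n <- sum(m2)
    p <- m2 / n
    po <- sum(diag(p))
    pe <- sum(rowSums(p) * colSums(p))
    plain <- (po - pe) / (1 - pe)
    expect_equal(weighted_kappa(m2, weighting = "linear")$kappa, plain,
                 tolerance = 1e-10)
    # the identity survives embedding in the grade space with an
    # empty third category
    m3 <- rbind(cbind(m2, 0), 0)
    expect_equal(weighted_kappa(m3, weighting = "linear")$kappa, plain,
                 tolerance = 1e-10)
  }
})

test_that("kappa is invariant under full ordinal reversal", {
  set.seed(44)
  for (rep in 1:10) {
    m <- matrix(rpois(9, 6) + 1, 3, 3)
    rev_m <- m[3:1, 3:1]
    expect_equal(weighted_kappa(rev_m)$kappa, weighted_kappa(m)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("kappa lies inside its confidence interval, both methods", {
  ka <- weighted_kappa(table1a_counts())
  expect_true(ka$conf.low <= ka$kappa && ka$kappa <= ka$conf.high)
  kb <- weighted_kappa(table1a_counts(), ci_method = "bootstrap",
                       n_boot = 500, seed = 1)
  expect_true(kb$conf.low <= kb$kappa && kb$kappa <= kb$conf.high)
})

test_that("bootstrap and asymptotic intervals overlap on a large cohort", {
  cohort <- generate_cohort(cohort_spec(n_lesions = 5000,
                                        allocation = "multinomial",
                                        seed = 45))
  tab <- grade_table(cohort$expert_grade, cohort$ai_grade)
  asym <- weighted_kappa(tab)
  boot <- weighted_kappa(tab, ci_method = "bootstrap", n_boot = 400,
                         seed = 46)
  expect_lt(max(asym$conf.low, boot$conf.low),
            min(asym$conf.high, boot$conf.high))
})

test_that("spearman correlation matches a rank-then-pearson oracle", {
  expect_equal(spearman_with_ci(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_with_ci(1:10, rev(1:10))$rho, -1)
  set.seed(47)
  for (rep in 1:15) {
    n <- sample(8:60, 1)
    x <- sample(1:3, n, replace = TRUE)   # tie-heavy, like grades
    y <- rnorm(n)
    r1 <- rank(x)
    r2 <- rank(y)
    oracle <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
      sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
    got <- spearman_with_ci(x, y)
    expect_equal(got$rho, oracle, tolerance = 1e-12)
    expect_true(got$conf.low <= got$rho && got$rho <= got$conf.high)
    # Fisher-z interval recomputed directly
    z <- atanh(oracle)
    half <- qnorm(0.975) * sqrt(1.06 / (n - 3))
    expect_equal(got$conf.low, tanh(z - half), tolerance = 1e-12)
  }
  expect_error(spearman_with_ci(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_with_ci(1:3, 1:3), "at least 4")
})

test_that("welch tests compare adjacent grades with degenerate handling", {
  set.seed(48)
  vals <- c(rnorm(20, 0), rnorm(20, 0.2), rnorm(20, 10))
  grades <- rep(1:3, each = 20)
  out <- group_difference_test(vals, grades)
  expect_equal(out$comparison, c("PRO I vs PRO II", "PRO II vs PRO III"))
  expect_lt(out$p.value[2], 1e-6)
  # cross-check against stats::t.test directly
  tt <- t.test(vals[21:40], vals[1:20])
  expect_equal(out$p.value[1], tt$p.value)
  expect_equal(out$statistic[1], unname(tt$statistic))

  # identical constant groups: no evidence of difference, flagged
  cons <- group_difference_test(rep(5, 30), rep(1:3, each = 10))
  expect_equal(cons$p.value, c(1, 1))
  expect_true(all(cons$flagged))

  # groups separated by ~10 pooled SDs at n = 20
  far <- group_difference_test(
    c(rnorm(20, 0, 1), rnorm(20, 10, 1), rnorm(20, 20, 1)),
    rep(1:3, each = 20))
  expect_true(all(far$p.value < 1e-6))
})
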