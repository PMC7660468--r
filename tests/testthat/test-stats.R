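# Group summaries, Kruskal-Wallis with Dunn post hocs, and ICC.

test_that("median [Q1, Q3] summaries use interpolated quartiles", {
  df <- tibble::tibble(v = c(1, 2, 3, 4, 5), g = "a")
  s <- summarize_groups(df, v, g)
  expect_equal(c(s$median, s$q1, s$q3), c(3, 2, 4))
  s1 <- summarize_groups(tibble::tibble(v = 7.3, g = "a"), v, g)
  expect_equal(c(s1$median, s1$q1, s1$q3), c(7.3, 7.3, 7.3))
  two <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  s2 <- summarize_groups(two, v, g)
  expect_equal(s2$median[1], s2$median[2])
  expect_equal(s2$n, c(3, 3))
})

test_that("identical groups give H = 0 and p = 1", {
  df <- tibble::tibble(v = rep(5, 9), ph = rep(c("a", "b", "c"), 3))
  cmp <- compare_phases(df, v, ph)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$posthoc_run)
  expect_error(compare_phases(df[1:3, ], v, ph), ">= 2")
})

test_that("omnibus H matches a hand rank-sum computation", {
  # small 3-group case, distinct values: H from first principles
  v <- c(1.2, 3.4, 2.2, 9.1, 7.7, 8.4, 4.5, 5.2, 6.1)
  g <- rep(c("a", "b", "c"), each = 3)
  rk <- rank(v)
  N <- 9
  Ri <- tapply(rk, g, sum)
  H_hand <- 12 / (N * (N + 1)) * sum(Ri^2 / 3) - 3 * (N + 1)
  cmp <- compare_phases(tibble::tibble(v = v, ph = g), v, ph)
  expect_equal(cmp$statistic, H_hand, tolerance = 1e-12)
  expect_equal(cmp$df, 2)
  # adjusted p values are capped at 1
  expect_true(all(cmp$pairwise$p_adj <= 1))
  expect_equal(cmp$pairwise$p_adj,
               pmin(1, cmp$pairwise$p_raw * 3))
})

test_that("rank-based comparison is invariant under monotone transforms", {
  withr::local_seed(31)
  df <- tibble::tibble(v = c(stats::rnorm(7, 27.7, 6), stats::rnorm(9, 45.2, 6),
                             stats::rnorm(6, 20.7, 6)),
                       ph = rep(c("early", "late", "dia"), c(7, 9, 6)))
  a <- compare_phases(df, v, ph)
  df2 <- dplyr::mutate(df, v = exp(v / 10))
  b <- compare_phases(df2, v, ph)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$pairwise$z, b$pairwise$z, tolerance = 1e-12)
  # tidy/glance accessors
  expect_named(tidy(a), c("group1", "group2", "z", "p.value",
                          "adj.p.value", "significant"))
  expect_equal(glance(a)$statistic, a$statistic)
})

test_that("Dunn z matches the pooled-rank formula on a tied example", {
  v <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 4)
  cmp <- compare_phases(tibble::tibble(v = v, ph = g), v, ph, alpha = 1)
  rk <- rank(v); N <- length(v)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / 4 + 1 / 4))
  z_ab <- (mean(rk[g == "a"]) - mean(rk[g == "b"])) / se
  expect_equal(cmp$pairwise$z[cmp$pairwise$group1 == "a" &
                                cmp$pairwise$group2 == "b"], z_ab)
})

test_that("synthetic sheetlet-angle phase contrast is detected reliably", {
  withr::local_seed(32)
  rejections <- replicate(200, {
    df <- tibble::tibble(
      v = c(stats::rnorm(7, 27.7, 6), stats::rnorm(9, 45.2, 6),
            stats::rnorm(6, 20.7, 6)),
      ph = rep(c("early", "late", "dia"), c(7, 9, 6)))
    compare_phases(df, v, ph)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.8)
})

test_that("ICC(2,1) is exact for perfect agreement and near zero under the null", {
  ratings <- matrix(rep(stats::rnorm(10, 50, 10), 4), ncol = 4)
  r <- icc(ratings)
  expect_equal(r$estimate, 1, tolerance = 1e-9)
  expect_lte(r$estimate, 1)
  withr::local_seed(33)
  noise <- matrix(stats::rnorm(200), ncol = 4)
  r0 <- icc(noise)
  expect_lt(abs(r0$estimate), 0.1)
  expect_true(r0$conf_low <= r0$estimate && r0$estimate <= r0$conf_high)
})

test_that("a systematic rater offset lowers absolute-agreement ICC", {
  withr::local_seed(34)
  truth <- stats::rnorm(30, 80, 15)
  ratings <- cbind(truth + stats::rnorm(30, 0, 2),
                   truth + stats::rnorm(30, 0, 2),
                   truth + 12 + stats::rnorm(30, 0, 2),   # offset rater
                   truth + 12 + stats::rnorm(30, 0, 2))
  r_abs <- icc(ratings)
  # consistency ICC(3,1) computed from the same mean squares
  ms <- r_abs$ms
  k <- 4
  icc_consistency <- (ms["MSR"] - ms["MSE"]) / (ms["MSR"] + (k - 1) * ms["MSE"])
  expect_lt(r_abs$estimate, unname(icc_consistency))
})

test_that("ICC designs select the intended observation subsets", {
  withr::local_seed(35)
  truth <- stats::rnorm(20, 80, 15)
  # observer 2 is noisier
  ratings <- cbind(truth + stats::rnorm(20, 0, 1), truth + stats::rnorm(20, 0, 1),
                   truth + stats::rnorm(20, 0, 12), truth + stats::rnorm(20, 0, 12))
  i1 <- icc(ratings, design = "intra", observer = 1)
  i2 <- icc(ratings, design = "intra", observer = 2)
  expect_gt(i1$estimate, i2$estimate)
  expect_equal(icc(ratings, design = "inter")$n_observations, 2)
  # missing cells are dropped with a warning; tiny designs error
  ratings[3, 2] <- NA
  expect_warning(icc(ratings), "dropped")
  expect_error(icc(ratings[1:2, ]), "at least 3")
  flat <- matrix(5, 10, 4)
  expect_warning(rf <- icc(flat), "undefined")
  expect_true(is.na(rf$estimate))
  expect_equal(tidy(i1)$design, "intra")
})
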