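test_that("FSS scoring: constant responses and the weighted-mean case", {
  all7 <- score_fss(rep(7L, 13))
  expect_equal(all7$fluency, 7); expect_equal(all7$absorption, 7)
  expect_equal(all7$importance, 7); expect_equal(all7$flow, 7)
  all1 <- score_fss(rep(1L, 13))
  expect_equal(unlist(all1[c("fluency", "absorption", "importance", "flow")]),
               c(fluency = 1, absorption = 1, importance = 1, flow = 1))
  mixed <- score_fss(c(rep(4L, 6), rep(6L, 4), rep(2L, 3)))
  expect_equal(mixed$flow, (6 * 4 + 4 * 6) / 10)  # 4.8
})

test_that("FSS validation rejects malformed responses and mappings", {
  expect_error(score_fss(rep(4L, 12)), "13 items")
  expect_error(score_fss(c(rep(4L, 12), 8L)), "1..7")
  expect_error(score_fss(c(rep(4L, 12), 0L)), "1..7")
  expect_error(fss_mapping(fluency = 1:5, absorption = 6:10,
                           importance = 11:13), "6 \\+ 4 \\+ 3")
  expect_error(fss_mapping(fluency = 1:6, absorption = c(7:9, 11),
                           importance = c(10, 12, 13)), "items 1..10")
})

test_that("flow equals the 6/4-weighted mean of fluency and absorption", {
  withr::with_seed(2, items <- simulate_fss_responses(40, 4.5))
  for (i in 1:40) {
    sc <- score_fss(items[i, ])
    expect_equal(sc$flow, (6 * sc$fluency + 4 * sc$absorption) / 10,
                 tolerance = 1e-12)
  }
  # and for the trial's printed group means
  expect_equal(round((6 * 4.03 + 4 * 4.96) / 10, 1), 4.4)
  expect_equal(round((6 * 4.52 + 4 * 5.6) / 10, 2), 4.95)
})

test_that("pooled t from summaries reproduces the trial's statistics", {
  ctrl <- group_summary(26, 4.4, 0.89)
  intv <- group_summary(22, 4.95, 0.85)
  res <- t_from_summary(ctrl, intv)
  expect_equal(res$df, 46)
  expect_equal(res$statistic, -2.177, tolerance = 1e-3)
  abs_res <- t_from_summary(group_summary(26, 4.96, 0.83),
                            group_summary(22, 5.6, 0.87))
  expect_equal(round(abs_res$statistic, 2), -2.6)
  evac <- t_from_summary(group_summary(26, 1.58, 1.94),
                         group_summary(22, 0.64, 0.95))
  expect_equal(round(evac$statistic, 2), 2.07)
  same <- t_from_summary(ctrl, ctrl)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_sided, 1)
})

test_that("Welch and pooled forms coincide for equal n and equal variance", {
  a <- group_summary(20, 5, 1.2)
  b <- group_summary(20, 4.5, 1.2)
  p <- t_from_summary(a, b, pooled = TRUE)
  w <- t_from_summary(a, b, pooled = FALSE)
  expect_equal(p$statistic, w$statistic, tolerance = 1e-12)
  expect_equal(p$df, w$df, tolerance = 1e-9)
})

test_that("t from raw data equals t from the samples' own summaries", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      x <- rnorm(sample(5:40, 1), mean = 5, sd = runif(1, 0.5, 2))
      y <- rnorm(sample(5:40, 1), mean = 5.5, sd = runif(1, 0.5, 2))
      for (pooled in c(TRUE, FALSE)) {
        raw <- t_from_raw(x, y, pooled)
        summ <- t_from_summary(group_summary(length(x), mean(x), sd(x)),
                               group_summary(length(y), mean(y), sd(y)),
                               pooled)
        expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
        expect_equal(raw$df, summ$df, tolerance = 1e-12)
        expect_equal(raw$p_two_sided, summ$p_two_sided, tolerance = 1e-12)
      }
    }
  })
  xy <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(t_from_raw(xy, xy)$statistic, 0)
  expect_error(t_from_raw(1, c(1, 2)), ">= 2")
})

test_that("Cohen's d from the trial summaries and degenerate cases", {
  d_flow <- cohens_d_from_summary(group_summary(26, 4.4, 0.89),
                                  group_summary(22, 4.95, 0.85))
  expect_equal(round(d_flow, 2), 0.63)
  d_abs <- cohens_d_from_summary(group_summary(26, 4.96, 0.83),
                                 group_summary(22, 5.6, 0.87))
  expect_equal(round(d_abs, 2), 0.75)
  expect_equal(cohens_d_from_summary(group_summary(10, 5, 1),
                                     group_summary(10, 5, 1)), 0)
  expect_error(cohens_d_from_summary(group_summary(10, 5, 0),
                                     group_summary(10, 6, 0)), "zero pooled")
})

test_that("Mann-Whitney: separation, symmetry, and exact small-sample p", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 16 / 2)  # n^2 / 2 for identical samples
  expect_equal(same$p_two_sided, 1, tolerance = 1e-9)

  withr::with_seed(77, {
    for (rep in 1:30) {
      n <- sample(2:5, 1); m <- sample(2:5, 1)
      x <- sample(1:6, n, replace = TRUE)  # ties likely
      y <- sample(1:6, m, replace = TRUE)
      got <- mann_whitney(x, y)
      oracle <- enum_mw_oracle(x, y)
      expect_equal(got$statistic, oracle$U)
      expect_equal(got$p_two_sided, oracle$p, tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney large-sample path matches wilcox.test without ties", {
  withr::with_seed(5, {
    x <- rnorm(20); y <- rnorm(25, 0.5)
  })
  got <- mann_whitney(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-9)
})

test_that("two-means sample size: planning inputs give 20 (normal) / 21 (t)", {
  res <- sample_size_two_means(0.05, 0.90, 4, 5.05, 1)
  expect_equal(res$n_normal_approx, 20L)
  expect_equal(res$n_per_group, 21L)
  # minimality of the noncentral-t answer
  expect_lt(stats::power.t.test(n = res$n_per_group - 1, delta = 1.05, sd = 1,
                                sig.level = 0.05)$power, 0.90)
  expect_gte(stats::power.t.test(n = res$n_per_group, delta = 1.05, sd = 1,
                                 sig.level = 0.05)$power, 0.90)
})

test_that("sample size scales as the formula dictates", {
  base <- sample_size_two_means(0.05, 0.90, 4, 5.05, 1)
  doubled <- sample_size_two_means(0.05, 0.90, 4, 5.05, 2)
  raw_n <- function(sd) 2 * (qnorm(0.975) + qnorm(0.90))^2 * sd^2 / 1.05^2
  expect_equal(doubled$n_normal_approx, ceiling(raw_n(2)))
  expect_equal(raw_n(2) / raw_n(1), 4)  # quadruples before rounding
  half_power <- sample_size_two_means(0.05, 0.5, 0, 1, 1)
  expect_equal(half_power$n_normal_approx, 8L)
  expect_error(sample_size_two_means(0, 0.9, 4, 5, 1), "alpha")
  expect_error(sample_size_two_means(0.05, 0.9, 4, 4, 1), "differ")
  expect_error(sample_size_two_means(0.05, 0.9, 4, 5, 0), "sd")
})

test_that("analysis-plan gate: t test for normal data, Mann-Whitney otherwise", {
  withr::with_seed(19, {
    xn <- rnorm(30, 5, 1); yn <- rnorm(28, 5.5, 1)
    xs <- rexp(30)^3; ys <- rexp(28)^3  # heavily skewed
  })
  tt <- compare_groups(xn, yn)
  expect_match(tt$method, "t test")
  expect_false(is.null(tt$effect_size))
  mw <- compare_groups(xs, ys)
  expect_match(mw$method, "Mann-Whitney")
})

test_that("synthetic FSS responses live on the 1..7 integer scale", {
  withr::with_seed(3, items <- simulate_fss_responses(100, 5.0))
  expect_equal(dim(items), c(100L, 13L))
  expect_true(all(items %in% 1:7))
  # arm-level means track the latent mean
  flows <- apply(items, 1, function(r) score_fss(r)$flow)
  expect_equal(mean(flows), 5.0, tolerance = 0.25)
})

test_that("the full printed-summary reproduction table is internally consistent", {
  tab <- reproduce_trial_table()
  expect_equal(nrow(tab), 7L)
  expect_true(all(tab$df == 46))
  expect_equal(sum(!is.na(tab$cohens_d)), 4L)
  expect_equal(tab$abs_t, abs(tab$t))
})
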