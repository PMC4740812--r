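test_that("DM is zero for degenerate and exactly inverse mean-CV data", {
  flat <- tibble::tibble(mean = rep(10, 60), cv = rep(0.5, 60))
  expect_true(all(compute_dm(flat)$dm == 0))

  set.seed(51)
  m <- rlnorm(500, log(1000), 1)
  inv <- tibble::tibble(mean = m, cv = 30 / sqrt(m))
  dm <- compute_dm(inv)$dm
  # running median of a monotone log-CV sequence is the centre value
  expect_true(all(abs(dm) < 1e-12))
})

test_that("DM is invariant to rescaling all means and decorrelates noise from abundance", {
  cfg <- synth_config(n_genes = 2000)
  truth <- gen_promoters(cfg, seed = 61)
  nt <- gen_noise_table(cfg, truth, seed = 62)
  d1 <- compute_dm(nt)
  d2 <- compute_dm(dplyr::mutate(nt, mean = mean * 7.3))
  expect_equal(d1$dm, d2$dm, tolerance = 1e-12)

  expect_lt(abs(mean(d1$dm)), 0.02)
  expect_lt(abs(cor(d1$dm, d1$mean, method = "spearman")), 0.08)
  expect_lt(cor(log10(d1$cv), log10(d1$mean), method = "spearman"), -0.5)
})

test_that("DM input contracts: window floor and positive records", {
  small <- tibble::tibble(mean = rlnorm(10), cv = rlnorm(10))
  expect_error(compute_dm(small), "window")
  withbad <- tibble::tibble(mean = c(rlnorm(60), -1),
                            cv = c(rlnorm(60), 0.5))
  expect_warning(out <- compute_dm(withbad), "excluded")
  expect_equal(nrow(out), 60)
})

test_that("rank-sum test matches hand values and the permutation oracle", {
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.99)

  sep <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_value, 0.1)
  expect_equal(sep$statistic, 0)

  set.seed(71)
  for (i in 1:20) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    x <- sample(100, m); y <- sample(100, n) + 0.5  # no cross-sample ties
    got <- rank_sum_test(x, y)
    expect_equal(got$p_value, perm_ranksum_p(x, y), tolerance = 1e-12)
  }

  # large shifted samples: approximate branch, clearly significant
  set.seed(72)
  big <- rank_sum_test(rnorm(200), rnorm(200, 1))
  expect_lt(big$p_value, 0.01)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  set.seed(81)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("chi-square goodness-of-fit matches the direct formula", {
  eq <- chisq_enrichment(c(5, 5), c(5, 5))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  skew <- chisq_enrichment(c(10, 0), c(5, 5))
  expect_equal(skew$statistic, 10)
  expect_equal(skew$df, 1L)
  # cross-check against the standard implementation when totals agree
  ref <- suppressWarnings(stats::chisq.test(c(10, 0), p = c(0.5, 0.5)))
  expect_equal(skew$statistic, unname(ref$statistic))
  expect_equal(skew$p_value, ref$p.value)

  expect_error(chisq_enrichment(5, 5), "two categories")
  expect_error(chisq_enrichment(c(1, 2), c(0, 3)), "positive")
})

test_that("box-plot summaries use interpolated quartiles and flag (not drop) outliers", {
  s <- boxplot_summary(1:7)
  expect_equal(s$median, 4)
  expect_equal(s$q1, 2.5)
  expect_equal(s$q3, 5.5)
  expect_equal(s$n_outliers, 0L)

  const <- boxplot_summary(rep(3, 5))
  expect_equal(const$iqr, 0)
  expect_equal(const$n_outliers, 0L)

  spike <- boxplot_summary(c(1, 1, 1, 100))
  expect_equal(spike$outliers[[1]], 100)
  expect_equal(spike$n, 4L)  # outlier flagged, never removed
})
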