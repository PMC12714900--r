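test_that("percent difference matches its definition and edge cases", {
  expect_equal(percent_difference(7.4, 7.4), 0)
  expect_equal(percent_difference(0, 6.3), -100)
  expect_equal(percent_difference(4.9, 7.4), 100 * (4.9 - 7.4) / 7.4)
  expect_error(percent_difference(1, 0), "undefined")
})

test_that("IQR filter reproduces hand computations and is idempotent", {
  f <- iqr_filter(c(1, 2, 3, 4, 5))
  expect_equal(f$removed, numeric(0))
  f2 <- iqr_filter(c(1, 2, 3, 4, 100), k = 1.5)
  expect_equal(f2$removed, 100)  # Q1=2, Q3=4, upper fence 7
  expect_equal(sort(f2$kept), c(1, 2, 3, 4))
  expect_equal(iqr_filter(c(1, 2, 3, 4, 100), k = Inf)$removed,
               numeric(0))
  # idempotence and order-invariance on a fixture
  set.seed(5)
  v <- c(rnorm(30), 40, -35)
  once <- iqr_filter(v)$kept
  twice <- iqr_filter(once)$kept
  expect_equal(sort(twice), sort(once))
  expect_equal(sort(iqr_filter(rev(v))$kept), sort(once))
  expect_warning(iqr_filter(c(1, 2, 3)), "identity")
})

test_that("curve alignment finds the first downward crossing", {
  s <- data.frame(t = 0:40, log10_P = 7 - 0.1 * (0:40))
  ac <- align_curve(s, reference = 5.6)
  expect_equal(attr(ac, "shift"), -14)
  expect_equal(approx(ac$t_shifted, ac$log10_P, 0)$y, 5.6)
  # already at the reference at t = 0
  s0 <- data.frame(t = 0:10, log10_P = 5.6 - 0.1 * (0:10))
  expect_equal(attr(align_curve(s0, 5.6), "shift"), 0)
  flat <- data.frame(t = 0:10, log10_P = rep(4, 11))
  expect_error(align_curve(flat, 5.6, label = "flat"), "flat")
})

test_that("window slope recovers -g/ln(10) on a pure exponential", {
  g <- 3.7  # d^-1
  t <- seq(0, 2, 0.02)
  s <- data.frame(t = t, log10_P = log10(1e7 * exp(-g * t)))
  ac <- align_curve(s, 5.6)
  ws <- window_slope(ac, 4.5, 6.5)
  expect_equal(ws$slope, -g / log(10), tolerance = 1e-10)
  expect_equal(ws$r_squared, 1, tolerance = 1e-10)
  # flat curve never enters the window from above
  flat <- data.frame(t_shifted = 0:10, log10_P = rep(7, 11))
  expect_error(window_slope(flat, 4.5, 6.5), "window")
})

test_that("Welch test matches the textbook formula oracle", {
  a <- c(2.1, 2.5, 1.9, 2.8, 2.2)
  b <- c(3.4, 3.1, 3.9, 2.9)
  got <- welch_t_test(a, b)
  orc <- welch_oracle(a, b)
  expect_equal(got$t, orc$t, tolerance = 1e-10)
  expect_equal(got$df, orc$df, tolerance = 1e-10)
  expect_equal(got$p, orc$p, tolerance = 1e-10)
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  far <- welch_t_test(c(1, 2, 3), c(101, 102, 103))
  expect_lt(far$p, 1e-3)
})

test_that("rank-sum test matches exact enumeration for small samples", {
  a <- 1:6
  b <- 7:12
  got <- rank_sum_test(a, b)
  expect_equal(got$p, 2 / choose(12, 6), tolerance = 1e-12)
  expect_equal(got$p, rank_sum_exact_oracle(a, b), tolerance = 1e-12)
  # a random untied fixture
  set.seed(8)
  x <- sample(seq(0, 1, 1e-4), 6)
  y <- sample(seq(2, 3, 1e-4), 5)
  expect_equal(rank_sum_test(x, y)$p, rank_sum_exact_oracle(x, y),
               tolerance = 1e-12)
  # Bonferroni doubles p for two comparisons, capped at 1
  expect_equal(rank_sum_test(a, b, n_comparisons = 2)$p_adjusted,
               2 * got$p)
  near <- rank_sum_test(c(1, 3, 5), c(2, 4, 6), n_comparisons = 3)
  expect_lte(near$p_adjusted, 1)
  ident <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(ident$p, 0.99)
})

test_that("Kruskal-Wallis agrees with its formula oracle and rank-sum direction", {
  gs <- list(c(1.2, 3.4, 2.2, 4.1, 2.8), c(5.5, 6.1, 4.9, 7.2, 6.6),
             c(9.1, 8.7, 10.2, 9.9, 8.8))
  got <- kruskal_wallis(gs)
  orc <- kruskal_oracle(gs)
  expect_equal(got$H, orc$H, tolerance = 1e-10)
  expect_equal(got$p, orc$p, tolerance = 1e-10)
  expect_lt(got$p, 0.01)
  # degenerate identical values: H = 0 by documented convention
  same <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  # two groups: consistent direction with the rank-sum test
  kw2 <- kruskal_wallis(gs[1:2])
  rs2 <- rank_sum_test(gs[[1]], gs[[2]])
  expect_equal(kw2$p < 0.05, rs2$p < 0.05)
})

test_that("abundance binning uses half-open bins in descending order", {
  rec <- data.frame(mean_log10_P = c(5.1, 5.4, 5.6))
  b <- bin_by_abundance(rec, 0.5)
  expect_equal(as.character(b$bin), c("[5,5.5)", "[5,5.5)", "[5.5,6)"))
  expect_equal(levels(b$bin), c("[5.5,6)", "[5,5.5)"))
  # boundary value falls in the upper bin (half-open convention)
  edge <- bin_by_abundance(data.frame(mean_log10_P = 5.5), 0.5)
  expect_equal(as.character(edge$bin), "[5.5,6)")
  one <- bin_by_abundance(rec, Inf)
  expect_equal(length(unique(one$bin)), 1L)
})

test_that("group summaries return mean, SE and n per group", {
  df <- data.frame(value = c(0.48, 0.31, 0.03, 0.05),
                   method = c("dln", "dln", "flb", "flb"))
  s <- summarize_rates(df, "value", "method")
  expect_equal(s$mean[s$method == "dln"], 0.395)
  expect_equal(s$mean[s$method == "flb"], 0.04)
  expect_equal(s$n, c(2L, 2L))
  expect_equal(s$se[1], sd(c(0.48, 0.31)) / sqrt(2))
  single <- summarize_rates(data.frame(value = 2, g = "a"), "value", "g")
  expect_equal(single$se, 0)
  expect_equal(single$n, 1L)
})

test_that("field report compares methods per depth with adjustment", {
  set.seed(9)
  rates <- expand.grid(method = c("dilution", "flb"), depth = c(25, 125),
                       experiment = 1:6)
  rates$value <- ifelse(rates$method == "dilution",
                        rnorm(nrow(rates), 0.4, 0.05),
                        rnorm(nrow(rates), 0.04, 0.01))
  rep <- field_report(rates)
  expect_equal(nrow(rep$summary), 4L)
  expect_equal(nrow(rep$tests), 2L)
  expect_true(all(rep$tests$p_adjusted < 0.05))
  expect_true(all(rep$tests$p_adjusted >= rep$tests$p))
  ratio <- rep$grand$grand_mean[rep$grand$method == "dilution"] /
    rep$grand$grand_mean[rep$grand$method == "flb"]
  expect_gt(ratio, 5)
  # identical rates for both methods: nothing significant
  flat <- rates; flat$value <- rep_len(seq(0.1, 0.6, length.out = 12),
                                       nrow(flat))
  rep2 <- field_report(flat)
  expect_true(all(rep2$tests$p_adjusted > 0.05))
})
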