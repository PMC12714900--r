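test_that("apparent growth and decay rates match closed forms", {
  expect_equal(apparent_growth(100, 100, 1), 0)
  expect_equal(apparent_growth(100, 200, 1), log(2))
  expect_equal(apparent_growth(1000, 500, 0.5), -2 * log(2))
  expect_equal(decay_rate(100, 100 / exp(1), 1), 1)
  expect_equal(decay_rate(100, 100, 1), 0)
  expect_equal(decay_rate(3.2e6, 1.6e6, 0.25), 4 * log(2))
  # exact antisymmetry
  n0 <- c(10, 250, 1e6); nt <- c(17, 30, 9.9e5)
  expect_identical(decay_rate(n0, nt, 0.3),
                   -apparent_growth(n0, nt, 0.3))
  expect_error(apparent_growth(0, 10, 1), "zero")
  expect_error(apparent_growth(10, 10, 0), "t must")
  # pseudo-count floor rescues zeros when explicitly enabled
  expect_equal(apparent_growth(0, 10, 1, pseudo_count = 1), log(10))
})

test_that("log-mean abundance matches the closed form and its bounds", {
  expect_equal(log_mean_abundance(1000, 1000), 1000)
  expect_equal(log_mean_abundance(100, 1000), 900 / log(10))
  expect_equal(log_mean_abundance(100, 1000),
               log_mean_abundance(1000, 100))
  set.seed(1)
  p1 <- 10^runif(1e4, 0, 8)
  p2 <- 10^runif(1e4, 0, 8)
  lm_ <- log_mean_abundance(p1, p2)
  expect_true(all(lm_ >= pmin(p1, p2) - 1e-9))
  expect_true(all(lm_ <= pmax(p1, p2) + 1e-9))
  expect_true(all(lm_ >= sqrt(p1 * p2) * (1 - 1e-12)))
  expect_true(all(lm_ <= (p1 + p2) / 2 * (1 + 1e-12)))
  expect_error(log_mean_abundance(0, 10), "abundances")
})

test_that("dilution regression recovers exact linear data to machine precision", {
  pts <- linear_dilution_points(mu = 1, m = 5)
  est <- fit_dilution(pts)
  expect_equal(est$value, 5, tolerance = 1e-12)
  expect_equal(est$mu, 1, tolerance = 1e-12)
  expect_true(est$detectable)
  # flat data: slope 0, not detectable, reported as 0
  flat <- pts; flat$k <- 0.3
  est0 <- fit_dilution(flat)
  expect_false(est0$detectable)
  expect_equal(est0$value, 0)
  expect_error(fit_dilution(data.frame(fraction_wsw = c(1, 1),
                                       k = c(0, 1))),
               "degenerate")
})

test_that("dilution regression matches the normal-equations oracle on noisy data", {
  set.seed(101)
  for (i in 1:5) {
    d <- rep(c(1, 0.8, 0.4, 0.2), each = 3)
    k <- 0.9 - 4.2 * d + rnorm(length(d), sd = 0.15)
    est <- fit_dilution(data.frame(fraction_wsw = d, k = k))
    orc <- ols_oracle(d, k)
    expect_equal(est$raw_value, -orc$slope, tolerance = 1e-8)
    expect_equal(est$se, orc$se_slope, tolerance = 1e-8)
    expect_equal(est$p, orc$p_slope, tolerance = 1e-8)
    expect_equal(est$mu, orc$intercept, tolerance = 1e-8)
  }
})

test_that("two-point estimate agrees with the full regression on linear data", {
  pts <- linear_dilution_points(mu = 1, m = 5)
  est2 <- fit_dilution_two_point(pts, fractions = c(0.2, 0.4))
  expect_equal(est2$value, 5, tolerance = 1e-12)
  expect_equal(est2$value, fit_dilution(pts)$value, tolerance = 1e-12)
  # equal means at both fractions: zero slope
  flat <- data.frame(fraction_wsw = rep(c(0.2, 0.4), each = 3),
                     k = rep(0.5, 6))
  expect_equal(fit_dilution_two_point(flat)$raw_value, 0)
  expect_error(fit_dilution_two_point(pts, fractions = c(0.3, 0.3)),
               "degenerate")
})

test_that("control correction is plain subtraction with sign preserved", {
  est <- control_corrected_flb(5.00, 1.35)
  expect_equal(est$value, 3.65)
  expect_equal(est$method, "flb")
  expect_equal(control_corrected_flb(2, 2)$raw_value, 0)
  # a negative corrected rate keeps its sign in raw_value
  neg <- control_corrected_flb(1.00, 1.35)
  expect_equal(neg$raw_value, -0.35)
})

test_that("mean control rate averages per-bottle decay rates", {
  ctl <- data.frame(bottle_id = c("c1", "c2"), role = "flb_control",
                    fraction_wsw = 1, population = "flb",
                    replicate = 1:2, t0 = 0, t1 = 1,
                    count_0 = c(1000, 1000),
                    count_t = c(1000 * exp(-1), 1000 * exp(-1.7)),
                    analyzed_volume = 1)
  expect_equal(mean_control_rate(ctl), 1.35, tolerance = 1e-12)
  unchanged <- ctl; unchanged$count_t <- unchanged$count_0
  expect_equal(mean_control_rate(unchanged), 0)
  expect_error(mean_control_rate(ctl[0, ]), "control")
})

test_that("observed mortality wraps decay rate with replicate statistics", {
  obs <- data.frame(bottle_id = paste0("o", 1:3), role = "undisturbed",
                    fraction_wsw = 1, population = "prey",
                    replicate = 1:3, t0 = 0, t1 = 0.5,
                    count_0 = c(1e5, 1.0002e5, 9.999e4),
                    count_t = c(1e4, 1.015e4, 0.985e4),
                    analyzed_volume = 0.05)
  est <- observed_mortality(obs)
  expect_equal(est$method, "observed")
  expect_equal(est$value, log(10) / 0.5, tolerance = 0.02)
  expect_true(est$detectable)
  expect_true(is.finite(est$mean_log10_P))
  # constant counts: zero rate (replicates identical -> z test on counts)
  flat <- obs; flat$count_t <- flat$count_0
  est0 <- observed_mortality(flat)
  expect_equal(est0$raw_value, 0)
})

test_that("all rates are invariant to a common count scaling", {
  pts_scale <- function(f) {
    obs <- data.frame(fraction_wsw = rep(c(1, 0.8, 0.4, 0.2), 2),
                      k = NA, replicate = rep(1:2, each = 4))
    n0 <- f * c(100, 90, 80, 70, 101, 89, 81, 69)
    nt <- f * c(60, 70, 75, 72, 59, 72, 74, 71)
    obs$k <- apparent_growth(n0, nt, 0.25)
    fit_dilution(obs)$raw_value
  }
  expect_equal(pts_scale(1), pts_scale(1000), tolerance = 1e-12)
  expect_equal(decay_rate(100, 60, 1), decay_rate(1e5, 6e4, 1),
               tolerance = 1e-12)
})

test_that("non-detect rule zeroes the value but keeps the raw estimate", {
  set.seed(3)
  # tiny slope against large noise: regression should not detect it
  d <- rep(c(1, 0.8, 0.4, 0.2), each = 3)
  k <- 0.5 - 0.01 * d + rnorm(length(d), sd = 0.4)
  est <- fit_dilution(data.frame(fraction_wsw = d, k = k))
  expect_false(est$detectable)
  expect_equal(est$value, 0)
  expect_false(est$raw_value == 0)
  expect_error(rate_estimate(value = 1, n = 3, detectable = FALSE,
                             method = "flb"),
               "non-detectable")
})
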