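test_that("grazer- and virus-free limit is exact exponential growth", {
  p <- community_params(mu_P = 0.7, c_max = 0, phi = 0)
  tr <- simulate_community(p, community_state(P = 1e5), seq(0, 2, 0.1),
                           rtol = 1e-10, atol = 1e-8)
  expect_lt(max(abs(tr$P / (1e5 * exp(0.7 * tr$t)) - 1)), 1e-6)
  tm <- true_mortality(tr, c(0, 2))
  expect_equal(tm$grazing, 0)
  expect_equal(tm$lysis, 0)
  expect_equal(tm$total, 0)
})

test_that("linear grazing regime matches the closed-form clearance rate", {
  # constant grazers, P << K_sat: prey declines at c_max * G and the
  # ledger-based grazing rate equals c_max * G
  p <- community_params(mu_P = 0, c_max = 2e-4, K_sat = 1e12,
                        Y_G = 1e-9, d_G = 0, phi = 0, mu_B_max = 0,
                        pref_B = 0)
  G0 <- 5e3
  tr <- simulate_community(p, community_state(P = 1e5, G = G0),
                           seq(0, 1, 0.05))
  cg <- p$c_max * G0
  expect_lt(max(abs(tr$P / (1e5 * exp(-cg * tr$t)) - 1)), 0.01)
  tm <- true_mortality(tr, c(0, 1))
  expect_lt(abs(tm$grazing / cg - 1), 0.01)
  expect_equal(tm$total, tm$grazing + tm$lysis)
})

test_that("all compartments stay non-negative across default scenarios", {
  for (nm in c("lab_high_grazer", "lab_low_grazer_virus", "saturated")) {
    sc <- scenario(nm)
    tr <- simulate_community(sc$params, sc$init, sc$t_grid)
    expect_true(all(as.matrix(tr[c("P", "G", "V", "I", "B", "F",
                                   "DOM")]) >= 0),
                info = nm)
  }
})

test_that("loss ledger closes the prey balance", {
  sc <- scenario("lab_high_grazer_virus")
  tr <- simulate_community(sc$params, sc$init, sc$t_grid)
  prey0 <- tr$P[1] + tr$I[1]
  prey_end <- tr$P[nrow(tr)] + tr$I[nrow(tr)]
  balance <- prey0 + tr$births[nrow(tr)] -
    tr$loss_grazing[nrow(tr)] - tr$loss_lysis[nrow(tr)]
  expect_lt(abs(balance - prey_end) / prey0, 1e-4)
  # ledger columns are cumulative, hence non-decreasing
  expect_true(all(diff(tr$loss_grazing) >= -1e-9))
  expect_true(all(diff(tr$loss_lysis) >= -1e-9))
})

test_that("dilution scales particulates, composes, and keeps DOM", {
  s <- community_state(P = 1e6, G = 1e3, V = 1e5, I = 10, B = 1e4,
                       F_ = 2e5, DOM = 7)
  expect_equal(unclass(dilute_state(s, 1))[], unclass(s)[])
  d <- dilute_state(s, 0.2)
  expect_equal(d[["P"]], 2e5)
  expect_equal(d[["DOM"]], 7)
  twice <- dilute_state(dilute_state(s, 0.5), 0.4)
  once <- dilute_state(s, 0.2)
  expect_equal(unclass(twice)[], unclass(once)[])
  expect_error(dilute_state(s, 0), "fraction")
  expect_error(dilute_state(s, 1.2), "fraction")
})

test_that("photoperiod modulation preserves the daily mean growth rate", {
  p <- community_params(mu_P = 0.5, c_max = 0, phi = 0,
                        photoperiod = c(14, 10))
  tr <- simulate_community(p, community_state(P = 1e5), seq(0, 1, 1 / 96),
                           rtol = 1e-10, atol = 1e-8)
  # over one full light:dark cycle growth integrates to mu_P * 1 d
  expect_lt(abs(tr$P[nrow(tr)] / (1e5 * exp(0.5)) - 1), 1e-3)
})

test_that("chlorophyll proxy weights phototroph compartments", {
  s <- community_state(P = 1e6, I = 1e5, B = 1e7)
  expect_equal(chlorophyll_proxy(s, c(P = 0, I = 0)), 0)
  expect_equal(chlorophyll_proxy(s, c(P = 2, I = 0)), 2e6)
  expect_equal(chlorophyll_proxy(s, c(P = 1, I = 1)), 1.1e6)
  expect_error(chlorophyll_proxy(s, c(P = -1, I = 0)), "yields")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(community_params(mu_P = -1), "non-negative")
  expect_error(community_params(K_sat = 0), "K_sat")
  expect_error(community_params(Y_G = 0), "Y_G")
  expect_error(community_params(Y_G = 1.5), "Y_G")
  expect_error(community_params(photoperiod = c(14, 11)), "photoperiod")
  expect_error(community_state(P = -5), "non-negative")
})

test_that("simulate rejects a bad time grid", {
  p <- community_params()
  s <- community_state(P = 1e5)
  expect_error(simulate_community(p, s, c(0, 0.5, 0.5)), "increasing")
  expect_error(simulate_community(p, s, 1), "increasing")
})
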