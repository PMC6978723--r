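test_that("molar yields from chemostat rates reproduce the published table", {
  rec <- chemostat_fixture_record()
  y <- yields_from_rates(rec)
  expect_equal(unname(y["acetate"]), 0.87)
  expect_equal(unname(y["lactate"]), 0.75)
  expect_equal(unname(y["co2"]), 1.04)
})

test_that("yield computation is exact at full precision and handles edge cases", {
  rec <- chemostat_record(c(galacturonate = -4, lactate = 3, acetate = 0),
                          D = 0.1)
  y <- yields_from_rates(rec, digits = NULL)
  expect_equal(unname(y["lactate"]), 0.75)
  expect_equal(unname(y["acetate"]), 0)

  # rates-from-yields then yields-from-rates is the identity
  yy <- c(lactate = 0.6180339887, acetate = 0.3141592653, co2 = 1.0101010101)
  qs <- 6.9
  rec2 <- chemostat_record(c(galacturonate = -qs, yy * qs), D = 0.13)
  expect_equal(yields_from_rates(rec2, digits = NULL), yy, tolerance = 1e-12)

  expect_error(chemostat_record(c(galacturonate = 0, lactate = 1), D = 0.1),
               "negative")
  expect_error(chemostat_record(c(galacturonate = -1, galacturonate = -1),
                                D = 0.1), "duplicated|unique")
})

test_that("biomass yield follows D / (q_s * M) with mu = D at steady state", {
  rec <- chemostat_fixture_record()
  # 0.13 / (0.0069 * 194.14) = 0.0970...; the published dry-weight-based
  # value rounds to 0.09
  expect_equal(biomass_yield(rec), 0.13 / (0.0069 * 194.14), tolerance = 1e-9)
  expect_equal(round(biomass_yield(rec), 2), 0.10)

  # constructed identity: q_s * 1e-3 * M == D gives Y = 1
  qs <- 0.13 / (1e-3 * 194.14)
  rec1 <- chemostat_record(c(galacturonate = -qs, lactate = qs), D = 0.13)
  expect_equal(biomass_yield(rec1), 1, tolerance = 1e-12)
})

test_that("carbon and electron balances close to the hand-oracle values", {
  rec <- chemostat_fixture_record()
  # hand oracle: q_x = 0.13/24.63*1000 = 5.278 mC-mol/g/h
  # C: (6.0*2 + 5.2*3 + 7.2*1 + 5.278) / (6.9*6)  = 0.968
  # e: (6.0*8 + 5.2*12 + 5.278*4.2)   / (6.9*20)  = 0.961
  qx <- 0.13 / (molar_mass("CH1.8O0.5N0.2")) * 1000
  expect_equal(carbon_balance(rec),
               (6.0 * 2 + 5.2 * 3 + 7.2 * 1 + qx) / (6.9 * 6), tolerance = 1e-9)
  expect_equal(electron_balance(rec),
               (6.0 * 8 + 5.2 * 12 + qx * 4.2) / (6.9 * 20), tolerance = 1e-9)
  expect_equal(round(carbon_balance(rec), 2), 0.97)
  expect_equal(round(electron_balance(rec), 2), 0.96)
})

test_that("recoveries are invariant to common rate rescaling and additive in products", {
  rec <- chemostat_fixture_record()
  scaled <- chemostat_record(rec$rates * 3.7, D = rec$D)
  # biomass term scales with D, so rescale that too via an explicit rate
  qx <- 0.13 / molar_mass("CH1.8O0.5N0.2") * 1000
  rec_b <- chemostat_record(c(rec$rates, biomass = qx), D = rec$D)
  scaled_b <- chemostat_record(c(rec$rates * 3.7, biomass = qx * 3.7), D = rec$D)
  expect_equal(carbon_balance(scaled_b), carbon_balance(rec_b), tolerance = 1e-12)
  expect_equal(electron_balance(scaled_b), electron_balance(rec_b), tolerance = 1e-12)

  # zeroing products leaves only the biomass term
  rec0 <- chemostat_record(c(galacturonate = -6.9, lactate = 0, acetate = 0,
                             co2 = 0), D = 0.13)
  expect_equal(carbon_balance(rec0), qx / (6.9 * 6), tolerance = 1e-9)
  # dropping the biomass term strictly lowers the recovery
  rec_nb <- chemostat_record(c(galacturonate = -6.9, acetate = 6.0,
                               lactate = 5.2, co2 = 7.2, biomass = 0), D = 0.13)
  expect_lt(electron_balance(rec_nb), electron_balance(rec))
})

test_that("batch growth-rate estimation recovers exact and noisy exponentials", {
  t <- seq(0, 10, by = 0.5)
  tc <- data.frame(time = t, od = 0.1 * exp(0.20 * t))
  est <- suppressWarnings(estimate_mu_batch(tc))   # exact fit warns in summary.lm
  expect_equal(est$mu, 0.20, tolerance = 1e-12)

  flat <- data.frame(time = t, od = rep(0.5, length(t)))
  expect_equal(suppressWarnings(estimate_mu_batch(flat))$mu, 0, tolerance = 1e-12)

  # noisy exponential: recovered within +/- 0.02 (multiplicative CV 5%)
  set.seed(42)
  ok <- vapply(1:50, function(i) {
    od <- 0.1 * exp(0.20 * t) * (1 + rnorm(length(t), 0, 0.05))
    abs(estimate_mu_batch(data.frame(time = t, od = od))$mu - 0.20) <= 0.02
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  expect_error(estimate_mu_batch(tc[1:2, ]), "3 points")
  expect_error(estimate_mu_batch(data.frame(time = t, od = -tc$od)), "non-positive")
})
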