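test_that("noise-free synthetic chemostat tables close both balances exactly", {
  cfg <- generator_config(seed = 3)
  rec <- gen_chemostat(cfg, noise_cv = 0)
  expect_equal(carbon_balance(rec), 1, tolerance = 1e-9)
  expect_equal(electron_balance(rec), 1, tolerance = 1e-9)
  # yields reflect the hybrid 1:1:1 conversion minus the biomass drain,
  # with the anabolic redox demand diverting lactate to acetate + CO2
  y <- yields_from_rates(rec, digits = NULL)
  expect_equal(unname(y["acetate"]), unname(y["co2"]), tolerance = 1e-12)
  expect_lt(y[["lactate"]], y[["acetate"]])
  expect_lt(y[["lactate"]], 1)
})

test_that("noisy chemostat tables reconcile near closure and are seeded", {
  cfg <- generator_config(seed = 9)
  a <- gen_chemostat(cfg)
  b <- gen_chemostat(cfg)
  expect_identical(a$rates, b$rates)          # same seed, same table
  expect_false(identical(a$rates, gen_chemostat(generator_config(seed = 10))$rates))
  expect_equal(carbon_balance(a), 1, tolerance = 0.1)

  # over many seeds the noise is unbiased: mean recovery within 3 SE of 1
  recov <- vapply(1:100, function(s)
    carbon_balance(gen_chemostat(generator_config(seed = s))), numeric(1))
  se <- sd(recov) / sqrt(length(recov))
  expect_lt(abs(mean(recov) - 1), 3 * se + 1e-12)
})

test_that("noise-free batch time courses conserve carbon at every time point", {
  cfg <- generator_config(seed = 4)
  tc <- gen_batch(cfg, noise_cv = 0)
  reg <- default_registry()
  Ms <- compound_field("galacturonate", "molar_mass", reg)
  cmol <- molar_mass("CH1.8O0.5N0.2")
  consumed <- (tc$substrate[1] - tc$substrate) / Ms * 6       # C-mol/L
  in_products <- tc$lactate / compound_field("lactate", "molar_mass", reg) * 3 +
    tc$acetate / compound_field("acetate", "molar_mass", reg) * 2 +
    tc$co2 / compound_field("co2", "molar_mass", reg) * 1
  in_biomass <- (tc$od - tc$od[1]) / cmol
  expect_equal(consumed, in_products + in_biomass, tolerance = 1e-6)

  # final product ratios follow the pathway's molar yields (1:1 lactate:acetate)
  nf <- nrow(tc)
  mol_lac <- tc$lactate[nf] / compound_field("lactate", "molar_mass", reg)
  mol_ace <- tc$acetate[nf] / compound_field("acetate", "molar_mass", reg)
  expect_equal(mol_lac, mol_ace, tolerance = 1e-6)
})

test_that("the Monod model approaches exponential growth at low Ks", {
  cfg <- generator_config(seed = 5, ks = 1e-4)
  tc <- gen_batch(cfg, noise_cv = 0)
  est <- estimate_mu_batch(tc, window = c(1, 15))
  expect_equal(est$mu, 0.20, tolerance = 0.002)   # < 1% of mu_max
})

test_that("noisy batch data recover the generating growth rate", {
  ok <- vapply(1:40, function(s) {
    tc <- gen_batch(generator_config(seed = 200 + s, ks = 0.05))
    abs(estimate_mu_batch(tc, window = c(2, 14))$mu - 0.20) <= 0.02
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("synthetic proteomes mirror the requested detection scenario", {
  cfg <- generator_config(seed = 6)
  pr <- gen_proteome(cfg, scenario = "canonical-lower-absent")
  can <- pathway_completeness(build_pathway("canonical_isomerase_plus_pdh"),
                              pr$map, pr$table)
  expect_setequal(can$missing, c("UxuA", "KdgK", "KdgA"))

  all_present <- gen_proteome(cfg, scenario = "all-present")
  for (v in c("canonical_isomerase", "phosphoketolase", "hybrid_isomerase_pk")) {
    rep <- pathway_completeness(build_pathway(v), all_present$map,
                                all_present$table)
    expect_equal(rep$completeness, 1.0, info = v)
  }

  # expressed pathway proteins sit above the 75th percentile of the proteome
  syn_ids <- grep("^SYN_", pr$table$protein_id, value = TRUE)
  expect_true(all(percentile_rank(pr$table, syn_ids) > 75))
})

test_that("kinetics generation is exact at zero noise and deterministic", {
  cfg <- generator_config(seed = 8)
  d0 <- gen_kinetics(cfg, noise_sd = 0)
  fit <- fit_kinetics(d0, "MM")
  expect_equal(fit$estimates$vmax, 0.24, tolerance = 1e-6)
  expect_equal(fit$estimates$km, 10, tolerance = 1e-6)
  expect_identical(gen_kinetics(cfg), gen_kinetics(cfg))
})

test_that("generator configuration is validated", {
  expect_error(generator_config(), "seed")
  expect_error(gen_chemostat(generator_config(seed = 1, yxs = 5)),
               "carbon|lactate")
})
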