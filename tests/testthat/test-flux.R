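test_that("canonical pathway net conversions match the classical accounting", {
  p <- build_pathway("canonical_isomerase")

  # upper pathway to pyruvate + GAP: invests 1 ATP and 1 NAD(P)H
  upper <- net_conversion(p, truncate_at = c("pyruvate", "gap"))
  expect_equal(upper$net_stoichiometry[["pyruvate"]], 1)
  expect_equal(upper$net_stoichiometry[["gap"]], 1)
  expect_equal(upper$atp_delta, -1)
  expect_equal(upper$nad_p_h_combined, -1)

  # run to two pyruvate: redox-neutral, net +1 ATP
  full <- net_conversion(p, truncate_at = "pyruvate")
  expect_equal(full$net_stoichiometry[["pyruvate"]], 2)
  expect_equal(full$atp_delta, 1)
  expect_equal(full$nad_p_h_combined, 0)
  expect_equal(atp_yield(p, truncate_at = "pyruvate"), 1)
})

test_that("hybrid pathway is redox-neutral to ribulose-5-P and yields 2 ATP overall", {
  h <- build_pathway("hybrid_isomerase_pk")

  upper <- net_conversion(h, truncate_at = "ribulose_5p")
  expect_equal(upper$net_stoichiometry[["ribulose_5p"]], 1)
  expect_equal(upper$net_stoichiometry[["co2"]], 1)
  expect_equal(upper$nad_p_h_combined, 0)

  full <- net_conversion(h)
  expect_equal(full$net_stoichiometry[["lactate"]], 1)
  expect_equal(full$net_stoichiometry[["acetate"]], 1)
  expect_equal(full$net_stoichiometry[["co2"]], 1)
  expect_equal(full$atp_delta, 2)
  expect_equal(full$nad_p_h_combined, 0)
  expect_equal(atp_yield(h), 2)
})

test_that("solved net conversions agree with the symbolic-summation oracle", {
  h <- build_pathway("hybrid_isomerase_pk")
  flux_h <- structure(rep(1, 15), names = names(h$reactions))
  orac <- symbolic_net(h, flux_h)
  nc <- net_conversion(h)
  for (sp in names(nc$net_stoichiometry))
    expect_equal(nc$net_stoichiometry[[sp]], unname(orac$net[sp]), info = sp)
  expect_equal(nc$atp_delta, unname(orac$cofactors[["ATP"]]))
  expect_equal(nc$nadh_delta + nc$nadph_delta,
               unname(orac$cofactors[["NADH"]] + orac$cofactors[["NADPH"]]))

  # canonical: glycolysis carries one triose, LDH carries both pyruvates
  p <- build_pathway("canonical_isomerase")
  flux_c <- structure(c(rep(1, 11), 2), names = names(p$reactions))
  orac_c <- symbolic_net(p, flux_c)
  nc_c <- net_conversion(p)
  expect_equal(nc_c$net_stoichiometry[["lactate"]], unname(orac_c$net[["lactate"]]))
  expect_equal(nc_c$atp_delta, unname(orac_c$cofactors[["ATP"]]))
})

test_that("net conversions conserve carbon and electrons", {
  reg <- default_registry()
  cases <- list(list("canonical_isomerase", NULL),
                list("canonical_isomerase", "pyruvate"),
                list("hybrid_isomerase_pk", NULL),
                list("hybrid_isomerase_pk", "ribulose_5p"),
                list("phosphoketolase", NULL))
  for (cs in cases) {
    nc <- net_conversion(build_pathway(cs[[1]]), truncate_at = cs[[2]])
    carbon <- sum(vapply(names(nc$net_stoichiometry), function(sp)
      nc$net_stoichiometry[[sp]] * compound_field(sp, "carbon", reg), numeric(1)))
    electrons <- sum(vapply(names(nc$net_stoichiometry), function(sp)
      nc$net_stoichiometry[[sp]] * compound_field(sp, "gamma", reg), numeric(1)))
    expect_lt(abs(carbon), 1e-9)
    expect_lt(abs(electrons + 2 * nc$nad_p_h_combined), 1e-9)
  }
})

test_that("net conversion scales linearly with uptake", {
  h <- build_pathway("hybrid_isomerase_pk")
  n1 <- net_conversion(h, uptake = 1)
  n2 <- net_conversion(h, uptake = 2)
  expect_equal(n2$net_stoichiometry, 2 * n1$net_stoichiometry)
  expect_equal(n2$atp_delta, 2 * n1$atp_delta)
  n0 <- net_conversion(h, uptake = 0)
  expect_equal(n0$atp_delta, 0)
})

test_that("branched variants are reported as underdetermined, not silently resolved", {
  cp <- build_pathway("canonical_isomerase_plus_pdh")
  expect_error(net_conversion(cp), "underdetermined.*PDH")
})

test_that("cofactor summary flags transhydrogenase-dependent redox neutrality", {
  h_matched <- net_conversion(build_pathway("hybrid_isomerase_pk",
                                            uxuB_cofactor = "NADPH"))
  s <- cofactor_summary(h_matched, transhydrogenase = FALSE)
  expect_equal(s$NADH, 0)
  expect_equal(s$NADPH, 0)
  expect_false(s$cofactor_imbalance)

  h_crossed <- net_conversion(build_pathway("hybrid_isomerase_pk",
                                            uxuB_cofactor = "NADH"))
  s2 <- cofactor_summary(h_crossed, transhydrogenase = FALSE)
  expect_equal(s2$`NAD(P)H`, 0)
  expect_true(s2$cofactor_imbalance)

  s3 <- cofactor_summary(h_crossed, transhydrogenase = TRUE)
  expect_equal(s3$`NAD(P)H`, h_crossed$nadh_delta + h_crossed$nadph_delta)
})

test_that("product-profile feasibility discriminates the pathway variants", {
  targets <- c(lactate = 1, acetate = 1)

  hy <- product_profile_feasible(build_pathway("hybrid_isomerase_pk"),
                                 targets, tolerance = 0.01)
  expect_true(hy$feasible)
  expect_equal(unname(hy$yields["lactate"]), 1)

  ca <- product_profile_feasible(build_pathway("canonical_isomerase"),
                                 targets, tolerance = 0.01)
  expect_false(ca$feasible)
  expect_match(paste(ca$violated, collapse = " "), "acetate")

  # with the PDH/PTA/AckA branch the pyruvate split can be pinned 1:1,
  # and that split is also redox-balanced
  cp <- product_profile_feasible(build_pathway("canonical_isomerase_plus_pdh"),
                                 targets, tolerance = 0.01,
                                 require_redox_neutral = TRUE)
  expect_true(cp$feasible)
  expect_equal(unname(cp$flux_vector[["nLDH"]]), 1, tolerance = 1e-6)
  expect_equal(unname(cp$flux_vector[["PDH"]]), 1, tolerance = 1e-6)

  expect_error(product_profile_feasible(build_pathway("hybrid_isomerase_pk"),
                                        targets, tolerance = -1),
               "non-negative")
})

test_that("feasibility windows reject unreachable splits on branched variants", {
  cp <- build_pathway("canonical_isomerase_plus_pdh")
  # all-acetate from the canonical+PDH route would strand 2 NADH + PDH NADH
  res <- product_profile_feasible(cp, c(lactate = 0, acetate = 2),
                                  tolerance = 0.01,
                                  require_redox_neutral = TRUE)
  expect_false(res$feasible)
})
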