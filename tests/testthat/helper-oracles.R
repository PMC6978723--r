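# Shared fixtures and independent oracles for the test suite.

# Independent symbolic-summation oracle: net stoichiometry and cofactor
# deltas of a pathway obtained by direct weighted summation of the reaction
# equations with a hand-specified flux vector (no linear algebra).
symbolic_net <- function(p, flux) {
  net <- numeric(0)
  cof <- c(ATP = 0, NADH = 0, NADPH = 0)
  for (id in names(flux)) {
    r <- p$reactions[[id]]
    for (sp in names(r$stoichiometry)) {
      cur <- if (sp %in% names(net)) net[[sp]] else 0
      net[sp] <- cur + flux[[id]] * r$stoichiometry[[sp]]
    }
    cof <- cof + flux[[id]] * r$cofactors
  }
  list(net = net[abs(net) > 1e-12], cofactors = cof)
}

chemostat_fixture_record <- function() {
  chemostat_record(c(galacturonate = -6.9, acetate = 6.0,
                     lactate = 5.2, co2 = 7.2), D = 0.13)
}

proteome_fixture <- function() {
  read_proteome_table(system.file("extdata", "proteome_detections.tsv",
                                  package = "galufer"))
}

canonical_core <- c("UxaC", "UxuE", "UxuB", "UxuA", "KdgK", "KdgA")

# gamma of one unit of reaction flux, computed directly from the registry
# (independent of check_reaction_balance)
reaction_gamma_sum <- function(r, registry = default_registry()) {
  g <- sum(vapply(names(r$stoichiometry), function(sp)
    r$stoichiometry[[sp]] * compound_field(sp, "gamma", registry), numeric(1)))
  g + 2 * (r$cofactors[["NADH"]] + r$cofactors[["NADPH"]])
}
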