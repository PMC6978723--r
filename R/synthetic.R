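# Seeded synthetic-data generators emulating the study's measurement types:
# chemostat rate tables, batch time courses, proteome tables and enzyme
# kinetics curves. Every generator is a pure function of its configuration
# (Mersenne-Twister RNG seeded per call), and noise-free outputs satisfy the
# conservation invariants of the downstream modules exactly.

#' Generator configuration
#'
#' Defaults reproduce the study conditions: hybrid pathway, dilution rate
#' 0.13 1/h, biomass yield 0.09 g/g, batch mu_max 0.20 1/h on 3.3 g/L
#' substrate, rate noise CV 0.02 (the ~1-3 percent mean deviations typical of
#' replicate chemostat rate measurements), gluconate-kinase kinetics truth
#' Vmax 0.24, Km 10 mM.
#'
#' @param seed Integer seed; mandatory for any stochastic output.
#' @param variant Pathway variant used for true product stoichiometry.
#' @param yxs True biomass yield, g biomass (g substrate)^-1.
#' @param D Dilution rate, 1/h.
#' @param rate_cv Coefficient of variation of multiplicative Gaussian noise
#'   on chemostat rates.
#' @param mu_max Batch maximum specific growth rate, 1/h.
#' @param ks Monod constant, mM.
#' @param s0 Initial substrate, g/L. @param x0 Initial biomass, g/L.
#' @param od_cv CV of multiplicative noise on batch measurements.
#' @param n_background Number of background proteins in synthetic proteomes.
#' @param count_meanlog,count_sdlog Log-normal parameters of background
#'   spectral counts.
#' @param kin_model,kin_vmax,kin_km,kin_ki,kin_sd,kin_grid Kinetics truth:
#'   model, parameters, additive noise SD, and substrate grid (mM).
#' @return List of class \code{generator_config}.
#' @export
generator_config <- function(seed,
                             variant = "hybrid_isomerase_pk",
                             yxs = 0.09,
                             D = 0.13,
                             rate_cv = 0.02,
                             mu_max = 0.20,
                             ks = 0.5,
                             s0 = 3.3,
                             x0 = 0.01,
                             od_cv = 0.05,
                             n_background = 800,
                             count_meanlog = log(20),
                             count_sdlog = 1,
                             kin_model = "MM",
                             kin_vmax = 0.24,
                             kin_km = 10,
                             kin_ki = 25,
                             kin_sd = 0.012,
                             kin_grid = c(1, 2, 5, 7, 10, 15, 20, 30, 40, 50,
                                          75, 100)) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer seed is mandatory", call. = FALSE)
  structure(as.list(environment()), class = "generator_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Generate a synthetic chemostat rate table
#'
#' True rates are constructed so that, noise-free, both the carbon and the
#' electron balance close exactly: the substrate uptake follows from D and
#' the true biomass yield, biomass carbon is drained at the dilution rate,
#' and the redox requirement of biomass formation (biomass is more reduced
#' per C-mol than galacturonate) is met by diverting a small carbon-neutral
#' amount of lactate to acetate + CO2. Multiplicative Gaussian noise at
#' \code{rate_cv} is then applied per rate.
#'
#' @param cfg A \code{generator_config}.
#' @param noise_cv Override for \code{cfg$rate_cv} (0 gives exact tables).
#' @return A \code{chemostat_record}; the noise-free rates are attached as
#'   attribute \code{"true_rates"}.
#' @export
gen_chemostat <- function(cfg, noise_cv = cfg$rate_cv) {
  p <- build_pathway(cfg$variant)
  nc <- net_conversion(p)
  if (abs(nc$nad_p_h_combined) > 1e-9)
    stop("generator requires a redox-cofactor-neutral pathway variant", call. = FALSE)
  y <- nc$net_stoichiometry
  prods <- y[names(y) != p$substrate & y > 0]
  if (!all(c("lactate", "acetate", "co2") %in% names(prods)))
    stop("generator requires a lactate/acetate/CO2-producing variant", call. = FALSE)

  reg <- default_registry()
  Ms <- compound_field(p$substrate, "molar_mass", reg)
  Cs <- compound_field(p$substrate, "carbon", reg)
  gs <- compound_field(p$substrate, "gamma", reg)
  f_x <- parse_formula("CH1.8O0.5N0.2")
  cmol_mass <- molar_mass(f_x)
  gamma_x <- degree_of_reduction(f_x)

  u <- cfg$D / (cfg$yxs * 1e-3 * Ms)          # |q_s|, mmol/g/h
  qx <- cfg$D / cmol_mass * 1000              # mC-mol/g/h
  if (qx >= u * Cs)
    stop("biomass carbon drain exceeds substrate carbon uptake; lower yxs", call. = FALSE)
  s <- u - qx / Cs                            # substrate catabolized
  # carbon-neutral redox shift: -delta lactate, +delta acetate, +delta co2
  # frees 4 electrons per mol, covering the biomass electron surplus
  delta <- (gamma_x - gs / Cs) * qx / 4
  rates <- c(-u, prods["lactate"] * s - delta,
             prods["acetate"] * s + delta,
             prods["co2"] * s + delta)
  names(rates) <- c(p$substrate, "lactate", "acetate", "co2")
  if (any(rates[-1] < 0))
    stop("redox shift exceeds lactate production; configuration inconsistent",
         call. = FALSE)
  true_rates <- rates
  if (noise_cv > 0)
    rates <- with_seed(cfg$seed,
                       rates * (1 + stats::rnorm(length(rates), 0, noise_cv)))
  rec <- chemostat_record(rates, D = cfg$D, substrate_id = p$substrate)
  attr(rec, "true_rates") <- true_rates
  attr(rec, "seed") <- cfg$seed
  rec
}

#' Generate a synthetic batch time course
#'
#' Integrates Monod growth dX/dt = mu(S) X, mu(S) = mu_max S/(Ks+S),
#' dS/dt = -mu X / Yxs, with catabolic products formed at the pathway's molar
#' yields from the substrate not drawn into biomass carbon. Noise-free output
#' conserves carbon at every time point. Multiplicative noise at
#' \code{od_cv} is applied to OD and concentrations.
#'
#' @param cfg A \code{generator_config}.
#' @param times Output time grid, h.
#' @param noise_cv Override for \code{cfg$od_cv} (0 gives exact curves).
#' @return Data frame with columns \code{time}, \code{od} (biomass g/L) and
#'   product/substrate concentrations (g/L); noise-free values attached as
#'   attribute \code{"truth"}.
#' @export
gen_batch <- function(cfg, times = seq(0, 30, by = 0.5), noise_cv = cfg$od_cv) {
  p <- build_pathway(cfg$variant)
  nc <- net_conversion(p)
  y <- nc$net_stoichiometry
  prods <- y[names(y) != p$substrate & y > 0]
  reg <- default_registry()
  Ms <- compound_field(p$substrate, "molar_mass", reg)
  Cs <- compound_field(p$substrate, "carbon", reg)
  Mi <- compound_field(names(prods), "molar_mass", reg)
  cmol_mass <- molar_mass(parse_formula("CH1.8O0.5N0.2"))
  # fraction of consumed substrate carbon fixed into biomass
  f_ana <- cfg$yxs * Ms / (cmol_mass * Cs)

  deriv <- function(t, state, parms) {
    S <- max(state[["S"]], 0)
    s_mM <- S / Ms * 1000
    mu <- cfg$mu_max * s_mM / (cfg$ks + s_mM)
    if (S <= 0) mu <- 0
    dX <- mu * state[["X"]]
    dS <- -dX / cfg$yxs
    r_cat <- -dS / Ms * (1 - f_ana)     # mol/L/h of substrate catabolized
    dP <- prods * r_cat * Mi            # g/L/h per product
    list(c(dX, dS, dP))
  }
  state0 <- c(X = cfg$x0, S = cfg$s0, structure(rep(0, length(prods)),
                                                names = names(prods)))
  sol <- deSolve::ode(y = state0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  sol <- as.data.frame(sol)
  sol$S <- pmax(sol$S, 0)
  truth <- data.frame(time = sol$time, od = sol$X,
                      substrate = sol$S,
                      sol[names(prods)], check.names = FALSE)
  out <- truth
  if (noise_cv > 0) {
    out[-1] <- with_seed(cfg$seed, {
      lapply(out[-1], function(v)
        pmax(v * (1 + stats::rnorm(length(v), 0, noise_cv)), 0))
    })
  }
  attr(out, "truth") <- truth
  attr(out, "seed") <- cfg$seed
  out
}

#' Generate a synthetic proteome table with its evidence map
#'
#' Background proteins receive log-normal spectral counts. Proteins of
#' pathway reactions marked present are drawn from above the 75th percentile
#' of the background distribution (expressed pathways sit high in the
#' abundance distribution); reactions marked absent contribute no row at all.
#'
#' @param cfg A \code{generator_config}.
#' @param scenario \code{"canonical-lower-absent"} (the mannonate dehydratase,
#'   KDG kinase and KDPG aldolase proteins are missing, everything else
#'   present) or \code{"all-present"}.
#' @param variants Pathway variants whose reactions are given evidence
#'   entries.
#' @return List with \code{table} (a \code{proteome_table}) and \code{map}
#'   (evidence-map data frame usable by \code{\link{pathway_completeness}}).
#' @export
gen_proteome <- function(cfg, scenario = c("canonical-lower-absent", "all-present"),
                         variants = c("canonical_isomerase_plus_pdh",
                                      "hybrid_isomerase_pk", "phosphoketolase")) {
  scenario <- match.arg(scenario)
  keys <- unique(unlist(lapply(variants, function(v) {
    p <- build_pathway(v)
    vapply(p$reactions, `[[`, character(1), "evidence_key")
  })))
  candidate_keys <- c("mannonate_kinase", "pmannonate_epimerase")
  absent_keys <- if (scenario == "canonical-lower-absent")
    c("uxuA", "kdgK", "kdgA") else character(0)

  with_seed(cfg$seed, {
    bg_counts <- stats::rlnorm(cfg$n_background, cfg$count_meanlog, cfg$count_sdlog)
    q75 <- stats::quantile(bg_counts, 0.75)
    rows <- data.frame(protein_id = sprintf("BG%04d", seq_along(bg_counts)),
                       count = bg_counts, stringsAsFactors = FALSE)
    map <- data.frame(evidence_key = keys,
                      tier = ifelse(keys %in% candidate_keys, "candidate",
                                    "confirmed"),
                      stringsAsFactors = FALSE)
    map$proteins <- lapply(keys, function(k) paste0("SYN_", k))
    present_keys <- setdiff(keys, absent_keys)
    pw_counts <- q75 * (1.2 + stats::rlnorm(length(present_keys), 0, 0.5))
    rows <- rbind(rows, data.frame(protein_id = paste0("SYN_", present_keys),
                                   count = pw_counts, stringsAsFactors = FALSE))
    list(table = proteome_table(rows$protein_id, rows$count),
         map = map, seed = cfg$seed, scenario = scenario)
  })
}

#' Generate a synthetic enzyme-kinetics dataset
#'
#' Rates from \code{\link{model_rate}} on the configured substrate grid plus
#' additive Gaussian noise.
#'
#' @param cfg A \code{generator_config}.
#' @param noise_sd Override for \code{cfg$kin_sd} (0 gives exact rates).
#' @return Data frame with columns \code{S} and \code{rate}; generating
#'   parameters attached as attribute \code{"truth"}.
#' @export
gen_kinetics <- function(cfg, noise_sd = cfg$kin_sd) {
  truth <- list(model = cfg$kin_model, vmax = cfg$kin_vmax, km = cfg$kin_km,
                ki = cfg$kin_ki)
  v <- model_rate(cfg$kin_grid, truth)
  if (noise_sd > 0)
    v <- with_seed(cfg$seed, v + stats::rnorm(length(v), 0, noise_sd))
  out <- data.frame(S = cfg$kin_grid, rate = v)
  attr(out, "truth") <- truth
  attr(out, "seed") <- cfg$seed
  out
}
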