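# Steady-state net conversions, ATP/redox deltas and product-profile
# feasibility for pathway models.
#
# The internal-metabolite steady state S_int %*% v = 0 with unit substrate
# uptake defines a unique flux ray for the linear (tree-like) variants; it is
# solved exactly by QR. Branched variants are handled either by designating
# sink species (truncation) or by the feasibility solver, which works on the
# affine solution set and falls back to an LP for higher-dimensional branch
# spaces.

flux_system <- function(p, truncate_at = NULL) {
  external <- union(p$external_species, truncate_at)
  S <- stoichiometric_matrix(p)
  # truncation: a designated sink is external; reactions all of whose
  # substrates are sinks (i.e. that would re-consume a sink) are dropped.
  # The growth substrate is external but is the entry point, never a sink.
  sinks <- setdiff(external, p$substrate)
  keep <- vapply(p$reactions, function(r) {
    consumed <- names(r$stoichiometry)[r$stoichiometry < 0]
    !all(consumed %in% sinks)
  }, logical(1))
  S <- S[, keep, drop = FALSE]
  reactions <- p$reactions[keep]
  internal <- setdiff(rownames(S), external)
  list(S = S, reactions = reactions, internal = internal, external = external)
}

#' Net conversion of a pathway at steady state
#'
#' Solves the internal-metabolite steady state with substrate uptake fixed at
#' \code{uptake} mol and all irreversible fluxes non-negative, and returns
#' the externally visible overall stoichiometry together with the net ATP,
#' NADH and NADPH deltas.
#'
#' @param p A \code{pathway_model}.
#' @param uptake Moles of substrate consumed (default 1).
#' @param truncate_at Optional character vector of species to treat as
#'   external sinks; reactions consuming only sinks are dropped. E.g.
#'   \code{truncate_at = "pyruvate"} runs the canonical pathway to two
#'   pyruvate, \code{c("pyruvate", "gap")} stops it before lower glycolysis.
#' @return Object of class \code{net_conversion}: \code{net_stoichiometry}
#'   (named, per \code{uptake} mol substrate; substrate coefficient
#'   \code{-uptake}), \code{atp_delta}, \code{nadh_delta}, \code{nadph_delta},
#'   \code{nad_p_h_combined}, \code{flux_vector}.
#' @examples
#' net_conversion(build_pathway("hybrid_isomerase_pk"))
#' @export
net_conversion <- function(p, uptake = 1, truncate_at = NULL) {
  fs <- flux_system(p, truncate_at)
  S <- fs$S
  n <- ncol(S)
  A <- rbind(S[fs$internal, , drop = FALSE], S[p$substrate, , drop = FALSE])
  b <- c(rep(0, length(fs$internal)), -uptake)

  qa <- qr(A)
  if (qa$rank < n) {
    N <- pracma::nullspace(A)
    free <- colnames(S)[apply(abs(N) > 1e-9, 1, any)]
    stop(sprintf("underdetermined pathway: flux not pinned for reaction(s) %s",
                 paste(free, collapse = ", ")), call. = FALSE)
  }
  v <- qr.solve(A, b)
  if (max(abs(A %*% v - b)) > 1e-9 * max(1, abs(uptake)))
    stop("disconnected pathway: no steady-state flux carries the substrate to the external species",
         call. = FALSE)
  irrev <- !vapply(fs$reactions, `[[`, logical(1), "reversible")
  if (any(v[irrev] < -1e-9))
    stop(sprintf("steady state requires irreversible reaction(s) %s to run backwards",
                 paste(names(fs$reactions)[irrev & v < -1e-9], collapse = ", ")),
         call. = FALSE)
  v <- round(v, 12)

  net_all <- drop(S %*% v)
  net <- net_all[fs$external[abs(net_all[fs$external]) > 1e-9 |
                               fs$external == p$substrate]]
  cof <- drop(t(cofactor_matrix(p)[names(fs$reactions), , drop = FALSE]) %*% v)
  structure(list(pathway = p$name,
                 options = p$options,
                 uptake = uptake,
                 net_stoichiometry = round(net, 12),
                 atp_delta = round(cof[["ATP"]], 12),
                 nadh_delta = round(cof[["NADH"]], 12),
                 nadph_delta = round(cof[["NADPH"]], 12),
                 nad_p_h_combined = round(cof[["NADH"]] + cof[["NADPH"]], 12),
                 flux_vector = v),
            class = "net_conversion")
}

#' @export
print.net_conversion <- function(x, ...) {
  eq <- x$net_stoichiometry
  lhs <- eq[eq < 0]; rhs <- eq[eq > 0]
  fmt <- function(v) paste(sprintf("%g %s", abs(v), names(v)), collapse = " + ")
  cat(sprintf("<net_conversion> %s\n  %s -> %s\n", x$pathway, fmt(lhs), fmt(rhs)))
  cat(sprintf("  ATP %+g, NADH %+g, NADPH %+g, NAD(P)H %+g per %g mol substrate\n",
              x$atp_delta, x$nadh_delta, x$nadph_delta, x$nad_p_h_combined,
              x$uptake))
  invisible(x)
}

#' Net ATP yield of a pathway
#'
#' The ATP delta of the unit-uptake net conversion, in mol ATP per mol
#' substrate. For the canonical isomerase pathway truncated at pyruvate this
#' is the classical value of 1 mol ATP (mol galacturonate)^-1.
#'
#' @inheritParams net_conversion
#' @return Net mol ATP per mol substrate.
#' @examples
#' atp_yield(build_pathway("canonical_isomerase"), truncate_at = "pyruvate")
#' @export
atp_yield <- function(p, truncate_at = NULL) {
  net_conversion(p, uptake = 1, truncate_at = truncate_at)$atp_delta
}

#' Cofactor summary of a net conversion
#'
#' @param n A \code{net_conversion}.
#' @param transhydrogenase Logical; if TRUE the NADH and NADPH pools are
#'   reported as one interconvertible NAD(P)H pool. If FALSE they are
#'   reported separately and a \code{cofactor_imbalance} flag is raised when
#'   the pooled delta is zero but the separate deltas are not (a pathway that
#'   is only redox-neutral given transhydrogenase activity).
#' @return Named list with ATP, NADH, NADPH, `NAD(P)H` and
#'   \code{cofactor_imbalance}.
#' @export
cofactor_summary <- function(n, transhydrogenase = n$options$transhydrogenase) {
  pooled <- n$nad_p_h_combined
  imbalance <- !transhydrogenase && abs(pooled) < 1e-9 &&
    (abs(n$nadh_delta) > 1e-9 || abs(n$nadph_delta) > 1e-9)
  list(ATP = n$atp_delta,
       NADH = if (transhydrogenase) NA_real_ else n$nadh_delta,
       NADPH = if (transhydrogenase) NA_real_ else n$nadph_delta,
       `NAD(P)H` = pooled,
       cofactor_imbalance = imbalance)
}

# minimum-norm least-squares solution + nullspace of the equality system
affine_solution_set <- function(A, b) {
  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  tolr <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tolr)
  dinv <- c(1 / sv$d[seq_len(r)], rep(0, length(sv$d) - r))
  v0 <- sv$v[, seq_along(sv$d), drop = FALSE] %*%
    (dinv * (t(sv$u[, seq_along(sv$d), drop = FALSE]) %*% b))
  consistent <- max(abs(A %*% v0 - b)) <= 1e-9 * max(1, max(abs(b)))
  N <- if (r < ncol(A)) sv$v[, (r + 1):ncol(A), drop = FALSE] else
    matrix(0, ncol(A), 0)
  list(v0 = drop(v0), N = N, consistent = consistent)
}

#' Test whether a pathway can realize a target product profile
#'
#' Poses the linear feasibility problem: internal steady state, unit
#' substrate uptake, irreversible fluxes non-negative, each target yield
#' within \code{tolerance} of its observed value, and (optionally) net
#' NAD(P)H of zero. Solved exactly on the affine steady-state solution set
#' when its dimension is at most one (all shipped variants); otherwise by
#' phase-1 linear programming.
#'
#' @param p A \code{pathway_model}.
#' @param target_yields Named numeric vector/list of mol product per mol
#'   substrate, names being external species.
#' @param tolerance Allowed absolute deviation per yield (mol/mol); the
#'   default 0.05 operationalizes "near-equimolar".
#' @param require_redox_neutral Logical; additionally require net
#'   NAD(P)H = 0.
#' @return Object of class \code{feasibility_result}: \code{feasible},
#'   \code{flux_vector} and \code{yields} (when feasible),
#'   \code{violated} (infeasibility certificate: the unsatisfiable
#'   constraints) and \code{residual} (worst target deviation beyond
#'   tolerance).
#' @examples
#' product_profile_feasible(build_pathway("hybrid_isomerase_pk"),
#'                          c(lactate = 1, acetate = 1))
#' @export
product_profile_feasible <- function(p, target_yields, tolerance = 0.05,
                                     require_redox_neutral = FALSE) {
  if (tolerance < 0) stop("tolerance must be non-negative", call. = FALSE)
  target_yields <- unlist(target_yields)
  fs <- flux_system(p)
  S <- fs$S
  internal_bad <- intersect(names(target_yields), fs$internal)
  if (length(internal_bad))
    stop(sprintf("target species are internal to the pathway: %s",
                 paste(internal_bad, collapse = ", ")), call. = FALSE)
  # a target the network cannot even touch is a structural infeasibility
  absent <- setdiff(names(target_yields), rownames(S))
  absent <- absent[unlist(target_yields[absent]) > tolerance]
  if (length(absent))
    return(structure(list(feasible = FALSE, flux_vector = NULL, yields = NULL,
                          violated = sprintf("yield:%s unreachable (no producing reaction in %s)",
                                             absent, p$name),
                          residual = max(abs(unlist(target_yields[absent])))),
                     class = "feasibility_result"))
  target_yields <- target_yields[names(target_yields) %in% rownames(S)]

  A <- rbind(S[fs$internal, , drop = FALSE], S[p$substrate, , drop = FALSE])
  b <- c(rep(0, length(fs$internal)), -1)
  aff <- affine_solution_set(A, b)
  if (!aff$consistent) {
    return(structure(list(feasible = FALSE, flux_vector = NULL, yields = NULL,
                          violated = "steady state with unit uptake is unsatisfiable",
                          residual = NA_real_),
                     class = "feasibility_result"))
  }
  irrev <- which(!vapply(fs$reactions, `[[`, logical(1), "reversible"))
  cofm <- cofactor_matrix(p)[names(fs$reactions), , drop = FALSE]
  redox_row <- cofm[, "NADH"] + cofm[, "NADPH"]

  # linear functionals of v with feasibility windows [lo, hi]
  cons <- list()
  for (sp in names(target_yields))
    cons[[paste0("yield:", sp)]] <-
      list(a = S[sp, ], lo = target_yields[[sp]] - tolerance,
           hi = target_yields[[sp]] + tolerance)
  if (require_redox_neutral)
    cons[["redox:NAD(P)H"]] <- list(a = redox_row, lo = 0, hi = 0)
  for (i in irrev)
    cons[[paste0("irreversible:", names(fs$reactions)[i])]] <-
      list(a = as.numeric(seq_len(ncol(S)) == i), lo = 0, hi = Inf)

  k <- ncol(aff$N)
  solution <- NULL
  violated <- character(0)
  residual <- 0
  if (k == 0L) {
    v <- aff$v0
    for (nm in names(cons)) {
      val <- sum(cons[[nm]]$a * v)
      if (val < cons[[nm]]$lo - 1e-9 || val > cons[[nm]]$hi + 1e-9) {
        violated <- c(violated, nm)
        if (startsWith(nm, "yield:"))
          residual <- max(residual,
                          max(cons[[nm]]$lo - val, val - cons[[nm]]$hi))
      }
    }
    if (!length(violated)) solution <- v
  } else if (k == 1L) {
    nvec <- drop(aff$N)
    lo <- -Inf; hi <- Inf
    for (nm in names(cons)) {
      c0 <- sum(cons[[nm]]$a * aff$v0)
      c1 <- sum(cons[[nm]]$a * nvec)
      if (abs(c1) < 1e-12) {
        if (c0 < cons[[nm]]$lo - 1e-9 || c0 > cons[[nm]]$hi + 1e-9) {
          violated <- c(violated, nm)
          if (startsWith(nm, "yield:"))
            residual <- max(residual,
                            max(cons[[nm]]$lo - c0, c0 - cons[[nm]]$hi))
        }
      } else {
        w <- sort(c((cons[[nm]]$lo - c0) / c1, (cons[[nm]]$hi - c0) / c1))
        lo <- max(lo, w[1]); hi <- min(hi, w[2])
      }
    }
    if (!length(violated) && lo <= hi + 1e-9) {
      alpha <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2 else
        max(lo, min(hi, 0))
      solution <- aff$v0 + alpha * nvec
    } else if (!length(violated)) {
      violated <- "target window empty on the feasible flux interval"
      residual <- (lo - hi)
    }
  } else {
    sol <- feasibility_lp(aff, cons)
    solution <- sol$solution
    violated <- sol$violated
  }

  if (!is.null(solution)) {
    solution <- round(solution, 12)
    names(solution) <- names(fs$reactions)
    yields <- drop(S[names(target_yields), , drop = FALSE] %*% solution)
    names(yields) <- names(target_yields)
    structure(list(feasible = TRUE, flux_vector = solution,
                   yields = round(yields, 12), violated = NULL, residual = 0),
              class = "feasibility_result")
  } else {
    structure(list(feasible = FALSE, flux_vector = NULL, yields = NULL,
                   violated = violated, residual = residual),
              class = "feasibility_result")
  }
}

# phase-1 LP over the branch space alpha (dim k >= 2):
# minimize sum of artificials for window violations
feasibility_lp <- function(aff, cons) {
  k <- ncol(aff$N)
  # variables: alpha+ (k), alpha- (k), slack artificials (one per finite bound)
  Ain <- NULL; bin <- NULL; art <- 0
  rows <- list()
  for (nm in names(cons)) {
    c0 <- sum(cons[[nm]]$a * aff$v0)
    c1 <- drop(cons[[nm]]$a %*% aff$N)
    if (is.finite(cons[[nm]]$hi))
      rows[[length(rows) + 1]] <- list(a = c1, b = cons[[nm]]$hi - c0, nm = nm)
    if (is.finite(cons[[nm]]$lo))
      rows[[length(rows) + 1]] <- list(a = -c1, b = c0 - cons[[nm]]$lo, nm = nm)
  }
  m <- length(rows)
  # a.(alpha+ - alpha-) - s <= b, s >= 0; minimize sum s
  Ain <- do.call(rbind, lapply(seq_len(m), function(i) {
    c(rows[[i]]$a, -rows[[i]]$a, -as.numeric(seq_len(m) == i))
  }))
  bin <- vapply(rows, `[[`, numeric(1), "b")
  cc <- c(rep(0, 2 * k), rep(1, m))
  ans <- tryCatch(pracma::linprog(cc, A = Ain, b = bin, maxiter = 200),
                  error = function(e) NULL)
  if (is.null(ans) || is.null(ans$x))
    return(list(solution = NULL, violated = "LP solver failed"))
  s <- ans$x[(2 * k + 1):(2 * k + m)]
  if (sum(s) > 1e-7) {
    viol <- unique(vapply(rows[s > 1e-7], `[[`, character(1), "nm"))
    return(list(solution = NULL, violated = viol))
  }
  alpha <- ans$x[seq_len(k)] - ans$x[k + seq_len(k)]
  list(solution = aff$v0 + drop(aff$N %*% alpha), violated = character(0))
}

#' @export
print.feasibility_result <- function(x, ...) {
  if (x$feasible) {
    cat("<feasibility_result> feasible\n  yields:",
        paste(names(x$yields), signif(x$yields, 6), sep = "=", collapse = ", "),
        "\n")
  } else {
    cat("<feasibility_result> infeasible\n  violated:",
        paste(x$violated, collapse = "; "), "\n")
  }
  invisible(x)
}
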