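# Reaction-network encodings of the candidate galacturonate fermentation
# pathways, with explicit ATP/NADH/NADPH bookkeeping and per-reaction element
# balance verification.
#
# Conventions:
#  * Cofactor pairs (ATP/ADP, NAD+/NADH, NADP+/NADPH) are net deltas per unit
#    flux, not species. One NAD(P)H carries 2 H (and hence 2 electron
#    equivalents); one ATP carries an HPO3 phosphoryl group (0 electrons).
#  * H2O and inorganic phosphate (H3PO4) are closure species: their reaction
#    coefficients are solved from the O and P balance, never written in
#    pathway files, and excluded from steady-state constraints.

PATHWAY_VARIANTS <- c("canonical_isomerase", "canonical_isomerase_plus_pdh",
                      "hybrid_isomerase_pk", "phosphoketolase")

#' Names of the shipped pathway variants
#' @return Character vector of valid \code{build_pathway()} variant names.
#' @export
pathway_variants <- function() PATHWAY_VARIANTS

# parse "2 a + b -> c" into a signed coefficient map plus cofactor deltas
parse_equation <- function(eq, uxuB_cofactor = "NADH") {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop(sprintf("equation '%s' must contain exactly one '->'", eq), call. = FALSE)
  stoich <- numeric(0)
  cof <- c(ATP = 0, NADH = 0, NADPH = 0)
  for (side in 1:2) {
    sgn <- if (side == 1L) -1 else 1
    terms <- strsplit(sides[side], "+", fixed = TRUE)[[1]]
    for (term in terms) {
      term <- trimws(term)
      if (!nzchar(term)) stop(sprintf("empty term in equation '%s'", eq), call. = FALSE)
      parts <- strsplit(term, "[[:space:]]+")[[1]]
      coef <- 1
      name <- parts[1]
      if (length(parts) == 2L) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop(sprintf("bad coefficient in term '%s'", term), call. = FALSE)
        name <- parts[2]
      } else if (length(parts) > 2L) {
        stop(sprintf("cannot parse term '%s'", term), call. = FALSE)
      }
      if (name == "NAD(P)H") name <- uxuB_cofactor
      if (name %in% names(cof)) {
        cof[name] <- cof[name] + sgn * coef
      } else {
        stoich[name] <- (if (name %in% names(stoich)) stoich[[name]] else 0) + sgn * coef
      }
    }
  }
  list(stoichiometry = stoich[stoich != 0], cofactors = cof)
}

#' Build a candidate pathway model
#'
#' Loads one of the shipped reaction-network encodings: the canonical
#' isomerase pathway (with or without the hypothetical PDH/PTA/AckA branch),
#' the phosphoketolase pathway entered at 6-phosphogluconate, or the hybrid
#' isomerase-phosphoketolase pathway joined by mannonate kinase and
#' 6-phosphomannonate 2-epimerase. Every reaction is element-balance checked
#' on load.
#'
#' @param variant One of \code{pathway_variants()}.
#' @param uxuB_cofactor Cofactor drawn by fructuronate reductase,
#'   \code{"NADH"} or \code{"NADPH"}. Defaults to NADPH for the hybrid
#'   variant (the cofactor-matched configuration with NADP+-linked
#'   6-phosphogluconate dehydrogenase) and NADH otherwise.
#' @param transhydrogenase Logical; when TRUE, downstream cofactor summaries
#'   pool NADH and NADPH as interconvertible NAD(P)H.
#' @param file Optional path to a user-defined pathway file in the documented
#'   grammar (overrides \code{variant} lookup; \code{variant} then only names
#'   the model).
#' @param registry Compound registry.
#' @return An object of class \code{pathway_model}: list with \code{name},
#'   \code{reactions}, \code{substrate}, \code{external_species},
#'   \code{internal_species}, \code{options}.
#' @examples
#' p <- build_pathway("hybrid_isomerase_pk")
#' length(p$reactions)
#' @export
build_pathway <- function(variant,
                          uxuB_cofactor = NULL,
                          transhydrogenase = FALSE,
                          file = NULL,
                          registry = default_registry()) {
  if (is.null(file)) {
    if (!is.character(variant) || length(variant) != 1L ||
        !variant %in% PATHWAY_VARIANTS)
      stop(sprintf("unknown pathway variant '%s'; valid variants: %s",
                   as.character(variant)[1],
                   paste(PATHWAY_VARIANTS, collapse = ", ")), call. = FALSE)
    file <- system.file("extdata", "pathways", paste0(variant, ".tsv"),
                        package = "galufer")
  }
  if (is.null(uxuB_cofactor))
    uxuB_cofactor <- if (identical(variant, "hybrid_isomerase_pk")) "NADPH" else "NADH"
  uxuB_cofactor <- match.arg(uxuB_cofactor, c("NADH", "NADPH"))

  # header metadata lives in '# substrate:' / '# external:' comment lines
  hdr <- readLines(file, warn = FALSE)
  sub_line <- grep("^#\\s*substrate:", hdr, value = TRUE)
  ext_line <- grep("^#\\s*external:", hdr, value = TRUE)
  if (length(sub_line) != 1L || length(ext_line) != 1L)
    stop("pathway file must declare '# substrate:' and '# external:' lines",
         call. = FALSE)
  substrate <- trimws(sub("^#\\s*substrate:", "", sub_line))
  external <- strsplit(trimws(sub("^#\\s*external:", "", ext_line)),
                       "[[:space:]]+")[[1]]

  df <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "enzyme", "ec", "equation", "reversible", "evidence")
  if (!all(need %in% names(df)))
    stop("pathway file needs columns id, enzyme, ec, equation, reversible, evidence",
         call. = FALSE)
  if (anyDuplicated(df$id))
    stop("reaction ids must be unique", call. = FALSE)

  reactions <- lapply(seq_len(nrow(df)), function(i) {
    pe <- parse_equation(df$equation[i], uxuB_cofactor = uxuB_cofactor)
    r <- list(id = df$id[i],
              enzyme = df$enzyme[i],
              ec = if (df$ec[i] %in% c("-", "")) NA_character_ else df$ec[i],
              stoichiometry = pe$stoichiometry,
              cofactors = pe$cofactors,
              reversible = as.logical(df$reversible[i]),
              evidence_key = df$evidence[i])
    class(r) <- "pathway_reaction"
    r
  })
  names(reactions) <- df$id

  p <- structure(list(name = variant,
                      reactions = reactions,
                      substrate = substrate,
                      external_species = external,
                      internal_species = NULL,
                      options = list(uxuB_cofactor = uxuB_cofactor,
                                     transhydrogenase = transhydrogenase)),
                 class = "pathway_model")

  species <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  if (!substrate %in% external)
    stop("substrate must be an external species", call. = FALSE)
  if (!all(external %in% species))
    stop("external species must appear in at least one reaction", call. = FALSE)
  p$internal_species <- setdiff(species, external)

  # validation: registered compounds, element balance, connectivity
  for (r in reactions) {
    bal <- check_reaction_balance(r, registry = registry)
    if (!bal$closed)
      stop(sprintf("reaction '%s' does not balance: %s", r$id,
                   paste(names(bal$residual), signif(bal$residual, 3),
                         sep = "=", collapse = ", ")), call. = FALSE)
  }
  S <- stoichiometric_matrix(p)
  for (sp in p$internal_species) {
    row <- S[sp, ]
    if (!any(row > 0) || !any(row < 0))
      stop(sprintf("internal species '%s' is not both produced and consumed", sp),
           call. = FALSE)
  }
  p
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("<pathway_model> %s: %d reactions, substrate %s\n",
              x$name, length(x$reactions), x$substrate))
  cat("  external:", paste(x$external_species, collapse = ", "), "\n")
  cat(sprintf("  options: uxuB_cofactor=%s, transhydrogenase=%s\n",
              x$options$uxuB_cofactor, x$options$transhydrogenase))
  invisible(x)
}

#' Check the element balance of a single reaction
#'
#' Sums the elemental content of all species (weighted by their signed
#' coefficients) plus the atoms carried by cofactor deltas (2 H per NAD(P)H,
#' HPO3 per ATP), then solves the implicit closure coefficients for H2O and
#' inorganic phosphate from the O and P rows. The reaction is closed when
#' every remaining per-element residual is below tolerance.
#'
#' @param r A \code{pathway_reaction} (element of \code{pathway_model$reactions}).
#' @param registry Compound registry.
#' @param tol Absolute per-element tolerance (default 1e-6).
#' @return A list of class \code{balance_report}: \code{residual} (named per
#'   element, after closure), \code{closed}, \code{closure} (moles of H2O and
#'   phosphate produced per unit flux).
#' @export
check_reaction_balance <- function(r, registry = default_registry(),
                                   tol = 1e-6) {
  res <- structure(numeric(length(ELEMENTS)), names = ELEMENTS)
  for (sp in names(r$stoichiometry))
    res <- res + r$stoichiometry[[sp]] * unclass(compound_formula(sp, registry))
  # atoms leaving the species pool into produced cofactors
  nadh_like <- r$cofactors[["NADH"]] + r$cofactors[["NADPH"]]
  res["H"] <- res["H"] + 2 * nadh_like
  res <- res + r$cofactors[["ATP"]] * c(C = 0, H = 1, O = 3, N = 0, P = 1, S = 0)
  # closure: a*H2O + b*H3PO4 produced; solve b from P, a from O
  b <- res[["P"]]
  a <- res[["O"]] - 4 * b
  res["P"] <- 0
  res["O"] <- 0
  res["H"] <- res[["H"]] - 2 * a - 3 * b
  closed <- max(abs(res)) <= tol
  structure(list(residual = res, closed = closed,
                 closure = c(water = -a, phosphate = -b)),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> closed=%s; residual: %s\n", x$closed,
              paste(names(x$residual), signif(x$residual, 3), sep = "=",
                    collapse = " ")))
  invisible(x)
}

#' Stoichiometric matrix of a pathway model
#'
#' @param p A \code{pathway_model}.
#' @return A species-by-reactions numeric matrix (closure species and cofactor
#'   deltas excluded); dimnames give the index maps.
#' @export
stoichiometric_matrix <- function(p) {
  species <- unique(c(p$substrate,
                      unlist(lapply(p$reactions, function(r) names(r$stoichiometry)))))
  S <- matrix(0, nrow = length(species), ncol = length(p$reactions),
              dimnames = list(species, names(p$reactions)))
  for (j in seq_along(p$reactions)) {
    st <- p$reactions[[j]]$stoichiometry
    S[names(st), j] <- as.numeric(st)
  }
  S
}

# net cofactor delta row vectors (one per cofactor) aligned with reactions
cofactor_matrix <- function(p) {
  t(vapply(p$reactions, function(r) r$cofactors, numeric(3)))
}

# gamma carried by one unit of reaction flux through its cofactor deltas
reaction_cofactor_gamma <- function(r) {
  2 * (r$cofactors[["NADH"]] + r$cofactors[["NADPH"]])
}
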