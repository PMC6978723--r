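# Elemental bookkeeping: formulas, molar masses and degrees of reduction.
# These are the primitives behind every balance check in the package.

ELEMENTS <- c("C", "H", "O", "N", "P", "S")

# CODATA standard atomic weights, g/mol
ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007,
                 P = 30.974, S = 32.06)

# Electron equivalents per atom relative to the CO2/H2O/NH3 reference state
# (Roels convention; P and S referenced to phosphate/sulfate, so gamma of
# H3PO4 and H2SO4 is 0).
GAMMA_PER_ATOM <- c(C = 4, H = 1, O = -2, N = -3, P = 5, S = 6)

#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula over C, H, O, N, P and S into a named
#' count vector. Subscripts may be real-valued, which permits per-carbon-mole
#' biomass compositions such as \code{"CH1.8O0.5N0.2"}.
#'
#' @param text A single formula string, e.g. \code{"C6H10O7"}.
#' @return A named numeric vector of class \code{elemental_formula} with one
#'   entry per element (C, H, O, N, P, S); unlisted elements are 0.
#' @examples
#' parse_formula("C6H10O7")      # galacturonic acid
#' parse_formula("CH1.8O0.5N0.2") # standard biomass composition
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", text)[[1]]
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", text))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (length(tokens) == 0L || covered != nchar(text))
    stop(sprintf("cannot parse formula '%s'", text), call. = FALSE)
  counts <- structure(numeric(length(ELEMENTS)), names = ELEMENTS)
  for (tok in tokens) {
    sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    num <- sub("^[A-Z][a-z]?", "", tok)
    if (!sym %in% ELEMENTS)
      stop(sprintf("unknown element symbol '%s' in formula '%s'", sym, text),
           call. = FALSE)
    n <- if (nzchar(num)) as.numeric(num) else 1
    counts[sym] <- counts[sym] + n
  }
  if (any(counts < 0) || all(counts == 0))
    stop("formula must have at least one positive element count", call. = FALSE)
  structure(counts, class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  parts <- character(0)
  for (el in ELEMENTS) {
    n <- unclass(x)[[el]]
    if (n == 0) next
    num <- format(n, scientific = FALSE)
    if (grepl(".", num, fixed = TRUE)) num <- sub("\\.?0+$", "", num)
    parts <- c(parts, if (n == 1) el else paste0(el, num))
  }
  paste(parts, collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", format(x), "\n")
  invisible(x)
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && all(ELEMENTS %in% names(f)))
    return(structure(as.numeric(f[ELEMENTS]), names = ELEMENTS,
                     class = "elemental_formula"))
  stop("not an elemental formula", call. = FALSE)
}

#' Molar mass of an elemental formula
#'
#' @param f An \code{elemental_formula} or formula string.
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass("C6H10O7") # 194.14 g/mol
#' @export
molar_mass <- function(f) {
  f <- as_formula(f)
  sum(unclass(f) * ATOMIC_MASS[ELEMENTS])
}

#' Degree of reduction of an elemental formula
#'
#' Electron equivalents per mole relative to the reference set CO2, H2O, NH3
#' (and phosphate/sulfate for P and S): gamma = 4C + H - 2O - 3N + 5P + 6S.
#' Glucose gives 24 (4 per C-mol); CO2, H2O and NH3 give 0. This is the
#' weighting used by the electron-balance closure of chemostat data.
#'
#' @param f An \code{elemental_formula} or formula string.
#' @return Electron equivalents per mole.
#' @examples
#' degree_of_reduction("C6H12O6")      # 24
#' degree_of_reduction("C6H10O7")      # 20, galacturonate
#' degree_of_reduction("CH1.8O0.5N0.2") # 4.2, biomass per C-mol
#' @export
degree_of_reduction <- function(f) {
  f <- as_formula(f)
  sum(unclass(f) * GAMMA_PER_ATOM[ELEMENTS])
}

#' Load a compound registry
#'
#' Reads a tab-delimited compound table (columns \code{id}, \code{name},
#' \code{formula}) and derives carbon counts, degrees of reduction and molar
#' masses. The packaged registry covers all species of the encoded
#' galacturonate pathways; users may load an extended file.
#'
#' @param path Path to a TSV file; defaults to the packaged registry.
#' @return A data frame of class \code{compound_registry} with columns
#'   \code{id}, \code{name}, \code{formula}, \code{carbon}, \code{gamma},
#'   \code{molar_mass}, plus a \code{formulas} attribute holding the parsed
#'   formula vectors.
#' @export
load_compounds <- function(path = system.file("extdata", "compounds.tsv",
                                              package = "galufer")) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "name", "formula")
  if (!all(need %in% names(df)))
    stop("compound registry needs columns id, name, formula", call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicated compound ids in registry", call. = FALSE)
  fl <- lapply(df$formula, parse_formula)
  names(fl) <- df$id
  df$carbon <- vapply(fl, function(f) unclass(f)[["C"]], numeric(1))
  df$gamma <- vapply(fl, degree_of_reduction, numeric(1))
  df$molar_mass <- round(vapply(fl, molar_mass, numeric(1)), 2)
  attr(df, "formulas") <- fl
  class(df) <- c("compound_registry", "data.frame")
  df
}

.galufer_env <- new.env(parent = emptyenv())

#' The packaged compound registry
#'
#' @return The default \code{compound_registry} (cached after first load).
#' @export
default_registry <- function() {
  if (is.null(.galufer_env$registry))
    .galufer_env$registry <- load_compounds()
  .galufer_env$registry
}

compound_formula <- function(id, registry = default_registry()) {
  fl <- attr(registry, "formulas")
  if (!id %in% names(fl))
    stop(sprintf("compound '%s' is not in the registry", id), call. = FALSE)
  fl[[id]]
}

compound_field <- function(id, field, registry = default_registry()) {
  i <- match(id, registry$id)
  if (anyNA(i))
    stop(sprintf("compound '%s' is not in the registry",
                 paste(id[is.na(i)], collapse = ", ")), call. = FALSE)
  registry[[field]][i]
}
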