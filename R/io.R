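# Readers and writers: delimited rate tables, proteome tables, evidence
# maps, chemostat config, JSON reports. Readers validate and reject rather
# than coerce; '#' comment lines are allowed everywhere; tab vs comma is
# chosen by file extension.

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                   comment.char = "#", stringsAsFactors = FALSE,
                                   strip.white = TRUE),
                 error = function(e) stop(sprintf("cannot read '%s': %s", path,
                                                  conditionMessage(e)),
                                          call. = FALSE))
  if (nrow(df) == 0L) stop(sprintf("no data rows in '%s'", path), call. = FALSE)
  df
}

RATE_UNIT_FACTORS <- c("mmol/g/h" = 1, "mmol/gx/h" = 1,
                       "mol/g/h" = 1000, "umol/g/h" = 1e-3)

#' Read a chemostat rate table
#'
#' Expects a delimited file with header columns \code{compound_id},
#' \code{rate}, \code{unit}; rates are converted to mmol (g biomass)^-1 h^-1.
#' Culture metadata (dilution rate, substrate, biomass formula) comes from a
#' sidecar YAML config, see \code{\link{read_chemostat_config}}.
#'
#' @param path Rate table path (.csv comma, .tsv tab).
#' @param config List from \code{\link{read_chemostat_config}}, or a list
#'   with \code{D}, \code{substrate_id}, \code{biomass_formula}.
#' @param registry Compound registry.
#' @return A \code{chemostat_record}.
#' @export
read_rate_table <- function(path, config, registry = default_registry()) {
  df <- read_delim_auto(path)
  need <- c("compound_id", "rate", "unit")
  if (!all(need %in% names(df)))
    stop("rate table needs header columns compound_id, rate, unit", call. = FALSE)
  if (anyDuplicated(df$compound_id))
    stop("duplicated compound row in rate table", call. = FALSE)
  if (!is.numeric(df$rate)) stop("rate column must be numeric", call. = FALSE)
  unk <- setdiff(df$unit, names(RATE_UNIT_FACTORS))
  if (length(unk))
    stop(sprintf("unknown rate unit(s): %s (supported: %s)",
                 paste(unk, collapse = ", "),
                 paste(names(RATE_UNIT_FACTORS), collapse = ", ")), call. = FALSE)
  rates <- df$rate * RATE_UNIT_FACTORS[df$unit]
  names(rates) <- df$compound_id
  chemostat_record(rates, D = config$D,
                   substrate_id = config$substrate_id,
                   biomass_formula = config$biomass_formula,
                   registry = registry)
}

#' Read a chemostat sidecar config (YAML)
#'
#' Recognized keys: \code{D} (1/h), \code{substrate_id},
#' \code{biomass_formula}. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_chemostat_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("D", "substrate_id", "biomass_formula")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (!all(c("D", "substrate_id") %in% names(cfg)))
    stop("config must define D and substrate_id", call. = FALSE)
  if (is.null(cfg$biomass_formula)) cfg$biomass_formula <- "CH1.8O0.5N0.2"
  cfg
}

#' Read a proteome detection table
#'
#' Delimited file with header \code{protein_id} and optionally \code{count}
#' (normalized spectral counts); every row is a detection.
#'
#' @param path File path (.tsv tab, .csv comma).
#' @return A \code{proteome_table}.
#' @export
read_proteome_table <- function(path) {
  df <- read_delim_auto(path)
  if (!"protein_id" %in% names(df))
    stop("proteome table needs a protein_id column", call. = FALSE)
  proteome_table(df$protein_id,
                 count = if ("count" %in% names(df)) df$count else NA_real_)
}

#' Read an evidence map
#'
#' Delimited file with header \code{evidence_key}, \code{tier}
#' ("confirmed" or "candidate") and \code{proteins} (semicolon-separated
#' protein ids; empty for unmapped reactions).
#'
#' @param path File path; defaults to the packaged map transcribing the
#'   study's gene-to-protein table.
#' @return Data frame with a \code{proteins} list column.
#' @export
read_evidence_map <- function(path = system.file("extdata", "evidence_map.tsv",
                                                 package = "galufer")) {
  df <- read_delim_auto(path)
  need <- c("evidence_key", "tier", "proteins")
  if (!all(need %in% names(df)))
    stop("evidence map needs columns evidence_key, tier, proteins", call. = FALSE)
  if (anyDuplicated(df$evidence_key))
    stop("duplicated evidence_key in map", call. = FALSE)
  if (!all(df$tier %in% c("confirmed", "candidate")))
    stop("tier must be 'confirmed' or 'candidate'", call. = FALSE)
  df$proteins <- lapply(strsplit(as.character(df$proteins), ";", fixed = TRUE),
                        function(x) trimws(x[nzchar(trimws(x)) & !is.na(x)]))
  df
}

hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Write an analysis report as JSON
#'
#' Serializes a report object (e.g. a \code{reconciliation_report},
#' \code{net_conversion} or \code{completeness_report}) with a metadata
#' block carrying the package version, a hash of the report body and
#' checksums of any input files. No timestamps are written, so identical
#' inputs produce byte-identical reports.
#'
#' @param report The object to serialize (its \code{fit} element, if any, is
#'   dropped).
#' @param path Output JSON path.
#' @param inputs Optional character vector of input file paths to checksum.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, inputs = character(0)) {
  body <- unclass(report)
  body$fit <- NULL
  meta <- list(tool = "galufer",
               version = as.character(utils::packageVersion("galufer")),
               body_hash = hash_object(body),
               input_checksums = if (length(inputs))
                 as.list(tools::md5sum(inputs)) else NULL)
  out <- list(meta = meta, report = body)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
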