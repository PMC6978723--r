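# Proteome evidence mapping: pathway completeness from protein detections
# and percentile ranks of spectral counts.

#' Construct a proteome table
#'
#' @param protein_id Character vector of unique protein identifiers.
#' @param count Optional numeric normalized spectral counts (NA allowed for
#'   detection-only tables).
#' @param detected Logical; defaults to TRUE for every listed protein (rows
#'   are detections).
#' @return Data frame of class \code{proteome_table}.
#' @export
proteome_table <- function(protein_id, count = NA_real_, detected = TRUE) {
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id)) stop("protein ids must be unique", call. = FALSE)
  df <- data.frame(protein_id = protein_id,
                   count = rep_len(as.numeric(count), length(protein_id)),
                   detected = rep_len(as.logical(detected), length(protein_id)),
                   stringsAsFactors = FALSE)
  if (any(!is.na(df$count) & df$count < 0))
    stop("spectral counts must be non-negative", call. = FALSE)
  if (any(df$detected & !is.na(df$count) & df$count == 0))
    stop("a detected protein cannot have a zero count", call. = FALSE)
  class(df) <- c("proteome_table", "data.frame")
  df
}

#' Score pathway completeness against a proteome table
#'
#' A reaction is \emph{detected} when at least one protein mapped to its
#' evidence key (any paralog) is present in the proteome table. Reactions
#' whose evidence is candidate-tier (the two novel enzymes of unresolved gene
#' identity) or unmapped are reported separately and excluded from the
#' completeness fraction.
#'
#' @param p A \code{pathway_model}.
#' @param em Evidence map from \code{\link{read_evidence_map}}: data frame
#'   with columns \code{evidence_key}, \code{tier} ("confirmed" or
#'   "candidate") and \code{proteins} (list column of protein id vectors).
#' @param pt A \code{proteome_table}.
#' @param reactions Optional character vector restricting scoring to a subset
#'   of reaction ids (e.g. the six upper isomerase-pathway reactions).
#' @return Object of class \code{completeness_report}: per-reaction
#'   \code{status} (detected / not_detected / candidate / unmapped),
#'   \code{completeness} = detected / (detected + not_detected),
#'   \code{missing} (not-detected reaction ids), \code{candidates}.
#' @export
pathway_completeness <- function(p, em, pt, reactions = NULL) {
  rxns <- p$reactions
  if (!is.null(reactions)) {
    bad <- setdiff(reactions, names(rxns))
    if (length(bad))
      stop(sprintf("unknown reaction id(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    rxns <- rxns[reactions]
  }
  present <- pt$protein_id[pt$detected]
  status <- character(length(rxns))
  names(status) <- names(rxns)
  for (id in names(rxns)) {
    key <- rxns[[id]]$evidence_key
    i <- match(key, em$evidence_key)
    if (is.na(i))
      stop(sprintf("evidence map has no entry for reaction '%s' (key '%s')",
                   id, key), call. = FALSE)
    prots <- em$proteins[[i]]
    if (identical(em$tier[i], "candidate")) {
      status[id] <- "candidate"
    } else if (length(prots) == 0L) {
      status[id] <- "unmapped"
    } else {
      status[id] <- if (any(prots %in% present)) "detected" else "not_detected"
    }
  }
  n_det <- sum(status == "detected")
  n_miss <- sum(status == "not_detected")
  structure(list(pathway = p$name,
                 status = status,
                 completeness = if (n_det + n_miss > 0) n_det / (n_det + n_miss) else NA_real_,
                 missing = names(status)[status == "not_detected"],
                 candidates = names(status)[status == "candidate"]),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("<completeness_report> %s: completeness %.2f\n",
              x$pathway, x$completeness))
  if (length(x$missing))
    cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  if (length(x$candidates))
    cat("  candidate-tier (not scored):", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

#' Percentile rank of proteins within the whole-proteome count distribution
#'
#' Percentile of a protein = 100 * (number of proteins with strictly lower
#' count + (ties - 1)/2) / n, i.e. the strictly-below fraction with mean tie
#' handling.
#'
#' @param pt A \code{proteome_table} with counts.
#' @param subset Character vector of protein ids to rank.
#' @return Named numeric vector of percentiles (0-100).
#' @export
percentile_rank <- function(pt, subset) {
  counts <- pt$count[pt$detected & !is.na(pt$count)]
  ids <- pt$protein_id[pt$detected & !is.na(pt$count)]
  miss <- setdiff(subset, ids)
  if (length(miss))
    stop(sprintf("protein(s) not in the count table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  n <- length(counts)
  out <- vapply(subset, function(id) {
    x <- counts[match(id, ids)]
    100 * (sum(counts < x) + (sum(counts == x) - 1) / 2) / n
  }, numeric(1))
  names(out) <- subset
  out
}
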