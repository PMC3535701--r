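# Machine-readable transcriptions of the published HCC venous-metastasis
# module tables (the 17-module cumulative classifier and its pathway
# enrichment), plus the accounting operations over them.

#' Load the published 17-module HCC metastasis classifier table
#'
#' Transcription of the published full list of regulatory modules predictive
#' of HCC venous metastasis: module name (\code{Regulator_Status}),
#' regulator id and semicolon-joined first-layer targets.
#'
#' @return data.frame with columns \code{name}, \code{regulator},
#'   \code{targets}.
#' @export
load_hcc_modules <- function() {
  path <- system.file("extdata", "hcc_modules.tsv", package = "comboreg",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Load the published module-pathway enrichment table
#'
#' Transcription of the published KEGG non-metabolic pathway enrichment of
#' the HCC metastasis classifier modules (unadjusted one-sided Fisher p).
#'
#' @return data.frame with columns \code{module}, \code{pathway}, \code{p}.
#' @export
load_hcc_enrichment <- function() {
  path <- system.file("extdata", "hcc_module_enrichment.tsv",
                      package = "comboreg", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Count distinct member nodes of a module table
#'
#' Size of the union of all regulators and all targets.
#'
#' @param modules_table data.frame with \code{regulator} and
#'   (semicolon-joined) \code{targets} columns.
#' @return integer count.
#' @export
count_unique_members <- function(modules_table) {
  if (!nrow(modules_table)) stop("empty module table")
  targets <- unlist(strsplit(modules_table$targets, ";", fixed = TRUE))
  length(union(modules_table$regulator, targets))
}

#' Count modules by source-network status suffix
#'
#' Parses the final underscore-separated token of each module name
#' (\code{_NM} or \code{_M}; embedded underscores as in
#' \code{hsa_miR_323_3p_M} are handled by taking the last token).
#'
#' @param modules_table data.frame with a \code{name} column.
#' @return named integer vector \code{c(NM = ..., M = ...)}.
#' @export
count_by_status <- function(modules_table) {
  suffix <- sub(".*_", "", modules_table$name)
  bad <- !(suffix %in% PHENOTYPES)
  if (any(bad)) stop("malformed module name(s): ",
                     paste(head(modules_table$name[bad], 5), collapse = ", "))
  c(NM = sum(suffix == "NM"), M = sum(suffix == "M"))
}

#' Summarize an enrichment table: distinct modules and pathways
#'
#' @param enrich_table data.frame with \code{module} and \code{pathway}
#'   columns.
#' @return named integer vector \code{c(n_modules = ..., n_pathways = ...)}.
#' @export
count_enrichment_summary <- function(enrich_table) {
  if (!nrow(enrich_table)) stop("empty enrichment table")
  c(n_modules = length(unique(enrich_table$module)),
    n_pathways = length(unique(enrich_table$pathway)))
}
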