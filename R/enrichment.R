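# One-sided Fisher exact overlap tests: network validation against curated
# gene collections and per-module gene-set (pathway) enrichment.

#' One-sided Fisher exact test of overlap between two gene sets
#'
#' Hypergeometric upper tail: with population \code{|universe|},
#' \code{|set_b|} successes and \code{|set_a|} draws, returns
#' P(X >= |intersection|). Zero overlap gives p = 1.
#'
#' @param set_a,set_b character vectors, both subsets of \code{universe}.
#' @param universe character vector of background ids.
#' @return one-sided p-value.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("set element(s) outside universe: ",
         paste(head(c(out_a, out_b), 5), collapse = ", "))
  k <- length(intersect(set_a, set_b))
  phyper(k - 1, length(set_b), length(universe) - length(set_b),
         length(set_a), lower.tail = FALSE)
}

#' Gene-set enrichment of one module's first-layer targets
#'
#' Tests the module's target genes (the regulator itself is excluded: only
#' first-step targets are tested) against each gene set by
#' \code{\link{fisher_overlap}} and reports sets with unadjusted p below
#' \code{alpha}, sorted by p. No multiplicity adjustment is applied across
#' sets by default (set \code{adjust = TRUE} for a BH-adjusted gate).
#'
#' @param module one row of a module data.frame (see
#'   \code{\link{extract_modules}}), or a list with \code{name} and
#'   \code{targets} (semicolon-joined or character vector).
#' @param gene_sets named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe background gene ids (e.g. all expressed genes).
#' @param alpha significance gate on the (possibly adjusted) p (default 0.05).
#' @param adjust BH-adjust across gene sets before gating (default FALSE).
#' @return data.frame (module, gene_set, overlap, p) sorted by p.
#' @export
module_enrichment <- function(module, gene_sets, universe, alpha = 0.05,
                              adjust = FALSE) {
  if (!length(gene_sets)) stop("no gene sets supplied")
  targets <- module$targets
  if (length(targets) == 1L && grepl(";", targets, fixed = TRUE))
    targets <- strsplit(targets, ";", fixed = TRUE)[[1L]]
  targets <- intersect(unique(targets), universe)
  gene_sets <- lapply(gene_sets, intersect, y = universe)
  p <- vapply(gene_sets, function(gs)
    fisher_overlap(targets, gs, universe), 0)
  ov <- vapply(gene_sets, function(gs) length(intersect(targets, gs)), 0L)
  gate <- if (adjust) p.adjust(p, method = "BH") else p
  keep <- gate < alpha
  out <- data.frame(module = rep(module$name, sum(keep)),
                    gene_set = names(gene_sets)[keep],
                    overlap = ov[keep], p = p[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene_set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-set enrichment across a table of modules
#'
#' @param modules module data.frame.
#' @inheritParams module_enrichment
#' @return row-bound \code{\link{module_enrichment}} results.
#' @export
modules_enrichment <- function(modules, gene_sets, universe, alpha = 0.05,
                               adjust = FALSE) {
  out <- lapply(seq_len(nrow(modules)), function(i)
    module_enrichment(modules[i, , drop = FALSE], gene_sets, universe,
                      alpha, adjust))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(module = character(), gene_set = character(),
                      overlap = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  res
}
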