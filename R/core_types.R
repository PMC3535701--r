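#' @useDynLib comboreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd quantile p.adjust phyper rnorm rpois runif predict
#' @importFrom utils read.delim write.table head
"_PACKAGE"

NODE_TYPES <- c("TF", "miRNA", "gene")
PHENOTYPES <- c("NM", "M")
EDGE_TYPES <- c("TF-TF", "TF-miRNA", "TF-gene", "miRNA-TF", "miRNA-gene")

#' Expression profiles with node types and sample phenotype labels
#'
#' Container for a combined regulator + gene expression matrix. Rows are
#' nodes (transcription factors, microRNAs or genes), columns are samples.
#' Each node carries one of the types \code{"TF"}, \code{"miRNA"},
#' \code{"gene"}; each sample carries one of the phenotype labels
#' \code{"NM"} (non-metastatic) or \code{"M"} (metastatic).
#'
#' @param values numeric matrix, nodes x samples, with unique row and column
#'   names and no missing entries.
#' @param node_types named character vector mapping every node id to
#'   \code{"TF"}, \code{"miRNA"} or \code{"gene"}.
#' @param labels named character vector mapping every sample id to
#'   \code{"NM"} or \code{"M"}.
#' @return An object of class \code{ExpressionProfiles}: a list with elements
#'   \code{values}, \code{node_types} (aligned to rows) and \code{labels}
#'   (aligned to columns).
#' @export
expression_profiles <- function(values, node_types, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row (node) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate node ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("'values' contains missing entries")
  missing_types <- setdiff(rownames(values), names(node_types))
  if (length(missing_types))
    stop("nodes without a type annotation: ",
         paste(head(missing_types, 5), collapse = ", "))
  node_types <- node_types[rownames(values)]
  if (!all(node_types %in% NODE_TYPES))
    stop("unknown node type token(s): ",
         paste(unique(setdiff(node_types, NODE_TYPES)), collapse = ", "))
  missing_lab <- setdiff(colnames(values), names(labels))
  if (length(missing_lab))
    stop("samples without a phenotype label: ",
         paste(head(missing_lab, 5), collapse = ", "))
  labels <- labels[colnames(values)]
  if (!all(labels %in% PHENOTYPES))
    stop("unknown phenotype label token(s): ",
         paste(unique(setdiff(labels, PHENOTYPES)), collapse = ", "))
  structure(list(values = values, node_types = node_types, labels = labels),
            class = "ExpressionProfiles")
}

#' @export
print.ExpressionProfiles <- function(x, ...) {
  cat("ExpressionProfiles:", nrow(x$values), "nodes x", ncol(x$values), "samples\n")
  cat("  nodes:  ", paste(sprintf("%s=%d", names(table(x$node_types)),
                                  as.integer(table(x$node_types))), collapse = ", "), "\n")
  cat("  samples:", paste(sprintf("%s=%d", names(table(x$labels)),
                                  as.integer(table(x$labels))), collapse = ", "), "\n")
  invisible(x)
}

#' Directed candidate regulator-target pair set
#'
#' Sequence-matched candidate pairs with per-source provenance and an edge
#' type derived from the node types of regulator and target. Only regulators
#' of type TF or miRNA are legal, self-loops are disallowed, and miRNA ->
#' miRNA pairs are disallowed.
#'
#' @param regulator,target character vectors of equal length.
#' @param edge_type character vector of edge types, one of
#'   \code{"TF-TF"}, \code{"TF-miRNA"}, \code{"TF-gene"}, \code{"miRNA-TF"},
#'   \code{"miRNA-gene"}.
#' @param sources character vector of comma-separated source names (may be
#'   \code{""} when provenance is unknown).
#' @return A \code{data.frame} of class \code{CandidatePairSet} with columns
#'   \code{regulator}, \code{target}, \code{edge_type}, \code{sources}.
#' @export
candidate_pairs <- function(regulator, target, edge_type,
                            sources = rep("", length(regulator))) {
  stopifnot(length(regulator) == length(target),
            length(regulator) == length(edge_type))
  if (any(regulator == target)) stop("self-loop pair(s) present")
  if (!all(edge_type %in% EDGE_TYPES))
    stop("illegal edge type(s): ",
         paste(unique(setdiff(edge_type, EDGE_TYPES)), collapse = ", "))
  key <- paste(regulator, target, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (regulator, target) pair(s)")
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   edge_type = as.character(edge_type),
                   sources = as.character(sources),
                   stringsAsFactors = FALSE)
  df <- df[order(df$regulator, df$target), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("CandidatePairSet", "data.frame")
  df
}

#' Phenotype-specific weighted regulatory network
#'
#' Directed, typed, weighted edge set for one phenotype. Weights are CLR
#' scores and are non-negative; every edge descends from a candidate pair.
#'
#' @param status phenotype of the samples the network was inferred from,
#'   \code{"NM"} or \code{"M"}.
#' @param edges data.frame with columns \code{regulator}, \code{target},
#'   \code{edge_type}, \code{weight}.
#' @param node_types named character vector typing (at least) every node
#'   appearing in \code{edges}.
#' @return Object of class \code{RegulatoryNetwork}.
#' @export
regulatory_network <- function(status, edges, node_types) {
  status <- match.arg(status, PHENOTYPES)
  need <- c("regulator", "target", "edge_type", "weight")
  if (!all(need %in% names(edges))) stop("edges must have columns: ",
                                         paste(need, collapse = ", "))
  if (nrow(edges) && any(edges$weight < 0)) stop("negative edge weight")
  nodes <- union(edges$regulator, edges$target)
  untyped <- setdiff(nodes, names(node_types))
  if (length(untyped)) stop("untyped network node(s): ",
                            paste(head(untyped, 5), collapse = ", "))
  edges <- edges[order(edges$regulator, edges$target), need, drop = FALSE]
  rownames(edges) <- NULL
  structure(list(status = status, edges = edges,
                 node_types = node_types[sort(nodes)]),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat("RegulatoryNetwork [", x$status, "]: ",
      length(x$node_types), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges)) {
    tab <- table(factor(x$edges$edge_type, levels = EDGE_TYPES))
    cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# nodes of a network: edge endpoints (isolated declared regulators may be
# added by callers via node_types)
network_nodes <- function(net) names(net$node_types)

edge_key <- function(regulator, target) paste(regulator, target, sep = "\r")

#' Module name from regulator id and source phenotype
#'
#' Module names join the regulator id and the source network phenotype with
#' an underscore, with any \code{"-"} in the regulator id (as in mature
#' miRNA ids, e.g. \code{"hsa-miR-16"}) replaced by \code{"_"}:
#' \code{"hsa_miR_16_M"}. The mapping is mechanical and reversible given the
#' regulator id.
#'
#' @param regulator regulator node id.
#' @param status \code{"NM"} or \code{"M"}.
#' @return character module name.
#' @export
module_name <- function(regulator, status) {
  paste(gsub("-", "_", regulator, fixed = TRUE), status, sep = "_")
}
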