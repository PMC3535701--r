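# Readers/writers for the on-disk formats: TSV expression matrices,
# two-column pair lists, TSV/SIF edge lists, GMT gene sets.
# All writers sort their rows so repeated runs are byte-identical.

#' Read an expression matrix with node types and sample labels
#'
#' @param path TSV matrix; header row of sample ids, first column of node ids.
#' @param types_path two-column TSV (node id, type in TF/miRNA/gene), no header.
#' @param labels_path two-column TSV (sample id, label in NM/M), no header.
#' @return \code{\link{expression_profiles}} object; row/column order of the
#'   matrix file is preserved.
#' @export
read_expression <- function(path, types_path, labels_path) {
  for (p in c(path, types_path, labels_path))
    if (!file.exists(p)) stop("file not found: ", p)
  mat <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(mat[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate node id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  values <- as.matrix(mat[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  ty <- read.delim(types_path, header = FALSE, stringsAsFactors = FALSE)
  node_types <- stats::setNames(as.character(ty[[2L]]), as.character(ty[[1L]]))
  lb <- read.delim(labels_path, header = FALSE, stringsAsFactors = FALSE)
  labels <- stats::setNames(as.character(lb[[2L]]), as.character(lb[[1L]]))
  expression_profiles(values, node_types, labels)
}

#' Write expression profiles to TSV files
#'
#' Inverse of \code{\link{read_expression}} up to numeric formatting.
#'
#' @param profiles an \code{ExpressionProfiles} object.
#' @param path,types_path,labels_path output TSV paths (types/labels optional).
#' @export
write_expression <- function(profiles, path, types_path = NULL,
                             labels_path = NULL) {
  df <- data.frame(node = rownames(profiles$values),
                   profiles$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(types_path))
    write.table(data.frame(names(profiles$node_types), profiles$node_types),
                types_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  if (!is.null(labels_path))
    write.table(data.frame(names(profiles$labels), profiles$labels),
                labels_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read per-source candidate pair lists
#'
#' Each file is a headerless two-column TSV (regulator, target); the file
#' stem names the source. Duplicate pairs within a file are collapsed.
#'
#' @param paths character vector of file paths.
#' @return named list, source -> data.frame(regulator, target), one row per
#'   distinct ordered pair, sorted.
#' @export
read_pairs <- function(paths) {
  out <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("pair file not found: ", p)
    src <- tools::file_path_sans_ext(basename(p))
    lines <- readLines(p)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      warning("empty pair file: ", p)
      out[[src]] <- data.frame(regulator = character(), target = character(),
                               stringsAsFactors = FALSE)
      next
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 2L)
    if (length(bad))
      stop("malformed line ", bad[1L], " in ", p, ": expected 2 tab-separated fields")
    reg <- vapply(fields, `[[`, "", 1L)
    tgt <- vapply(fields, `[[`, "", 2L)
    keep <- !duplicated(edge_key(reg, tgt))
    df <- data.frame(regulator = reg[keep], target = tgt[keep],
                     stringsAsFactors = FALSE)
    df <- df[order(df$regulator, df$target), , drop = FALSE]
    rownames(df) <- NULL
    out[[src]] <- df
  }
  out
}

#' Write a pair list as a headerless two-column TSV
#' @param pairs data.frame with columns \code{regulator}, \code{target}.
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  pairs <- pairs[order(pairs$regulator, pairs$target), c("regulator", "target")]
  write.table(pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Write a regulatory network as TSV or SIF
#'
#' The TSV dialect has a header and columns (regulator, target, edge_type,
#' weight) with weights printed to 6 decimals; SIF emits
#' (regulator, edge_type, target). Lines are sorted by regulator then target.
#'
#' @param net a \code{RegulatoryNetwork}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"sif"}.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  e <- net$edges[order(net$edges$regulator, net$edges$target), , drop = FALSE]
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(err)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  if (format == "tsv") {
    writeLines("regulator\ttarget\tedge_type\tweight", con)
    if (nrow(e))
      writeLines(sprintf("%s\t%s\t%s\t%.6f", e$regulator, e$target,
                         e$edge_type, e$weight), con)
  } else {
    if (nrow(e))
      writeLines(sprintf("%s\t%s\t%s", e$regulator, e$edge_type, e$target), con)
  }
  invisible(NULL)
}

#' Read a regulatory network written by \code{\link{write_network}} (TSV)
#'
#' @param path TSV edge list with header (regulator, target, edge_type, weight).
#' @param status phenotype to attach, \code{"NM"} or \code{"M"}.
#' @param node_types optional named type vector; inferred from edge types
#'   when omitted.
#' @return A \code{RegulatoryNetwork}.
#' @export
read_network <- function(path, status, node_types = NULL) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (is.null(node_types)) {
    # edge types encode both endpoint types, so reconstruct the annotation
    parts <- strsplit(df$edge_type, "-", fixed = TRUE)
    rt <- vapply(parts, `[[`, "", 1L)
    tt <- vapply(parts, function(p) p[[length(p)]], "")
    node_types <- c(stats::setNames(rt, df$regulator),
                    stats::setNames(tt, df$target))
    node_types <- node_types[!duplicated(names(node_types))]
  }
  regulatory_network(status, df, node_types)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated (name, description,
#' members...). Member lists are deduplicated; an empty description field is
#' tolerated.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set name -> member ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set name(s): ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = rep("na", length(sets))) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(NULL)
}
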