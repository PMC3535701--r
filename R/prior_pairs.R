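# Assembly of the sequence-matched candidate pair set: multi-source
# consensus for miRNA targets, union of all edge classes, self-loop removal,
# restriction to expressed nodes.

#' Consensus pairs across prediction sources
#'
#' Retains ordered pairs reported by at least \code{min_sources} of the
#' provided sources (the study's rule: agreement of at least two target
#' prediction algorithms).
#'
#' @param source_lists named list, source -> data.frame(regulator, target),
#'   as returned by \code{\link{read_pairs}}.
#' @param min_sources minimum number of supporting sources.
#' @return data.frame(regulator, target, sources) where \code{sources} is the
#'   comma-separated list of supporting source names, sorted by pair.
#' @export
consensus_pairs <- function(source_lists, min_sources = 2L) {
  if (min_sources < 1L) stop("min_sources must be >= 1")
  if (min_sources > length(source_lists))
    stop("min_sources (", min_sources, ") exceeds number of sources (",
         length(source_lists), ")")
  all <- do.call(rbind, lapply(names(source_lists), function(s) {
    df <- source_lists[[s]]
    if (!nrow(df)) return(NULL)
    data.frame(regulator = df$regulator, target = df$target, source = s,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all) || !nrow(all))
    return(data.frame(regulator = character(), target = character(),
                      sources = character(), stringsAsFactors = FALSE))
  key <- edge_key(all$regulator, all$target)
  support <- tapply(all$source, key, function(s) sort(unique(s)))
  keep <- names(support)[lengths(support) >= min_sources]
  if (!length(keep))
    return(data.frame(regulator = character(), target = character(),
                      sources = character(), stringsAsFactors = FALSE))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  df <- data.frame(regulator = vapply(parts, `[[`, "", 1L),
                   target = vapply(parts, `[[`, "", 2L),
                   sources = vapply(support[keep], paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  df <- df[order(df$regulator, df$target), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assemble the typed candidate pair set restricted to expressed nodes
#'
#' Takes the union of TF-target, TF-miRNA and (consensus) miRNA-target pair
#' lists, removes self-loops and pairs with either node absent from the
#' expression profiles, classifies each surviving pair into one of the five
#' legal edge types from the node-type annotation, and rejects illegal
#' pairs (e.g. a non-TF gene as regulator, or miRNA -> miRNA) with a
#' warning giving the count.
#'
#' @param tf_pairs,tf_mirna_pairs,mirna_pairs data.frames with columns
#'   \code{regulator}, \code{target} (and optionally \code{sources}); any may
#'   be \code{NULL} or empty.
#' @param profiles \code{ExpressionProfiles} supplying the expressed node set
#'   and node types.
#' @return A \code{\link{candidate_pairs}} set.
#' @export
assemble_candidates <- function(tf_pairs = NULL, tf_mirna_pairs = NULL,
                                mirna_pairs = NULL, profiles) {
  stopifnot(inherits(profiles, "ExpressionProfiles"))
  pick <- function(df) {
    if (is.null(df) || !nrow(df)) return(NULL)
    if (!("sources" %in% names(df))) df$sources <- ""
    df[, c("regulator", "target", "sources")]
  }
  all <- do.call(rbind, Filter(Negate(is.null),
                               list(pick(tf_pairs), pick(tf_mirna_pairs),
                                    pick(mirna_pairs))))
  if (is.null(all) || !nrow(all))
    return(candidate_pairs(character(), character(), character(), character()))
  # collapse duplicates across the input lists, merging provenance
  key <- edge_key(all$regulator, all$target)
  src <- tapply(all$sources, key, function(s)
    paste(sort(unique(unlist(strsplit(s[nzchar(s)], ",", fixed = TRUE)))),
          collapse = ","))
  parts <- strsplit(names(src), "\r", fixed = TRUE)
  df <- data.frame(regulator = vapply(parts, `[[`, "", 1L),
                   target = vapply(parts, `[[`, "", 2L),
                   sources = unname(unlist(src)),
                   stringsAsFactors = FALSE)
  df <- df[df$regulator != df$target, , drop = FALSE]
  expressed <- rownames(profiles$values)
  df <- df[df$regulator %in% expressed & df$target %in% expressed, ,
           drop = FALSE]
  if (!nrow(df))
    return(candidate_pairs(character(), character(), character(), character()))
  et <- classify_edge_type(df$regulator, df$target, profiles$node_types)
  legal <- et %in% EDGE_TYPES
  if (any(!legal))
    warning(sum(!legal), " pair(s) with illegal edge type dropped (e.g. ",
            et[!legal][1L], ")")
  df <- df[legal, , drop = FALSE]
  candidate_pairs(df$regulator, df$target, et[legal], df$sources)
}
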