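# Comparison of the two phenotype networks: overview counts, node/edge
# category partitions, per-regulator-type target-increase rates, and
# topology statistics (degree / betweenness / edge betweenness).

#' Node- and edge-type overview counts of a network
#'
#' @param net a \code{RegulatoryNetwork}.
#' @return list with \code{n_nodes}, \code{nodes_by_type} (TF/miRNA/gene),
#'   \code{n_edges}, \code{edges_by_type} (the five legal edge types);
#'   counts by type partition the totals.
#' @export
network_overview <- function(net) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  nt <- table(factor(net$node_types, levels = NODE_TYPES))
  et <- table(factor(net$edges$edge_type, levels = EDGE_TYPES))
  list(status = net$status,
       n_nodes = length(net$node_types),
       nodes_by_type = stats::setNames(as.integer(nt), names(nt)),
       n_edges = nrow(net$edges),
       edges_by_type = stats::setNames(as.integer(et), names(et)))
}

#' Partition nodes and edges into NM-specific / common / M-specific
#'
#' An edge is common iff the identical ordered (regulator, target) pair
#' exists in both networks; a node is common iff it appears in both.
#'
#' @param nm,m the two phenotype networks.
#' @return list with \code{nodes} and \code{edges}, each a list of character
#'   vectors \code{NM_specific}, \code{common}, \code{M_specific} (edges as
#'   "regulator->target" strings), plus count summaries.
#' @export
categorize <- function(nm, m) {
  stopifnot(inherits(nm, "RegulatoryNetwork"), inherits(m, "RegulatoryNetwork"))
  n_nm <- network_nodes(nm); n_m <- network_nodes(m)
  e_nm <- paste(nm$edges$regulator, nm$edges$target, sep = "->")
  e_m <- paste(m$edges$regulator, m$edges$target, sep = "->")
  part <- function(a, b) list(NM_specific = sort(setdiff(a, b)),
                              common = sort(intersect(a, b)),
                              M_specific = sort(setdiff(b, a)))
  nodes <- part(n_nm, n_m); edges <- part(e_nm, e_m)
  list(nodes = nodes, edges = edges,
       node_counts = lengths(nodes), edge_counts = lengths(edges))
}

#' Increase rate of average target count per regulator type, M vs NM
#'
#' For each legal (regulator type, target type) combination, the mean number
#' of targets of that type per regulator -- restricted to regulators having
#' at least one such target -- is computed in each network, and the relative
#' increase (mean_M - mean_NM) / mean_NM is returned. The rate is \code{NA}
#' when the combination is absent from the NM network.
#'
#' @param nm,m the two phenotype networks.
#' @return data.frame with columns \code{regulator_type},
#'   \code{target_type}, \code{mean_NM}, \code{mean_M}, \code{rate}.
#' @export
avg_target_increase <- function(nm, m) {
  combos <- do.call(rbind, strsplit(EDGE_TYPES, "-", fixed = TRUE))
  mean_deg <- function(net, rt, tt) {
    e <- net$edges[net$edges$edge_type == paste(rt, tt, sep = "-"), ,
                   drop = FALSE]
    if (!nrow(e)) return(NA_real_)
    mean(table(e$regulator))
  }
  out <- data.frame(regulator_type = combos[, 1L], target_type = combos[, 2L],
                    stringsAsFactors = FALSE)
  out$mean_NM <- mapply(mean_deg, list(nm), out$regulator_type, out$target_type)
  out$mean_M <- mapply(mean_deg, list(m), out$regulator_type, out$target_type)
  out$rate <- ifelse(is.na(out$mean_NM) | out$mean_NM == 0, NA_real_,
                     (out$mean_M - out$mean_NM) / out$mean_NM)
  out
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("regulator", "target")],
                                directed = TRUE,
                                vertices = network_nodes(net))
}

#' Topology statistics: degree, betweenness, edge betweenness
#'
#' Shortest-path (unweighted) betweenness on the directed graph,
#' unnormalized. Rankings break ties by node id (then target id for edges).
#'
#' @param net a \code{RegulatoryNetwork}.
#' @param top_k length of the hub / bottleneck / edge-bottleneck lists.
#' @return list with per-node data.frame \code{nodes} (id, degree, in/out
#'   degree, betweenness), per-edge data.frame \code{edges} (regulator,
#'   target, edge_betweenness), and ranked \code{hubs} (by degree),
#'   \code{bottlenecks} (by betweenness), \code{edge_bottlenecks}.
#' @export
topology_stats <- function(net, top_k = 10L) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  g <- as_igraph(net)
  ids <- igraph::V(g)$name
  nodes <- data.frame(
    id = ids,
    degree = as.integer(igraph::degree(g, mode = "all")),
    in_degree = as.integer(igraph::degree(g, mode = "in")),
    out_degree = as.integer(igraph::degree(g, mode = "out")),
    betweenness = igraph::betweenness(g, directed = TRUE, normalized = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  eb <- igraph::edge_betweenness(g, directed = TRUE)
  edges <- data.frame(regulator = net$edges$regulator,
                      target = net$edges$target,
                      edge_betweenness = eb, stringsAsFactors = FALSE)
  rank_top <- function(df, key) {
    args <- c(list(-df[[key]], df[[1L]]),
              if ("target" %in% names(df)) list(df$target))
    ord <- do.call(order, args)
    head(df[ord, , drop = FALSE], top_k)
  }
  list(nodes = nodes, edges = edges,
       hubs = rank_top(nodes, "degree"),
       bottlenecks = rank_top(nodes, "betweenness"),
       edge_bottlenecks = rank_top(edges, "edge_betweenness"))
}
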