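# Differential-module extraction: non-discriminative-edge removal,
# regulator-headed first-layer modules, permutation global ANCOVA gene-set
# test and BH-gated ranking.

#' Remove non-discriminative edges from both phenotype networks
#'
#' Over the union of the two networks' edges, computes the absolute CLR
#' weight difference |w_NM - w_M| (a missing edge has weight 0) and removes
#' the \code{floor(frac * |union|)} edges with the smallest difference
#' (ties broken by edge id) from both networks.
#'
#' @param nm,m the two phenotype networks.
#' @param frac fraction of union edges to drop, in [0, 1) (default 0.25).
#' @return list with filtered networks \code{nm}, \code{m} and the dropped
#'   edge ids \code{removed}.
#' @export
differential_edge_filter <- function(nm, m, frac = 0.25) {
  if (!is.numeric(frac) || frac < 0 || frac >= 1)
    stop("'frac' must lie in [0, 1)")
  key_nm <- edge_key(nm$edges$regulator, nm$edges$target)
  key_m <- edge_key(m$edges$regulator, m$edges$target)
  union_key <- union(key_nm, key_m)
  if (!length(union_key)) return(list(nm = nm, m = m, removed = character()))
  w_nm <- stats::setNames(rep(0, length(union_key)), union_key)
  w_nm[key_nm] <- nm$edges$weight
  w_m <- stats::setNames(rep(0, length(union_key)), union_key)
  w_m[key_m] <- m$edges$weight
  d <- abs(w_nm - w_m)
  n_drop <- floor(frac * length(union_key))
  drop <- union_key[order(d, union_key)][seq_len(n_drop)]
  strip <- function(net, keys) {
    keep <- !(keys %in% drop)
    regulatory_network(net$status, net$edges[keep, , drop = FALSE],
                       net$node_types)
  }
  list(nm = strip(nm, key_nm), m = strip(m, key_m),
       removed = gsub("\r", "->", drop, fixed = TRUE))
}

#' Extract regulator-headed first-layer modules from a network
#'
#' One module per regulator with more than one first-layer target: the
#' module is the regulator plus all of its direct out-neighbors, named
#' \code{Regulator_Status} (with \code{"-"} replaced by \code{"_"}).
#'
#' @param net a \code{RegulatoryNetwork} (typically after
#'   \code{\link{differential_edge_filter}}).
#' @return data.frame with columns \code{name}, \code{regulator},
#'   \code{status}, \code{targets} (semicolon-joined), \code{n_targets}.
#' @export
extract_modules <- function(net) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  tg <- split(net$edges$target, net$edges$regulator)
  tg <- lapply(tg, function(x) sort(unique(x)))
  tg <- tg[lengths(tg) >= 2L]
  if (!length(tg))
    return(data.frame(name = character(), regulator = character(),
                      status = character(), targets = character(),
                      n_targets = integer(), stringsAsFactors = FALSE))
  df <- data.frame(name = module_name(names(tg), net$status),
                   regulator = names(tg), status = net$status,
                   targets = vapply(tg, paste, "", collapse = ";"),
                   n_targets = lengths(tg),
                   stringsAsFactors = FALSE, row.names = NULL)
  df[order(df$name), , drop = FALSE]
}

#' Member node ids of each module row
#'
#' The tested node set of a module is its regulator plus all targets.
#'
#' @param modules module data.frame (see \code{\link{extract_modules}}).
#' @return named list of character vectors.
#' @export
module_members <- function(modules) {
  stats::setNames(lapply(seq_len(nrow(modules)), function(i)
    unique(c(modules$regulator[i],
             strsplit(modules$targets[i], ";", fixed = TRUE)[[1L]]))),
    modules$name)
}

#' Permutation global ANCOVA test of a node set against the phenotype
#'
#' Tests whether the joint expression of a module's nodes differs between
#' the two phenotype groups. Per node g, the full model fits a group mean
#' per phenotype and the reduced model a grand mean; the statistic pools
#' residual sums of squares across nodes:
#' \deqn{F = \frac{\sum_g (RSS_{red,g} - RSS_{full,g}) / df_{extra}}
#'            {\sum_g RSS_{full,g} / df_{resid}}}
#' with \eqn{df_{extra} = G} and \eqn{df_{resid} = G (n - 2)} for G nodes
#' and two groups. For a single node the statistic equals the squared
#' pooled two-sample t statistic. Significance comes from random label
#' permutations with the +1 correction:
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param module_nodes character vector of node ids (regulator + targets).
#' @param profiles \code{ExpressionProfiles} with both labels present.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return list with \code{statistic} (observed F), \code{p_value},
#'   \code{n_perm}.
#' @export
global_ancova <- function(module_nodes, profiles, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(profiles, "ExpressionProfiles"))
  y <- profiles$labels
  if (length(unique(y)) != 2L) stop("both phenotype labels must be present")
  member <- ga_perm_matrix(length(y), sum(y == "M"), n_perm, seed)
  ga_core(ga_module_matrix(module_nodes, profiles), y, member)
}

ga_module_matrix <- function(module_nodes, profiles) {
  if (!length(module_nodes)) stop("empty module")
  missing <- setdiff(module_nodes, rownames(profiles$values))
  if (length(missing)) stop("module node(s) absent from profiles: ",
                            paste(head(missing, 5), collapse = ", "))
  profiles$values[module_nodes, , drop = FALSE]
}

# 0/1 matrix (n x n_perm) flagging the permuted group-M members per column
ga_perm_matrix <- function(n, n1, n_perm, seed) {
  set.seed(as.integer(seed))
  rows <- vapply(seq_len(n_perm), function(i) sample.int(n, n1),
                 integer(n1))
  member <- matrix(0, n, n_perm)
  member[cbind(as.vector(rows), rep(seq_len(n_perm), each = n1))] <- 1
  member
}

# observed pooled F and its permutation p for one module's rows
ga_core <- function(X, y, member) {
  n <- ncol(X)
  n1 <- sum(y == "M"); n2 <- n - n1
  G <- nrow(X)
  rss_red <- rowSums((X - rowMeans(X))^2)
  tot_red <- sum(rss_red)
  xsum <- rowSums(X)
  fstat <- function(mem) {
    s1 <- X %*% mem                            # G x P group-M sums
    b <- (n1 * n2 / n) * ((s1 / n1 - (xsum - s1) / n2))^2
    num <- colSums(b) / G
    den <- (tot_red - colSums(b)) / (G * (n - 2))
    f <- num / den
    f[den <= 0] <- 0
    f
  }
  obs <- fstat(matrix(as.numeric(y == "M"), ncol = 1L))[1L]
  if (tot_red == 0)
    return(list(statistic = 0, p_value = 1, n_perm = ncol(member)))
  perm_f <- fstat(member)
  list(statistic = unname(obs),
       p_value = (1 + sum(perm_f >= obs)) / (1 + ncol(member)),
       n_perm = ncol(member))
}

#' Test, adjust and rank candidate differential modules
#'
#' Computes the permutation global ANCOVA p-value for every module
#' (regulator + targets as the tested node set), Benjamini-Hochberg-adjusts
#' across all modules from both networks jointly, retains modules with
#' adjusted p < \code{alpha}, sorts ascending by raw p (ties by module
#' name) and assigns ranks 1..k.
#'
#' @param modules module data.frame (rows from both networks, see
#'   \code{\link{extract_modules}}).
#' @param profiles \code{ExpressionProfiles}.
#' @param alpha BH-adjusted significance gate (default 0.001).
#' @param n_perm number of label permutations, shared across all modules
#'   (as is standard for permutation gene-set tests). The default 50000
#'   gives the permutation p-value enough resolution for the BH gate: with
#'   m modules the smallest attainable adjusted p is m/(n_perm + 1), so
#'   n_perm must comfortably exceed m/alpha for any module to be able to
#'   pass at alpha = 0.001.
#' @param seed integer seed for the shared permutation set.
#' @return the significant modules with added columns \code{p_raw},
#'   \code{p_adj}, \code{rank}; the full tested table (all modules) is
#'   attached as attribute \code{"all"}.
#' @export
rank_modules <- function(modules, profiles, alpha = 0.001, n_perm = 50000L,
                         seed = 1L) {
  if (!nrow(modules)) stop("no modules to rank")
  y <- profiles$labels
  if (length(unique(y)) != 2L) stop("both phenotype labels must be present")
  member <- ga_perm_matrix(length(y), sum(y == "M"), n_perm, seed)
  members <- module_members(modules)
  modules$p_raw <- vapply(members, function(nd)
    ga_core(ga_module_matrix(nd, profiles), y, member)$p_value, 0)
  modules$p_adj <- p.adjust(modules$p_raw, method = "BH")
  all <- modules[order(modules$p_raw, modules$name), , drop = FALSE]
  rownames(all) <- NULL
  sig <- all[all$p_adj < alpha, , drop = FALSE]
  if (nrow(sig)) sig$rank <- seq_len(nrow(sig))
  else sig$rank <- integer(0)
  rownames(sig) <- NULL
  attr(sig, "all") <- all
  sig
}
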