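# Planted-network synthetic data: a directed combinatorial network over
# TF/miRNA/gene nodes with condition-specific edges, linear regulator
# effects (miRNA repression, TF activation/repression) plus Gaussian noise,
# and noisy multi-source candidate-pair predictions. Every downstream stage
# of the pipeline is testable against the planted truth.

#' Configuration for the synthetic-data generator
#'
#' @param n_tf,n_mirna,n_gene node counts per type.
#' @param n_nm_samples,n_m_samples samples per phenotype (NM / M).
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   target rows.
#' @param effect_sd spread of regulatory-effect magnitudes.
#' @param effect_min minimum effect magnitude; with the defaults
#'   (\code{effect_min = 1}, \code{noise_sd = 0.5}) every planted effect
#'   satisfies |effect| >= 2 * noise_sd, i.e. a strong-signal regime.
#' @param common_fraction expected fraction of each condition's edges shared
#'   with the other condition.
#' @param activity_shift mean expression shift of a regulator in a condition
#'   where it has condition-specific targets (differential regulator
#'   activity: a regulator that acquires targets in one phenotype is more
#'   active there). Targets inherit the shift through their effects, so
#'   condition-specific modules are both re-wired and differentially
#'   expressed; set to 0 for a pure re-wiring model with identical group
#'   means.
#' @param targets_lambda mean number of extra targets per regulator beyond
#'   the guaranteed 2 (Poisson).
#' @param prior_sensitivity probability that a prediction source reports a
#'   true edge.
#' @param prior_fp_rate probability that a source reports a legal non-edge.
#' @param n_sources number of independent prediction sources.
#' @param seed integer seed; one global seed drives a per-operation seed
#'   sequence so each stage is independently reproducible.
#' @return list of class \code{SynthConfig}.
#' @export
synth_config <- function(n_tf = 10, n_mirna = 10, n_gene = 200,
                         n_nm_samples = 60, n_m_samples = 20,
                         noise_sd = 0.5, effect_sd = 0.5, effect_min = 1,
                         common_fraction = 0.5, activity_shift = 1,
                         targets_lambda = 2,
                         prior_sensitivity = 0.85, prior_fp_rate = 0.05,
                         n_sources = 3, seed = 1L) {
  cfg <- list(n_tf = n_tf, n_mirna = n_mirna, n_gene = n_gene,
              n_nm_samples = n_nm_samples, n_m_samples = n_m_samples,
              noise_sd = noise_sd, effect_sd = effect_sd,
              effect_min = effect_min, common_fraction = common_fraction,
              activity_shift = activity_shift,
              targets_lambda = targets_lambda,
              prior_sensitivity = prior_sensitivity,
              prior_fp_rate = prior_fp_rate, n_sources = n_sources,
              seed = as.integer(seed))
  counts <- c(cfg$n_tf, cfg$n_mirna, cfg$n_gene,
              cfg$n_nm_samples, cfg$n_m_samples, cfg$n_sources)
  if (any(counts < 0) || cfg$n_tf + cfg$n_mirna < 1 || cfg$n_gene < 1 ||
      cfg$n_nm_samples < 1 || cfg$n_m_samples < 1 || cfg$n_sources < 1)
    stop("invalid counts in synth_config")
  probs <- c(cfg$common_fraction, cfg$prior_sensitivity, cfg$prior_fp_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$noise_sd <= 0 || cfg$effect_sd <= 0)
    stop("noise_sd and effect_sd must be positive")
  class(cfg) <- "SynthConfig"
  cfg
}

synth_node_ids <- function(cfg) {
  c(if (cfg$n_tf) sprintf("TF%02d", seq_len(cfg$n_tf)),
    if (cfg$n_mirna) sprintf("miR%02d", seq_len(cfg$n_mirna)),
    sprintf("g%03d", seq_len(cfg$n_gene)))
}

synth_node_types <- function(cfg) {
  ids <- synth_node_ids(cfg)
  stats::setNames(rep(c("TF", "miRNA", "gene"),
                      c(cfg$n_tf, cfg$n_mirna, cfg$n_gene)), ids)
}

# all (regulator, target) pairs allowed by the type rules:
# TF -> anything but itself; miRNA -> TF or gene (miRNA->miRNA disallowed)
legal_pairs <- function(node_types) {
  regs <- names(node_types)[node_types %in% c("TF", "miRNA")]
  out <- lapply(regs, function(r) {
    if (node_types[[r]] == "TF") tg <- setdiff(names(node_types), r)
    else tg <- names(node_types)[node_types %in% c("TF", "gene")]
    data.frame(regulator = rep(r, length(tg)), target = tg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

classify_edge_type <- function(regulator, target, node_types) {
  paste(unname(node_types[regulator]), unname(node_types[target]), sep = "-")
}

#' Generate a planted two-condition regulatory network
#'
#' Draws, per regulator, a set of targets under the five legal edge types
#' (TF-TF, TF-miRNA, TF-gene, miRNA-TF, miRNA-gene); each edge is shared
#' between the NM and M conditions with probability \code{common_fraction},
#' otherwise assigned to one condition. Shared edges carry identical effects.
#' Effects are \code{sign * (effect_min + |N(0, effect_sd)|)} with the sign
#' forced negative for miRNA regulators (repression) and Rademacher for TFs.
#' Every regulator has at least 2 targets in at least one condition, so
#' modules exist downstream.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return list of class \code{PlantedNetwork} with elements
#'   \code{node_types}, \code{true_edges_NM}, \code{true_edges_M}
#'   (data.frames regulator/target/edge_type/effect) and \code{config}.
#' @export
generate_planted_network <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  node_types <- synth_node_types(cfg)
  regs <- names(node_types)[node_types %in% c("TF", "miRNA")]
  rows <- list()
  for (r in regs) {
    if (node_types[[r]] == "TF") pool <- setdiff(names(node_types), r)
    else pool <- names(node_types)[node_types %in% c("TF", "gene")]
    k <- min(length(pool), 2L + rpois(1L, cfg$targets_lambda))
    if (k > length(pool))
      stop("requested more targets than legal pairs for ", r)
    tg <- sample(pool, k)
    mag <- cfg$effect_min + abs(rnorm(k, 0, cfg$effect_sd))
    sgn <- if (node_types[[r]] == "miRNA") rep(-1, k)
           else sample(c(-1, 1), k, replace = TRUE)
    shared <- runif(k) < cfg$common_fraction
    cond <- ifelse(shared, "both", sample(PHENOTYPES, k, replace = TRUE))
    # guarantee >=2 targets in at least one condition
    n_nm <- sum(cond != "M"); n_m <- sum(cond != "NM")
    if (max(n_nm, n_m) < 2L && k >= 2L)
      cond[1:2] <- if (sample(2L, 1L) == 1L) c("NM", "NM") else c("M", "M")
    rows[[r]] <- data.frame(regulator = r, target = tg,
                            edge_type = classify_edge_type(r, tg, node_types),
                            effect = sgn * mag, condition = cond,
                            stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  pick <- function(status) {
    e <- all[all$condition %in% c("both", status),
             c("regulator", "target", "edge_type", "effect")]
    e <- e[order(e$regulator, e$target), , drop = FALSE]
    rownames(e) <- NULL
    e
  }
  # differential regulator activity: a regulator with condition-specific
  # targets is shifted upward in that condition
  activity <- data.frame(
    regulator = regs,
    shift_NM = cfg$activity_shift *
      (regs %in% all$regulator[all$condition == "NM"]),
    shift_M = cfg$activity_shift *
      (regs %in% all$regulator[all$condition == "M"]),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(node_types = node_types,
                 true_edges_NM = pick("NM"), true_edges_M = pick("M"),
                 activity = activity, config = cfg),
            class = "PlantedNetwork")
}

#' Simulate two-condition expression data from a planted network
#'
#' Source nodes (no in-edges in the relevant condition) are i.i.d. standard
#' normal; every other node's row is the sum over its in-edges of
#' effect x regulator value, plus Gaussian(0, noise_sd) noise. A regulator
#' with condition-specific targets additionally receives its activity shift
#' (see \code{\link{synth_config}}) in that condition. NM samples are
#' generated under the NM edge set and M samples under the M edge set.
#' Regulator-regulator dependencies are resolved in topological order; if a
#' directed cycle exists among regulators, cycle edges are applied in one
#' pass over nodes in id order (documented contract).
#'
#' @param pn a \code{PlantedNetwork}.
#' @param cfg a \code{\link{synth_config}} (defaults to the one stored in
#'   \code{pn}).
#' @return \code{\link{expression_profiles}} with samples \code{NM001...}
#'   and \code{M001...} and matching labels.
#' @export
simulate_expression <- function(pn, cfg = pn$config) {
  stopifnot(inherits(pn, "PlantedNetwork"))
  set.seed(cfg$seed + 1L)
  node_types <- pn$node_types
  ids <- names(node_types)
  shift_col <- c(NM = "shift_NM", M = "shift_M")
  sim_condition <- function(edges, n_samples, status) {
    vals <- matrix(rnorm(length(ids) * n_samples), length(ids), n_samples,
                   dimnames = list(ids, NULL))
    shift <- stats::setNames(rep(0, length(ids)), ids)
    if (!is.null(pn$activity))
      shift[pn$activity$regulator] <- pn$activity[[shift_col[[status]]]]
    vals <- vals + shift
    targets <- unique(edges$target)
    # topological order over the in-edge graph; cycles broken in id order
    order_ids <- ids
    if (length(targets)) {
      g <- igraph::graph_from_data_frame(edges[, c("regulator", "target")],
                                         vertices = ids)
      ord <- tryCatch(names(igraph::topo_sort(g, mode = "out")),
                      error = function(e) NULL)
      if (!is.null(ord) && length(ord) == length(ids)) order_ids <- ord
    }
    for (id in order_ids) {
      if (!(id %in% targets)) next
      ein <- edges[edges$target == id, , drop = FALSE]
      pred <- vals[ein$regulator, , drop = FALSE] * ein$effect
      vals[id, ] <- colSums(pred) + shift[[id]] +
        rnorm(n_samples, 0, cfg$noise_sd)
    }
    vals
  }
  nm <- sim_condition(pn$true_edges_NM, cfg$n_nm_samples, "NM")
  m <- sim_condition(pn$true_edges_M, cfg$n_m_samples, "M")
  colnames(nm) <- sprintf("NM%03d", seq_len(cfg$n_nm_samples))
  colnames(m) <- sprintf("M%03d", seq_len(cfg$n_m_samples))
  values <- cbind(nm, m)
  labels <- stats::setNames(rep(PHENOTYPES, c(cfg$n_nm_samples, cfg$n_m_samples)),
                            colnames(values))
  expression_profiles(values, node_types, labels)
}

#' Generate noisy multi-source candidate regulator-target predictions
#'
#' Emulates multiple sequence-based prediction databases: each source
#' independently reports each true edge (union of both conditions) with
#' probability \code{prior_sensitivity} and each legal non-edge with
#' probability \code{prior_fp_rate}.
#'
#' @param pn a \code{PlantedNetwork}.
#' @param cfg a \code{\link{synth_config}}.
#' @return named list \code{source1..sourceN} of data.frames
#'   (regulator, target), as returned by \code{\link{read_pairs}}.
#' @export
generate_candidate_priors <- function(pn, cfg = pn$config) {
  stopifnot(inherits(pn, "PlantedNetwork"))
  set.seed(cfg$seed + 2L)
  truth <- unique(rbind(pn$true_edges_NM[, c("regulator", "target")],
                        pn$true_edges_M[, c("regulator", "target")]))
  lp <- legal_pairs(pn$node_types)
  is_true <- edge_key(lp$regulator, lp$target) %in%
    edge_key(truth$regulator, truth$target)
  out <- list()
  for (s in seq_len(cfg$n_sources)) {
    p <- ifelse(is_true, cfg$prior_sensitivity, cfg$prior_fp_rate)
    keep <- runif(nrow(lp)) < p
    df <- lp[keep, , drop = FALSE]
    df <- df[order(df$regulator, df$target), , drop = FALSE]
    rownames(df) <- NULL
    out[[sprintf("source%d", s)]] <- df
  }
  out
}

#' Generate a complete synthetic study (network, expression, priors)
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return list with \code{network} (PlantedNetwork), \code{profiles}
#'   (ExpressionProfiles) and \code{priors} (per-source pair lists).
#' @export
simulate_study <- function(cfg = synth_config()) {
  pn <- generate_planted_network(cfg)
  list(network = pn,
       profiles = simulate_expression(pn, cfg),
       priors = generate_candidate_priors(pn, cfg))
}
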