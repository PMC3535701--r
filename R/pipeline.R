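# End-to-end orchestration: simulate -> preprocess -> priors -> corr-filter
# -> infer (NM, M) -> compare -> modules -> classify [-> enrich], persisting
# every intermediate and a summary JSON. Reruns with the same config are
# byte-identical.

#' Default pipeline configuration
#'
#' @param seed global integer seed; drives the synthetic generator and every
#'   stochastic stage.
#' @param synth list of \code{\link{synth_config}} overrides.
#' @param preprocess_frac lowest-SD row fraction removed (default 0.05).
#' @param min_sources prior consensus rule (default 2 sources).
#' @param corr_reps,corr_q empirical-null repetitions and quantile for the
#'   Spearman pair filter (defaults 100, 0.95).
#' @param weight_cutoff CLR edge-weight cutoff (default 1).
#' @param edge_filter_frac non-discriminative edge fraction removed
#'   (default 0.25).
#' @param alpha BH gate for module significance (default 0.001).
#' @param n_perm global ANCOVA permutations (default 50000; see
#'   \code{\link{rank_modules}}).
#' @param k_max maximum number of top modules accumulated by the classifier
#'   (default 17).
#' @param gmt optional GMT path for the enrichment stage (NULL skips it).
#' @return nested configuration list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(seed = 1L, synth = list(), preprocess_frac = 0.05,
                            min_sources = 2L, corr_reps = 100L, corr_q = 0.95,
                            weight_cutoff = 1.0, edge_filter_frac = 0.25,
                            alpha = 0.001, n_perm = 50000L, k_max = 17L,
                            gmt = NULL) {
  seed <- as.integer(seed)
  scfg <- do.call(synth_config, c(synth[setdiff(names(synth), "seed")],
                                  list(seed = seed)))
  if (scfg$n_m_samples < 1 || scfg$n_nm_samples < 1)
    stop("both phenotypes need at least one sample")
  structure(list(seed = seed, synth = scfg,
                 preprocess_frac = preprocess_frac,
                 min_sources = as.integer(min_sources),
                 corr_reps = as.integer(corr_reps), corr_q = corr_q,
                 weight_cutoff = weight_cutoff,
                 edge_filter_frac = edge_filter_frac,
                 alpha = alpha, n_perm = as.integer(n_perm),
                 k_max = as.integer(k_max), gmt = gmt),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{pipeline_config}};
#' the \code{synth} key is a mapping of \code{\link{synth_config}}
#' overrides.
#'
#' @param path YAML file path.
#' @return \code{PipelineConfig}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the full synthetic-study pipeline
#'
#' Executes all stages in order on a seeded synthetic study, persisting
#' every intermediate under \code{out_dir} and returning (and writing) a
#' summary. Any stage failure halts with the stage name; artifacts written
#' so far are retained.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  study <- stage("simulate", simulate_study(config$synth))
  write_expression(study$profiles, file.path(out_dir, "expr.tsv"),
                   file.path(out_dir, "types.tsv"),
                   file.path(out_dir, "labels.tsv"))
  for (s in names(study$priors))
    write_pairs(study$priors[[s]], file.path(out_dir, paste0(s, ".tsv")))

  prof <- stage("preprocess",
                preprocess_profiles(study$profiles, config$preprocess_frac))
  write_expression(prof, file.path(out_dir, "expr.norm.tsv"))

  cand <- stage("priors", {
    cons <- consensus_pairs(study$priors, config$min_sources)
    assemble_candidates(mirna_pairs = cons, profiles = prof)
  })

  kept <- stage("corr_filter", {
    thr <- null_threshold(prof, n_pairs = max(1L, nrow(cand)),
                          n_reps = config$corr_reps, q = config$corr_q,
                          seed = config$seed + 10L)
    jsonlite::write_json(list(threshold = thr$threshold,
                              n_reps = thr$n_reps, quantile = thr$quantile),
                         file.path(out_dir, "corr_threshold.json"),
                         auto_unbox = TRUE, digits = NA)
    filter_pairs(cand, prof, thr)
  })
  write.table(kept, file.path(out_dir, "pairs.kept.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!nrow(kept)) stop("pipeline stage 'corr_filter' retained no pairs")

  nets <- stage("infer", {
    lapply(stats::setNames(PHENOTYPES, PHENOTYPES), function(st)
      infer_network(subset_phenotype(prof, st), kept,
                    weight_cutoff = config$weight_cutoff))
  })
  write_network(nets$NM, file.path(out_dir, "net_nm.tsv"))
  write_network(nets$M, file.path(out_dir, "net_m.tsv"))

  cmp <- stage("compare", {
    list(overview = lapply(nets, network_overview),
         categories = categorize(nets$NM, nets$M),
         target_increase = avg_target_increase(nets$NM, nets$M))
  })

  mods <- stage("modules", {
    filt <- differential_edge_filter(nets$NM, nets$M,
                                     config$edge_filter_frac)
    cand_mods <- rbind(extract_modules(filt$nm), extract_modules(filt$m))
    if (!nrow(cand_mods)) stop("no candidate modules (all out-degrees < 2)")
    rank_modules(cand_mods, prof, alpha = config$alpha,
                 n_perm = config$n_perm, seed = config$seed + 20L)
  })
  write.table(attr(mods, "all"), file.path(out_dir, "modules_all.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(mods), file.path(out_dir, "modules.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  clf <- NULL; best_k <- NULL
  if (nrow(mods)) {
    cls <- stage("classify", {
      scan <- cumulative_module_scan(prof, mods,
                                     k_max = min(config$k_max, nrow(mods)))
      write.table(scan, file.path(out_dir, "classifier_scan.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      k <- scan$k[which.max(scan$acc)]
      list(k = k, clf = module_loocv(prof, mods, k = k))
    })
    clf <- cls$clf
    best_k <- cls$k
  }

  enr <- NULL
  if (!is.null(config$gmt) && nrow(mods)) {
    enr <- stage("enrich", {
      sets <- read_gmt(config$gmt)
      universe <- rownames(prof$values)[prof$node_types == "gene"]
      modules_enrichment(mods, sets, universe)
    })
    write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    seed = config$seed,
    n_nodes = nrow(prof$values),
    n_samples = ncol(prof$values),
    n_candidate_pairs = nrow(cand),
    n_pairs_after_corr_filter = nrow(kept),
    network = lapply(cmp$overview, function(o)
      list(n_nodes = o$n_nodes, n_edges = o$n_edges,
           nodes_by_type = as.list(o$nodes_by_type),
           edges_by_type = as.list(o$edges_by_type))),
    edge_categories = as.list(cmp$categories$edge_counts),
    node_categories = as.list(cmp$categories$node_counts),
    n_modules_tested = nrow(attr(mods, "all")),
    n_modules_significant = nrow(mods),
    classifier = if (!is.null(clf))
      list(k = best_k, acc = clf$acc, mcc = clf$mcc,
           n_features = clf$n_features),
    n_enriched_rows = if (!is.null(enr)) nrow(enr))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(summary)
}
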