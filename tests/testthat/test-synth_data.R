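test_that("planted networks honor type rules, sharing and determinism", {
  cfg <- synth_config(n_tf = 4, n_mirna = 4, n_gene = 30, seed = 11L)
  pn <- generate_planted_network(cfg)
  all_edges <- rbind(pn$true_edges_NM, pn$true_edges_M)
  expect_true(all(all_edges$edge_type %in%
                    c("TF-TF", "TF-miRNA", "TF-gene", "miRNA-TF", "miRNA-gene")))
  expect_false(any(all_edges$regulator == all_edges$target))
  # miRNA effects are repressive, always negative
  mir <- all_edges[startsWith(all_edges$edge_type, "miRNA"), ]
  expect_true(all(mir$effect < 0))
  # shared edges carry identical effects
  key_nm <- paste(pn$true_edges_NM$regulator, pn$true_edges_NM$target)
  key_m <- paste(pn$true_edges_M$regulator, pn$true_edges_M$target)
  common <- intersect(key_nm, key_m)
  expect_equal(pn$true_edges_NM$effect[match(common, key_nm)],
               pn$true_edges_M$effect[match(common, key_m)])
  # every regulator has >= 2 targets in at least one condition
  regs <- names(pn$node_types)[pn$node_types != "gene"]
  deg <- function(e) table(factor(e$regulator, levels = regs))
  expect_true(all(pmax(deg(pn$true_edges_NM), deg(pn$true_edges_M)) >= 2))
  # determinism
  pn2 <- generate_planted_network(cfg)
  expect_identical(pn, pn2)
})

test_that("common_fraction = 1 makes the two condition networks identical", {
  cfg <- synth_config(n_tf = 3, n_mirna = 3, n_gene = 20,
                      common_fraction = 1, seed = 3L)
  pn <- generate_planted_network(cfg)
  expect_identical(pn$true_edges_NM, pn$true_edges_M)
})

test_that("n_mirna = 0 yields no miRNA-involved edges", {
  cfg <- synth_config(n_tf = 5, n_mirna = 0, n_gene = 20, seed = 2L)
  pn <- generate_planted_network(cfg)
  et <- c(pn$true_edges_NM$edge_type, pn$true_edges_M$edge_type)
  expect_false(any(grepl("miRNA", et)))
})

test_that("expression follows the linear model in the low-noise limit", {
  cfg <- synth_config(n_tf = 2, n_mirna = 2, n_gene = 10,
                      n_nm_samples = 100, n_m_samples = 100,
                      noise_sd = 1e-8, common_fraction = 1,
                      activity_shift = 0, seed = 5L)
  pn <- generate_planted_network(cfg)
  ep <- simulate_expression(pn, cfg)
  # single-parent targets correlate (+/-)1 with their regulator
  e <- pn$true_edges_NM
  single <- names(which(table(e$target) == 1))
  single <- setdiff(single, e$regulator)  # pure leaf targets
  for (tg in single[1:min(3, length(single))]) {
    row <- e[e$target == tg, ]
    expect_equal(abs(cor(ep$values[row$regulator, ], ep$values[tg, ])), 1,
                 tolerance = 1e-6)
  }
})

test_that("planted miRNA repression shows as negative in-condition Spearman", {
  cfg <- synth_config(n_tf = 2, n_mirna = 4, n_gene = 20,
                      n_nm_samples = 100, n_m_samples = 100,
                      noise_sd = 0.5, seed = 7L)
  pn <- generate_planted_network(cfg)
  ep <- simulate_expression(pn, cfg)
  nm_samples <- names(ep$labels)[ep$labels == "NM"]
  e <- pn$true_edges_NM
  mir <- e[e$edge_type == "miRNA-gene" & !(e$target %in% e$regulator), ]
  mir <- mir[table(e$target)[mir$target] == 1, ]  # single-parent targets
  expect_gt(nrow(mir), 0)
  rho <- vapply(seq_len(nrow(mir)), function(i)
    cor(ep$values[mir$regulator[i], nm_samples],
        ep$values[mir$target[i], nm_samples], method = "spearman"), 0)
  expect_true(all(rho < 0))
})

test_that("same config and seed reproduce the expression matrix exactly", {
  cfg <- synth_config(n_tf = 3, n_mirna = 3, n_gene = 15, seed = 9L)
  pn <- generate_planted_network(cfg)
  expect_identical(simulate_expression(pn, cfg)$values,
                   simulate_expression(pn, cfg)$values)
})

test_that("prior sources match truth at the sensitivity/fp-rate extremes", {
  cfg <- synth_config(n_tf = 3, n_mirna = 3, n_gene = 20,
                      prior_sensitivity = 1, prior_fp_rate = 0,
                      n_sources = 3, seed = 13L)
  pn <- generate_planted_network(cfg)
  pr <- generate_candidate_priors(pn, cfg)
  truth <- unique(rbind(pn$true_edges_NM[, 1:2], pn$true_edges_M[, 1:2]))
  truth <- truth[order(truth$regulator, truth$target), ]
  rownames(truth) <- NULL
  for (s in names(pr)) expect_identical(pr[[s]], truth)

  cfg0 <- synth_config(n_tf = 3, n_mirna = 3, n_gene = 20,
                       prior_sensitivity = 0, prior_fp_rate = 0.1,
                       n_sources = 2, seed = 13L)
  pn0 <- generate_planted_network(cfg0)
  pr0 <- generate_candidate_priors(pn0, cfg0)
  key_truth <- paste(truth$regulator, truth$target)
  for (s in names(pr0))
    expect_false(any(paste(pr0[[s]]$regulator, pr0[[s]]$target) %in% key_truth))
})

test_that("per-source prior sizes match the binomial expectation within 3 sd", {
  cfg <- synth_config(n_tf = 5, n_mirna = 5, n_gene = 60,
                      prior_sensitivity = 0.8, prior_fp_rate = 0.05,
                      n_sources = 4, seed = 17L)
  pn <- generate_planted_network(cfg)
  pr <- generate_candidate_priors(pn, cfg)
  truth <- unique(rbind(pn$true_edges_NM[, 1:2], pn$true_edges_M[, 1:2]))
  n_true <- nrow(truth)
  # legal pairs: TF -> anything else; miRNA -> TF or gene
  n_legal <- 5 * (69) + 5 * (5 + 60)
  n_false <- n_legal - n_true
  mu <- 0.8 * n_true + 0.05 * n_false
  sigma <- sqrt(0.8 * 0.2 * n_true + 0.05 * 0.95 * n_false)
  for (s in names(pr))
    expect_lt(abs(nrow(pr[[s]]) - mu), 3 * sigma)
})

test_that("label permutation leaves no systematic NM/M edge-count difference", {
  # exchangeable (equal-size) groups; with unequal sizes the larger group's
  # network is systematically denser, a sample-size artifact
  d <- vapply(1:10, function(s) {
    cfg <- synth_config(seed = s, n_gene = 100,
                        n_nm_samples = 40, n_m_samples = 40)
    study <- simulate_study(cfg)
    prof <- preprocess_profiles(study$profiles, 0.05)
    cand <- assemble_candidates(
      mirna_pairs = consensus_pairs(study$priors, 2), profiles = prof)
    kept <- filter_pairs(cand, prof,
                         null_threshold(prof, nrow(cand), seed = s + 10L))
    set.seed(s + 30L)
    perm <- prof
    perm$labels <- stats::setNames(sample(prof$labels), names(prof$labels))
    nets <- lapply(stats::setNames(c("NM", "M"), c("NM", "M")), function(st)
      infer_network(subset_phenotype(perm, st), kept))
    cc <- categorize(nets$NM, nets$M)
    cc$edge_counts[["NM_specific"]] - cc$edge_counts[["M_specific"]]
  }, 0)
  nz <- d[d != 0]
  pv <- stats::binom.test(sum(nz > 0), length(nz))$p.value
  expect_gt(pv, 0.01)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(n_gene = 0), "counts")
  expect_error(synth_config(prior_fp_rate = 1.5), "probabilities")
  expect_error(synth_config(noise_sd = 0), "positive")
})
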