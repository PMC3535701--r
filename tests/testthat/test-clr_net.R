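test_that("mutual information matches direct summation over the joint table", {
  # joint count table [[2,1],[1,2]] over 6 samples
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(0, 0, 1, 0, 1, 1)
  cfg <- mi_config(n_bins = 2)
  expect_equal(mutual_information(x, y, cfg),
               oracle_mi_table(matrix(c(2, 1, 1, 2), 2, byrow = TRUE)),
               tolerance = 1e-10)
  # independence of a constant
  expect_equal(mutual_information(rep(1, 6), y, cfg), 0)
  # I(X;X) = H(X) = 2 bits for 4 equally filled bins
  x4 <- c(0.1, 0.2, 1.1, 1.2, 2.1, 2.2, 3.1, 3.2)
  expect_equal(mutual_information(x4, x4, mi_config(n_bins = 4, log_base = "2")),
               2)
  # random tables against the oracle
  set.seed(5)
  for (rep in 1:5) {
    bx <- sample(1:3, 30, replace = TRUE)
    by <- sample(1:3, 30, replace = TRUE)
    expect_equal(mutual_information(as.numeric(bx), as.numeric(by),
                                    mi_config(n_bins = 3)),
                 max(0, oracle_mi_table(unname(table(bx, by)))),
                 tolerance = 1e-10)
  }
})

test_that("the all-pairs MI matrix agrees with the pairwise estimator", {
  set.seed(8)
  vals <- matrix(rnorm(6 * 40), 6, 40)
  rownames(vals) <- paste0("n", 1:6)
  cfg <- mi_config(n_bins = 5)
  mm <- mi_matrix(vals, cfg)
  expect_true(isSymmetric(unname(mm)))
  expect_true(all(mm >= 0))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(mm[i, j],
                 mutual_information(vals[i, ], vals[j, ], cfg),
                 tolerance = 1e-12)
})

test_that("MI with equal-frequency binning is invariant to monotone maps", {
  set.seed(9)
  x <- rnorm(60); y <- x + rnorm(60, 0, 0.5)
  cfg <- mi_config(n_bins = 5, binning = "equal_frequency")
  expect_equal(mutual_information(x, y, cfg),
               mutual_information(exp(x), y, cfg), tolerance = 1e-12)
  expect_equal(mutual_information(x, y, cfg),
               mutual_information(x, y^3 + 5 * y, cfg), tolerance = 1e-12)
})

test_that("CLR scores match the brute-force oracle on small matrices", {
  set.seed(10)
  for (n in c(4, 5, 6)) {
    mi <- matrix(0, n, n)
    mi[upper.tri(mi)] <- runif(n * (n - 1) / 2)
    mi <- mi + t(mi)
    rownames(mi) <- colnames(mi) <- paste0("n", seq_len(n))
    got <- clr_scores(mi)$z
    expect_equal(unname(got), oracle_clr(mi), tolerance = 1e-10)
    expect_true(isSymmetric(unname(got)))
  }
  # all-equal MI gives all-zero scores
  flat <- matrix(1, 4, 4)
  expect_true(all(clr_scores(flat)$z == 0))
})

test_that("a single inflated MI entry produces the hand-computed CLR score", {
  mi <- matrix(0.2, 4, 4)
  diag(mi) <- 0
  mi[1, 2] <- mi[2, 1] <- 0.9
  rownames(mi) <- colnames(mi) <- paste0("n", 1:4)
  off1 <- c(0.9, 0.2, 0.2)
  z1 <- (0.9 - mean(off1)) / sd(off1)
  expect_equal(clr_scores(mi)$z["n1", "n2"], sqrt(2) * z1, tolerance = 1e-12)
})

test_that("network inference respects the cutoff, direction and status", {
  cfg <- synth_config(n_tf = 3, n_mirna = 3, n_gene = 25,
                      n_nm_samples = 40, n_m_samples = 15, seed = 23L)
  study <- simulate_study(cfg)
  prof <- study$profiles
  cand <- assemble_candidates(mirna_pairs = consensus_pairs(study$priors, 1),
                              profiles = prof)
  sub <- subset_phenotype(prof, "NM")
  all_scored <- infer_network(sub, cand, weight_cutoff = 0)
  expect_identical(all_scored$status, "NM")
  # cutoff 0 keeps every candidate pair (scores are >= 0 by construction)
  expect_equal(nrow(all_scored$edges), nrow(cand))
  # +Inf cutoff empties the network
  none <- infer_network(sub, cand, weight_cutoff = Inf)
  expect_equal(nrow(none$edges), 0L)
  # default cutoff keeps the subset with weight >= 1
  net1 <- infer_network(sub, cand, weight_cutoff = 1)
  expect_true(all(net1$edges$weight >= 1))
  expect_true(all(paste(net1$edges$regulator, net1$edges$target) %in%
                  paste(cand$regulator, cand$target)))
  # direction comes from the prior orientation
  expect_true(all(prof$node_types[net1$edges$regulator] %in% c("TF", "miRNA")))
  # a node missing from the profiles is an upstream error
  bad <- candidate_pairs("TF1", "ghost", "TF-gene")
  expect_error(infer_network(sub, bad), "absent")
})

test_that("retained edges are enriched for planted in-condition edges", {
  cfg <- synth_config(seed = 31L, n_gene = 120)
  study <- simulate_study(cfg)
  prof <- preprocess_profiles(study$profiles, 0.05)
  cand <- assemble_candidates(mirna_pairs = consensus_pairs(study$priors, 2),
                              profiles = prof)
  kept <- filter_pairs(cand, prof,
                       null_threshold(prof, nrow(cand), seed = 41L))
  net <- infer_network(subset_phenotype(prof, "NM"), kept)
  truth <- paste(study$network$true_edges_NM$regulator,
                 study$network$true_edges_NM$target)
  in_net <- paste(net$edges$regulator, net$edges$target)
  cand_keys <- paste(cand$regulator, cand$target)
  rejected <- setdiff(cand_keys, in_net)
  tab <- matrix(c(sum(in_net %in% truth), sum(!(in_net %in% truth)),
                  sum(rejected %in% truth), sum(!(rejected %in% truth))),
                2, byrow = TRUE)
  expect_lt(stats::fisher.test(tab, alternative = "greater")$p.value, 0.01)
})
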