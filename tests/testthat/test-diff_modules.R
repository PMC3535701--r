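nt <- c(TF1 = "TF", miR1 = "miRNA",
        stats::setNames(rep("gene", 8), paste0("g", 1:8)))
mknet <- function(status, reg, tgt, w) {
  regulatory_network(status, data.frame(
    regulator = reg, target = tgt,
    edge_type = paste(nt[reg], nt[tgt], sep = "-"), weight = w), nt)
}

test_that("edge filter drops the lowest-difference fraction from both nets", {
  # 8 union edges with |w_NM - w_M| = 1..8; frac 0.25 removes the 2 smallest
  nm <- mknet("NM", rep("TF1", 8), paste0("g", 1:8), w = 10 + 1:8)
  m <- mknet("M", rep("TF1", 8), paste0("g", 1:8), w = rep(10, 8))
  out <- differential_edge_filter(nm, m, 0.25)
  expect_equal(nrow(out$nm$edges), 6L)
  expect_setequal(out$removed, c("TF1->g1", "TF1->g2"))
  expect_false(any(c("g1", "g2") %in% out$m$edges$target))
  # frac 0 is the identity
  id <- differential_edge_filter(nm, m, 0)
  expect_equal(nrow(id$nm$edges), 8L)
  # a missing edge counts as weight 0: its difference is the full weight
  nm2 <- mknet("NM", rep("TF1", 2), c("g1", "g2"), w = c(5, 6))
  m2 <- mknet("M", "TF1", "g1", w = 5)  # g1 diff 0; g2 absent: diff |6-0| = 6
  out2 <- differential_edge_filter(nm2, m2, 0.5)
  expect_identical(out2$removed, "TF1->g1")
  expect_identical(out2$nm$edges$target, "g2")
  # equal weights in both networks are removed first
  nmq <- mknet("NM", rep("TF1", 4), paste0("g", 1:4), w = c(2, 3, 4, 5))
  mq <- mknet("M", rep("TF1", 4), paste0("g", 1:4), w = c(2, 9, 9, 9))
  expect_identical(differential_edge_filter(nmq, mq, 0.25)$removed, "TF1->g1")
})

test_that("modules are regulators with more than one first-layer target", {
  net <- mknet("M", c("TF1", "TF1", "TF1", "miR1"),
               c("g1", "g2", "g3", "g4"), w = 2)
  mods <- extract_modules(net)
  expect_equal(nrow(mods), 1L)  # miR1 has a single target: no module
  expect_identical(mods$name, "TF1_M")
  expect_identical(mods$targets, "g1;g2;g3")
  expect_identical(module_members(mods)$TF1_M, c("TF1", "g1", "g2", "g3"))
  # miRNA ids get underscores; same regulator in both networks -> two modules
  nt3 <- c(`hsa-miR-16` = "miRNA", g1 = "gene", g2 = "gene")
  net3 <- regulatory_network("M", data.frame(
    regulator = "hsa-miR-16", target = c("g1", "g2"),
    edge_type = "miRNA-gene", weight = 1), nt3)
  expect_identical(extract_modules(net3)$name, "hsa_miR_16_M")
})

test_that("global ANCOVA reduces to the squared pooled t for one node", {
  set.seed(14)
  for (rep in 1:3) {
    y <- rep(c("NM", "M"), c(12, 8))
    v <- rnorm(20) + 0.8 * (y == "M")
    ep <- make_profiles(matrix(v, 1, 20), labels = stats::setNames(y, sprintf("s%02d", 1:20)))
    ga <- global_ancova(rownames(ep$values), ep, n_perm = 50L, seed = rep)
    tt <- stats::t.test(v[y == "M"], v[y == "NM"], var.equal = TRUE)
    expect_equal(ga$statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  }
})

test_that("global ANCOVA handles degenerate and invalid inputs", {
  ep <- make_profiles(matrix(5, 3, 10))
  res <- global_ancova(rownames(ep$values), ep, n_perm = 20L)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(global_ancova(character(), ep), "empty")
  expect_error(global_ancova("ghost", ep), "absent")
})

test_that("strong group separation yields the smallest permutation p", {
  set.seed(15)
  y <- rep(c("NM", "M"), c(15, 10))
  vals <- rbind(rnorm(25) + 3 * (y == "M"), rnorm(25) + 3 * (y == "M"))
  ep <- make_profiles(vals, labels = stats::setNames(y, sprintf("s%02d", 1:25)))
  res <- global_ancova(rownames(ep$values), ep, n_perm = 200L, seed = 6L)
  expect_equal(res$p_value, 1 / 201)
})

test_that("module ranking gates on adjusted p and sorts by raw p", {
  set.seed(16)
  y <- rep(c("NM", "M"), c(30, 20))
  n <- 9
  vals <- matrix(rnorm(n * 50), n, 50)
  vals[1:3, y == "M"] <- vals[1:3, y == "M"] + 3   # strong signal nodes
  rownames(vals) <- c(paste0("t", 1:3), paste0("x", 1:6))
  ep <- make_profiles(vals, labels = stats::setNames(y, sprintf("s%02d", 1:50)))
  mods <- data.frame(
    name = c("R1_M", "R2_M", "R3_NM"),
    regulator = c("t1", "t2", "x1"),
    status = c("M", "M", "NM"),
    targets = c("t2;t3", "t1;t3", "x2;x3"),
    n_targets = c(2L, 2L, 2L), stringsAsFactors = FALSE)
  sig <- rank_modules(mods, ep, alpha = 0.05, n_perm = 2000L, seed = 3L)
  all <- attr(sig, "all")
  expect_equal(nrow(all), 3L)
  expect_true(all(diff(all$p_raw) >= 0))
  expect_true(all(all$p_adj >= all$p_raw))
  expect_setequal(sig$name, c("R1_M", "R2_M"))
  expect_identical(sig$rank, seq_len(nrow(sig)))
  # the null module does not pass
  expect_false("R3_NM" %in% sig$name)
})
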