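test_that("trees separate separable data and degrade to stumps gracefully", {
  X <- matrix(c(rep(0, 10), rep(5, 10)), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- rep(c("NM", "M"), each = 10)
  tr <- fit_tree(X, y, tree_params(min_split = 4, min_leaf = 2))
  pred <- ifelse(predict_proba(tr, X) > 0.5, "M", "NM")
  expect_identical(pred, y)
  # constant response: stump with probability 1
  stump <- fit_tree(X, rep("M", 20))
  expect_equal(predict_proba(stump, X), rep(1, 20))
  stump_nm <- fit_tree(X, rep("NM", 20))
  expect_equal(predict_proba(stump_nm, X), rep(0, 20))
  expect_error(predict_proba(tr, matrix(0, 1, 1, dimnames = list(NULL, "zz"))),
               "missing feature")
})

test_that("leaf probabilities are training-class frequencies", {
  # one feature, one forced leaf of 3 M / 1 NM
  X <- matrix(c(1, 1.1, 1.2, 0.9, 5, 5.1, 5.2, 5.3), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c("M", "M", "M", "NM", "NM", "NM", "NM", "M")
  tr <- fit_tree(X, y, tree_params(min_split = 4, min_leaf = 2))
  pr <- predict_proba(tr, X)
  expect_equal(pr[1:4], rep(0.75, 4))
  expect_equal(pr[5:8], rep(0.25, 4))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("the first split matches exhaustive Gini enumeration", {
  set.seed(17)
  for (rep in 1:5) {
    X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
    y <- sample(rep(c("NM", "M"), each = 5))
    tr <- fit_tree(X, y, tree_params(min_split = 2, min_leaf = 1,
                                     complexity = 0, max_depth = 1))
    stopifnot(is.null(tr$constant))
    leaf <- tr$fit$where
    n <- length(y)
    dec <- gini_impurity(y) -
      sum(vapply(split(y, leaf), function(part)
        length(part) / n * gini_impurity(part), 0))
    expect_equal(dec, oracle_best_gini_decrease(X, y), tolerance = 1e-10)
  }
})

test_that("accuracy and MCC match the confusion-matrix formulas", {
  p <- c(a = "M", b = "NM", c = "M", d = "NM")
  expect_equal(acc_mcc(p, p), list(acc = 1, mcc = 1))
  inv <- c(a = "NM", b = "M", c = "NM", d = "M")
  expect_equal(acc_mcc(inv, p)$mcc, -1)
  # TP=45 TN=135 FP=15 FN=3 worked example
  truth <- rep(c("M", "NM"), c(48, 150))
  pred <- c(rep("M", 45), rep("NM", 3), rep("M", 15), rep("NM", 135))
  got <- acc_mcc(pred, truth)
  expect_equal(got$acc, 180 / 198)
  expect_equal(got$mcc,
               (45 * 135 - 15 * 3) / sqrt(60 * 48 * 150 * 138))
  # degenerate denominator -> 0
  expect_equal(acc_mcc(rep("M", 4), rep(c("M", "NM"), 2))$mcc, 0)
  # random vectors against a direct oracle
  set.seed(18)
  for (rep in 1:5) {
    tr <- sample(c("NM", "M"), 30, replace = TRUE)
    pr <- sample(c("NM", "M"), 30, replace = TRUE)
    tp <- sum(pr == "M" & tr == "M"); tn <- sum(pr == "NM" & tr == "NM")
    fp <- sum(pr == "M" & tr == "NM"); fn <- sum(pr == "NM" & tr == "M")
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    want <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(acc_mcc(pr, tr)$mcc, want, tolerance = 1e-12)
  }
})

sim_modular_profiles <- function(seed, n_nm = 30, n_m = 15) {
  set.seed(seed)
  y <- rep(c("NM", "M"), c(n_nm, n_m))
  n <- n_nm + n_m
  vals <- matrix(rnorm(12 * n), 12, n)
  vals[1:3, y == "M"] <- vals[1:3, y == "M"] + 2.5
  vals[4:6, y == "M"] <- vals[4:6, y == "M"] - 2
  rownames(vals) <- c(paste0("a", 1:3), paste0("b", 1:3), paste0("x", 1:6))
  make_profiles(vals, labels = stats::setNames(y, sprintf("s%02d", 1:n)))
}

two_modules <- data.frame(
  name = c("A_M", "B_M"), regulator = c("a1", "b1"),
  status = "M", targets = c("a2;a3", "b2;b3"),
  n_targets = 2L, stringsAsFactors = FALSE)

test_that("module LOOCV with k = 1 equals the single-module classifier", {
  ep <- sim_modular_profiles(19)
  r1 <- module_loocv(ep, two_modules, k = 1)
  expect_gt(r1$acc, 0.85)
  expect_equal(r1$n_features, 3L)
  rboth <- module_loocv(ep, two_modules, k = 2)
  expect_equal(rboth$n_features, 6L)
  expect_true(all(rboth$predicted %in% c("NM", "M")))
  expect_length(rboth$predicted, 45L)
})

test_that("the probability-sum voting rule predicts the larger total", {
  # two modules with P(M) 0.6 and 0.3: sum_M = 0.9 < sum_NM = 1.1 -> NM
  probs <- matrix(c(0.6, 0.3), 1, 2,
                  dimnames = list("s1", c("A_M", "B_M")))
  res <- comboreg:::cumulative_result(probs, c(s1 = "NM"), 2L,
                                      list(c("a"), c("b")))
  expect_identical(unname(res$predicted), "NM")
  expect_equal(unname(res$prob_M), 0.45)
  # exact tie also predicts the majority class NM
  tie <- matrix(c(0.8, 0.2), 1, 2, dimnames = list("s1", c("A_M", "B_M")))
  expect_identical(unname(comboreg:::cumulative_result(
    tie, c(s1 = "M"), 2L, list("a", "b"))$predicted), "NM")
})

test_that("each LOOCV fold is fitted without its held-out sample", {
  ep <- sim_modular_profiles(20, n_nm = 16, n_m = 10)
  probs <- comboreg:::loocv_module_probs(ep, two_modules)
  members <- module_members(two_modules)
  samples <- colnames(ep$values)
  for (s in samples[c(1, 10, 26)]) {
    for (j in 1:2) {
      f <- t(ep$values[members[[j]], , drop = FALSE])
      tr <- fit_tree(f[setdiff(samples, s), , drop = FALSE],
                     ep$labels[setdiff(samples, s)])
      expect_equal(probs[s, j], predict_proba(tr, f[s, , drop = FALSE]))
    }
  }
})

test_that("cumulative scan evaluates every prefix consistently", {
  ep <- sim_modular_profiles(21)
  scan <- cumulative_module_scan(ep, two_modules)
  expect_equal(scan$k, 1:2)
  r2 <- module_loocv(ep, two_modules, k = 2)
  expect_equal(scan$acc[2], r2$acc)
  expect_equal(scan$n_features, c(3L, 6L))
})

test_that("gene-list ranking gates by t-test and orders by mRMR", {
  set.seed(22)
  n <- 60
  y <- rep(c("NM", "M"), each = 30)
  informative <- rnorm(n) + 2.5 * (y == "M")
  vals <- rbind(a_inf = informative, b_dup = informative,  # exact duplicate
                c_noise = rnorm(n))
  ep <- make_profiles(vals, labels = stats::setNames(y, sprintf("s%02d", 1:n)))
  gl <- genelist_rank(ep, alpha = 1)
  expect_equal(nrow(gl), 3L)
  # greedy base case: first pick maximizes relevance (tie broken by id)
  expect_identical(gl$node[1], "a_inf")
  # redundancy penalty: noise precedes the duplicate
  expect_identical(gl$node[2], "c_noise")
  expect_identical(gl$node[3], "b_dup")
  # BH gate at 0.05 keeps only the informative pair
  expect_setequal(genelist_rank(ep, alpha = 0.05)$node, c("a_inf", "b_dup"))
  # alpha = 1 passes everything to the ranking
  ep_null <- make_profiles(matrix(rnorm(5 * 40), 5, 40))
  expect_equal(nrow(genelist_rank(ep_null, alpha = 1)), 5L)
  expect_equal(nrow(genelist_rank(ep_null, alpha = 1e-6)), 0L)
})

test_that("gene-list LOOCV classifies a perfectly separating gene", {
  y <- rep(c("NM", "M"), each = 15)
  vals <- matrix(rnorm(2 * 30), 2, 30)
  vals[1, ] <- ifelse(y == "M", 5, 0) + rnorm(30, 0, 0.1)
  rownames(vals) <- c("sep", "junk")
  ep <- make_profiles(vals, labels = stats::setNames(y, sprintf("s%02d", 1:30)))
  res <- genelist_loocv(ep, c("sep", "junk"), n_genes = 1,
                        tree_params(min_split = 4, min_leaf = 2))
  expect_equal(res$acc, 1)
  expect_equal(res$n_features, 1L)
  expect_error(genelist_loocv(ep, "sep", n_genes = 2), "n_genes")
})

test_that("ranking AUROC matches the rank-sum definition", {
  expect_equal(ranking_auroc(c(3, 2, 1), c(TRUE, FALSE, FALSE)), 1)
  expect_equal(ranking_auroc(c(1, 2, 3), c(TRUE, FALSE, FALSE)), 0)
  expect_equal(ranking_auroc(c(1, 1), c(TRUE, FALSE)), 0.5)
  expect_true(is.na(ranking_auroc(1:3, rep(TRUE, 3))))
})
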