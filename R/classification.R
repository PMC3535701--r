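# Recursive-partitioning classifiers over module features; single-module and
# cumulative-module LOOCV with ACC/MCC; t-test + MRMR gene-list counterpart.

#' Recursive-partitioning (CART) parameters
#'
#' Defaults mirror the documented defaults of the rpart implementation the
#' classification model is built on: Gini impurity, minsplit 20,
#' minbucket 7, complexity 0.01, maxdepth 30.
#'
#' @param min_split minimum node size to attempt a split.
#' @param min_leaf minimum terminal-node size.
#' @param complexity complexity parameter (cp).
#' @param max_depth maximum tree depth.
#' @return list of class \code{TreeParams}.
#' @export
tree_params <- function(min_split = 20L, min_leaf = 7L, complexity = 0.01,
                        max_depth = 30L) {
  if (min_leaf > min_split) stop("min_leaf must be <= min_split")
  if (complexity < 0) stop("complexity must be >= 0")
  structure(list(min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf),
                 complexity = complexity, max_depth = as.integer(max_depth)),
            class = "TreeParams")
}

#' Fit a CART decision tree on a sample-by-feature matrix
#'
#' Binary Gini-impurity tree via \code{rpart}; deterministic given inputs.
#' A single-class response yields a degenerate stump predicting that class
#' with probability 1.
#'
#' @param X numeric matrix, samples x features (column names = feature ids).
#' @param y character/factor vector of labels ("NM"/"M") aligned to rows.
#' @param params a \code{\link{tree_params}}.
#' @return object of class \code{comboreg_tree}.
#' @export
fit_tree <- function(X, y, params = tree_params()) {
  y <- as.character(y)
  features <- colnames(X)
  if (length(unique(y)) < 2L) {
    return(structure(list(constant = y[1L], features = features),
                     class = "comboreg_tree"))
  }
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_along(features))  # syntactic feature names
  df$.y <- factor(y, levels = PHENOTYPES)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minsplit = params$min_split,
                        minbucket = params$min_leaf,
                        cp = params$complexity,
                        maxdepth = params$max_depth,
                        xval = 0L))
  structure(list(fit = fit, features = features), class = "comboreg_tree")
}

#' Predicted probability of the metastatic class
#'
#' Returns the fitted leaf's training-class frequency for "M" for each row
#' of the feature matrix.
#'
#' @param tree a \code{comboreg_tree}.
#' @param X numeric matrix with the same feature columns used at fit time.
#' @return numeric vector of P(M) per row.
#' @export
predict_proba <- function(tree, X) {
  stopifnot(inherits(tree, "comboreg_tree"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L,
                                   dimnames = list(NULL, tree$features))
  missing <- setdiff(tree$features, colnames(X))
  if (length(missing)) stop("missing feature(s): ",
                            paste(head(missing, 5), collapse = ", "))
  if (!is.null(tree$constant))
    return(rep(as.numeric(tree$constant == "M"), nrow(X)))
  df <- as.data.frame(X[, tree$features, drop = FALSE])
  names(df) <- paste0("f", seq_along(tree$features))
  pr <- predict(tree$fit, newdata = df, type = "prob")
  unname(pr[, "M"])
}

#' Accuracy and Matthews correlation coefficient
#'
#' \code{acc = (TP + TN)/n}; \code{mcc = (TP*TN - FP*FN) /
#' sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}, defined as 0 when any factor of the
#' denominator is 0. "M" is the positive class.
#'
#' @param predicted,truth character vectors of "NM"/"M" with matching names
#'   (or equal order).
#' @return list with \code{acc} and \code{mcc}.
#' @export
acc_mcc <- function(predicted, truth) {
  if (!is.null(names(predicted)) && !is.null(names(truth)))
    truth <- truth[names(predicted)]
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted == "M" & truth == "M")
  tn <- sum(predicted == "NM" & truth == "NM")
  fp <- sum(predicted == "M" & truth == "NM")
  fn <- sum(predicted == "NM" & truth == "M")
  acc <- (tp + tn) / length(truth)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(acc = acc, mcc = mcc)
}

module_feature_matrix <- function(profiles, nodes) {
  t(profiles$values[nodes, , drop = FALSE])
}

#' Cumulative-module classifier evaluated by leave-one-out cross-validation
#'
#' For each held-out sample, one CART tree is fitted per module (features =
#' expression of the module's regulator and targets) on the remaining
#' samples; the per-class probabilities are summed over the top-k modules
#' and the class with the larger overall probability is predicted. A tie
#' predicts "NM" (the majority class convention).
#'
#' @param profiles \code{ExpressionProfiles}.
#' @param modules ranked module data.frame (see \code{\link{rank_modules}}).
#' @param k number of top modules to accumulate (default: all rows).
#' @param params \code{\link{tree_params}}.
#' @return list of class \code{ClassifierResult}: \code{predicted},
#'   \code{prob_M} (summed P(M) / k), \code{acc}, \code{mcc},
#'   \code{n_features} (distinct member nodes across the k modules).
#' @export
module_loocv <- function(profiles, modules, k = nrow(modules),
                         params = tree_params()) {
  stopifnot(inherits(profiles, "ExpressionProfiles"))
  if (k < 1L || k > nrow(modules)) stop("k must lie in 1..nrow(modules)")
  modules <- modules[seq_len(k), , drop = FALSE]
  probs <- loocv_module_probs(profiles, modules, params)
  cumulative_result(probs, profiles$labels, k,
                    module_members(modules))
}

# held-out P(M) per sample (rows) and module (columns): one tree per module
# per LOOCV fold, fitted without the held-out sample
loocv_module_probs <- function(profiles, modules, params = tree_params()) {
  members <- module_members(modules)
  feats <- lapply(members, function(nd) module_feature_matrix(profiles, nd))
  samples <- colnames(profiles$values)
  truth <- profiles$labels
  probs <- matrix(NA_real_, length(samples), length(feats),
                  dimnames = list(samples, modules$name))
  for (s in samples) {
    train <- setdiff(samples, s)
    for (j in seq_along(feats)) {
      f <- feats[[j]]
      tree <- fit_tree(f[train, , drop = FALSE], truth[train], params)
      probs[s, j] <- predict_proba(tree, f[s, , drop = FALSE])
    }
  }
  probs
}

cumulative_result <- function(probs, truth, k, members) {
  sum_m <- rowSums(probs[, seq_len(k), drop = FALSE])
  predicted <- ifelse(sum_m > k - sum_m, "M", "NM")  # tie -> NM
  names(predicted) <- rownames(probs)
  perf <- acc_mcc(predicted, truth)
  structure(list(predicted = predicted,
                 prob_M = stats::setNames(sum_m / k, rownames(probs)),
                 acc = perf$acc, mcc = perf$mcc,
                 n_features = length(unique(unlist(members[seq_len(k)])))),
            class = "ClassifierResult")
}

#' Cumulative-module classifier scan
#'
#' Evaluates the cumulative classifier for every prefix k = 1..k_max of the
#' ranked module list under a single set of LOOCV folds (the per-module
#' trees do not depend on k, so they are fitted once). This reproduces the
#' module-accumulation procedure used to choose the final classifier size:
#' modules are added one at a time from the top of the ranked list and the
#' performance curve is inspected for its peak.
#'
#' @param profiles \code{ExpressionProfiles}.
#' @param modules ranked module data.frame.
#' @param k_max largest prefix evaluated (default: all modules).
#' @param params \code{\link{tree_params}}.
#' @return data.frame with one row per k: \code{k}, \code{acc}, \code{mcc},
#'   \code{n_features}.
#' @export
cumulative_module_scan <- function(profiles, modules, k_max = nrow(modules),
                                   params = tree_params()) {
  stopifnot(inherits(profiles, "ExpressionProfiles"))
  if (k_max < 1L || k_max > nrow(modules))
    stop("k_max must lie in 1..nrow(modules)")
  modules <- modules[seq_len(k_max), , drop = FALSE]
  probs <- loocv_module_probs(profiles, modules, params)
  members <- module_members(modules)
  res <- lapply(seq_len(k_max), function(k)
    cumulative_result(probs, profiles$labels, k, members))
  data.frame(k = seq_len(k_max),
             acc = vapply(res, `[[`, 0, "acc"),
             mcc = vapply(res, `[[`, 0, "mcc"),
             n_features = vapply(res, `[[`, 0L, "n_features"))
}

#' @export
print.ClassifierResult <- function(x, ...) {
  cat(sprintf("ClassifierResult: ACC %.3f, MCC %.3f (%d features, %d samples)\n",
              x$acc, x$mcc, x$n_features, length(x$predicted)))
  invisible(x)
}

pooled_t_stats <- function(X, y) {
  # two-sided pooled-variance t per row of X
  g1 <- X[, y == "M", drop = FALSE]; g2 <- X[, y == "NM", drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2); v2 <- rowSums((g2 - m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(abs(tt), df = n1 + n2 - 2, lower.tail = FALSE)
  p[sp2 == 0 & m1 == m2] <- 1
  list(t = tt, p = p)
}

#' Differential-expression gene list ranked by mRMR
#'
#' Per-node two-sided pooled-variance (Student) t-test of M vs NM, BH
#' adjustment, survivors with adjusted p < \code{alpha} ranked greedily by
#' minimum-redundancy-maximum-relevance (MID form): the first pick
#' maximizes MI relevance to the label; each subsequent pick maximizes
#' relevance minus mean MI redundancy with the already-selected features.
#' MI uses the same discretization as the network MI estimator. Ties break
#' by node id.
#'
#' @param profiles \code{ExpressionProfiles}.
#' @param alpha BH-adjusted p-value gate (default 0.001).
#' @param cfg \code{\link{mi_config}} for the MI terms.
#' @return data.frame (node, t, p_raw, p_adj, relevance, rank) in selection
#'   order; zero rows when nothing survives the gate.
#' @export
genelist_rank <- function(profiles, alpha = 0.001, cfg = mi_config()) {
  stopifnot(inherits(profiles, "ExpressionProfiles"))
  y <- profiles$labels
  if (length(unique(y)) != 2L) stop("both phenotype labels must be present")
  ts <- pooled_t_stats(profiles$values, y)
  p_adj <- p.adjust(ts$p, method = "BH")
  keep <- which(p_adj < alpha)
  if (!length(keep))
    return(data.frame(node = character(), t = numeric(), p_raw = numeric(),
                      p_adj = numeric(), relevance = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  ids <- rownames(profiles$values)[keep]
  nb <- resolve_bins(cfg, ncol(profiles$values))
  disc <- lapply(ids, function(i)
    discretize(profiles$values[i, ], nb, cfg$binning))
  names(disc) <- ids
  lab <- factor(y, levels = PHENOTYPES)
  relevance <- vapply(disc, function(d) mutual_information(d, lab, cfg), 0)
  # order candidates by id for deterministic tie-breaks via which.max
  ord <- order(ids)
  ids <- ids[ord]; relevance <- relevance[ord]; disc <- disc[ord]
  selected <- character(0)
  remaining <- ids
  red_sum <- stats::setNames(numeric(length(ids)), ids)
  while (length(remaining)) {
    if (!length(selected)) {
      score <- relevance[remaining]
    } else {
      score <- relevance[remaining] - red_sum[remaining] / length(selected)
    }
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      red_sum[remaining] <- red_sum[remaining] + vapply(
        remaining, function(r) mutual_information(disc[[r]], disc[[pick]], cfg), 0)
  }
  out <- data.frame(node = selected, stringsAsFactors = FALSE)
  out$t <- ts$t[match(selected, rownames(profiles$values))]
  out$p_raw <- ts$p[match(selected, rownames(profiles$values))]
  out$p_adj <- p_adj[match(selected, rownames(profiles$values))]
  out$relevance <- relevance[selected]
  out$rank <- seq_len(nrow(out))
  out
}

#' Gene-list classifier evaluated by leave-one-out cross-validation
#'
#' A single CART tree over the top-n ranked genes, the gene-list
#' counterpart of the cumulative-module classifier.
#'
#' @param profiles \code{ExpressionProfiles}.
#' @param ranked_genes character vector of node ids in rank order (or the
#'   data.frame from \code{\link{genelist_rank}}).
#' @param n_genes how many genes from the top of the list to use.
#' @param params \code{\link{tree_params}}.
#' @return \code{ClassifierResult}.
#' @export
genelist_loocv <- function(profiles, ranked_genes, n_genes,
                           params = tree_params()) {
  if (is.data.frame(ranked_genes)) ranked_genes <- ranked_genes$node
  if (n_genes < 1L || n_genes > length(ranked_genes))
    stop("n_genes must lie in 1..length(ranked_genes)")
  nodes <- ranked_genes[seq_len(n_genes)]
  f <- module_feature_matrix(profiles, nodes)
  samples <- colnames(profiles$values)
  truth <- profiles$labels
  prob_m <- stats::setNames(numeric(length(samples)), samples)
  predicted <- stats::setNames(character(length(samples)), samples)
  for (s in samples) {
    train <- setdiff(samples, s)
    tree <- fit_tree(f[train, , drop = FALSE], truth[train], params)
    pm <- predict_proba(tree, f[s, , drop = FALSE])
    prob_m[s] <- pm
    predicted[s] <- if (pm > 0.5) "M" else "NM"
  }
  perf <- acc_mcc(predicted, truth)
  structure(list(predicted = predicted, prob_M = prob_m,
                 acc = perf$acc, mcc = perf$mcc, n_features = length(nodes)),
            class = "ClassifierResult")
}

#' Ranking AUROC of scores against binary truth
#'
#' Rank-sum (Wilcoxon) estimate of the probability that a random positive
#' outscores a random negative; ties contribute 1/2.
#'
#' @param scores numeric vector.
#' @param positive logical vector, same length.
#' @return AUROC in [0, 1]; \code{NA} if either class is empty.
#' @export
ranking_auroc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}
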