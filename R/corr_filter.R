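# Spearman-correlation pruning of candidate pairs against an empirical null
# built from randomly sampled node pairs.

# rank rows then center/scale, so that pairwise Spearman correlations reduce
# to inner products of rows
rank_standardize <- function(values) {
  r <- t(apply(values, 1L, rank))  # average-rank tie handling
  ctr <- r - rowMeans(r)
  ss <- sqrt(rowSums(ctr^2))
  ok <- ss > 0
  ctr[ok, ] <- ctr[ok, , drop = FALSE] / ss[ok]
  ctr[!ok, ] <- 0  # constant rows: correlation defined as 0
  ctr
}

#' Absolute Spearman correlation of two sample vectors
#'
#' Rank correlation with average-rank tie handling, returned as an absolute
#' value in [0, 1]. A constant vector yields 0 with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return absolute Spearman correlation.
#' @export
spearman_abs <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: absolute Spearman correlation defined as 0")
    return(0)
  }
  abs(cor(x, y, method = "spearman"))
}

#' Empirical null threshold for absolute Spearman correlation
#'
#' Draws \code{n_reps} independent samples of \code{n_pairs} distinct
#' non-self node pairs, pools all \code{n_reps * n_pairs} absolute Spearman
#' correlations, and returns the empirical \code{q}-quantile of the pool.
#' When \code{n_pairs} exceeds the number of available distinct pairs the
#' draw within each repetition is exhaustive (and pairs recur across
#' repetitions).
#'
#' @param profiles an \code{ExpressionProfiles} (>= 2 nodes).
#' @param n_pairs pairs per repetition (the study used the size of the
#'   candidate pair set).
#' @param n_reps number of repetitions (default 100).
#' @param q quantile of the pooled null (default 0.95).
#' @param seed integer seed.
#' @return list of class \code{NullThreshold} with \code{threshold},
#'   \code{n_reps}, \code{quantile}, \code{pooled_null_size}, \code{seed}.
#' @export
null_threshold <- function(profiles, n_pairs, n_reps = 100L, q = 0.95,
                           seed = 1L) {
  stopifnot(inherits(profiles, "ExpressionProfiles"))
  n <- nrow(profiles$values)
  if (n < 2L) stop("need at least 2 nodes")
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  set.seed(as.integer(seed))
  rs <- rank_standardize(profiles$values)
  n_avail <- n * (n - 1L) / 2
  k <- min(n_pairs, n_avail)
  pool <- numeric(0)
  for (rep in seq_len(n_reps)) {
    # sample distinct unordered non-self pairs by linear index
    idx <- sample(n_avail, k)
    # invert linear index over the strictly-lower triangle
    i <- floor((1 + sqrt(8 * (idx - 1) + 1)) / 2) + 1
    j <- idx - (i - 1) * (i - 2) / 2
    pool <- c(pool, abs(rowSums(rs[i, , drop = FALSE] * rs[j, , drop = FALSE])))
  }
  structure(list(threshold = unname(quantile(pool, q)),
                 n_reps = n_reps, quantile = q,
                 pooled_null_size = length(pool), seed = as.integer(seed)),
            class = "NullThreshold")
}

#' Absolute Spearman correlation for each candidate pair
#'
#' @param pairs \code{CandidatePairSet} (or data.frame with regulator/target).
#' @param profiles \code{ExpressionProfiles} containing all pair nodes.
#' @return numeric vector aligned to the rows of \code{pairs}.
#' @export
pair_correlations <- function(pairs, profiles) {
  if (!nrow(pairs)) return(numeric(0))
  missing <- setdiff(union(pairs$regulator, pairs$target),
                     rownames(profiles$values))
  if (length(missing)) stop("pair node(s) absent from profiles: ",
                            paste(head(missing, 5), collapse = ", "))
  rs <- rank_standardize(profiles$values)
  abs(rowSums(rs[pairs$regulator, , drop = FALSE] *
              rs[pairs$target, , drop = FALSE]))
}

#' Filter candidate pairs by the empirical null threshold
#'
#' Retains pairs whose absolute Spearman correlation is strictly greater
#' than the null threshold ("higher than" the null quantile); provenance and
#' edge types are preserved.
#'
#' @param pairs a \code{CandidatePairSet}.
#' @param profiles an \code{ExpressionProfiles}.
#' @param t a \code{\link{null_threshold}} result (or a bare number).
#' @return filtered \code{CandidatePairSet}.
#' @export
filter_pairs <- function(pairs, profiles, t) {
  thr <- if (inherits(t, "NullThreshold")) t$threshold else as.numeric(t)
  if (!nrow(pairs)) return(pairs)
  rho <- pair_correlations(pairs, profiles)
  out <- pairs[rho > thr, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("CandidatePairSet", "data.frame")
  out
}
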