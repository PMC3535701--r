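# Mutual-information estimation and Context Likelihood of Relatedness (CLR)
# scoring; constructs one phenotype's directed, typed, weighted network from
# the candidate pair set.

#' Mutual-information estimator configuration
#'
#' @param n_bins number of discretization bins, or \code{"auto"} for
#'   \code{floor(sqrt(n_samples))}.
#' @param binning \code{"equal_width"} or \code{"equal_frequency"}.
#' @param log_base \code{"natural"} (nats) or \code{"2"} (bits).
#' @return list of class \code{MIEstimatorConfig}.
#' @export
mi_config <- function(n_bins = "auto",
                      binning = c("equal_width", "equal_frequency"),
                      log_base = c("natural", "2")) {
  binning <- match.arg(binning)
  log_base <- match.arg(log_base)
  if (!identical(n_bins, "auto")) {
    n_bins <- as.integer(n_bins)
    if (n_bins < 2L) stop("n_bins must be >= 2")
  }
  structure(list(n_bins = n_bins, binning = binning, log_base = log_base),
            class = "MIEstimatorConfig")
}

resolve_bins <- function(cfg, n_samples) {
  if (identical(cfg$n_bins, "auto")) max(2L, floor(sqrt(n_samples))) else cfg$n_bins
}

#' Discretize a continuous vector into bins
#'
#' Equal-width binning splits the observed range into \code{n_bins} equal
#' intervals; equal-frequency binning uses empirical quantile breakpoints
#' (ties may merge bins). A constant vector maps to a single bin. Factors
#' and character vectors are passed through as their level codes.
#'
#' @param x numeric vector (or factor/character, returned as level codes).
#' @param n_bins number of bins.
#' @param binning \code{"equal_width"} or \code{"equal_frequency"}.
#' @return integer vector of bin codes in \code{1..n_bins}.
#' @export
discretize <- function(x, n_bins, binning = "equal_width") {
  if (is.factor(x) || is.character(x)) return(as.integer(factor(x)))
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(1L, length(x)))
  if (binning == "equal_width") {
    breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  } else {
    breaks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
    if (length(breaks) < 2L) return(rep(1L, length(x)))
  }
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Mutual information of two sample vectors
#'
#' Discretizes both vectors per the estimator configuration and computes
#' \eqn{I(X;Y) = \sum_{i,j} p(x_i, y_j) \log [ p(x_i, y_j) / (p(x_i) p(y_j)) ]}
#' with the convention \eqn{0 \log 0 = 0}. A constant vector yields 0.
#'
#' @param x,y equal-length vectors (numeric, or factor/character treated as
#'   already-discrete).
#' @param cfg an \code{\link{mi_config}}.
#' @return non-negative mutual information (nats by default).
#' @export
mutual_information <- function(x, y, cfg = mi_config()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  nb <- resolve_bins(cfg, length(x))
  if (is.numeric(x) && length(x) < nb)
    stop("need at least n_bins (", nb, ") observations")
  bx <- discretize(x, nb, cfg$binning)
  by <- discretize(y, nb, cfg$binning)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  expected <- outer(px, py)
  mi <- sum(joint[nz] * log(joint[nz] / expected[nz]))
  if (cfg$log_base == "2") mi <- mi / log(2)
  max(mi, 0)
}

#' All-pairs mutual-information matrix over profile rows
#'
#' @param values numeric matrix (nodes x samples).
#' @param cfg an \code{\link{mi_config}}.
#' @return symmetric non-negative matrix of MI values (diagonal 0), with
#'   dimnames from the rows of \code{values}.
#' @export
mi_matrix <- function(values, cfg = mi_config()) {
  nb <- resolve_bins(cfg, ncol(values))
  disc <- t(apply(values, 1L, discretize, n_bins = nb, binning = cfg$binning))
  storage.mode(disc) <- "integer"
  out <- .mi_matrix_cpp(disc, nb)
  if (cfg$log_base == "2") out <- out / log(2)
  dimnames(out) <- list(rownames(values), rownames(values))
  out
}

#' CLR scores from a mutual-information matrix
#'
#' For each node \eqn{i}, let \eqn{\mu_i} and \eqn{\sigma_i} be the mean and
#' standard deviation of its off-diagonal MI values (its MI background);
#' \eqn{z_i(j) = \max(0, (MI_{ij} - \mu_i)/\sigma_i)} and the CLR score is
#' \eqn{\sqrt{z_i(j)^2 + z_j(i)^2}}. A degenerate row (\eqn{\sigma_i = 0})
#' contributes zero z-scores.
#'
#' @param mi square symmetric non-negative matrix.
#' @return list of class \code{CLRMatrix} with \code{nodes}, \code{mi} and
#'   the symmetric score matrix \code{z}.
#' @export
clr_scores <- function(mi) {
  n <- nrow(mi)
  if (n != ncol(mi)) stop("MI matrix must be square")
  if (n < 2L) stop("need at least 2 nodes")
  off <- mi
  diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sig <- apply(off, 1L, sd, na.rm = TRUE)
  sig[is.na(sig)] <- 0
  z <- (mi - mu) / ifelse(sig > 0, sig, Inf)
  z[z < 0] <- 0
  diag(z) <- 0
  score <- sqrt(z^2 + t(z)^2)
  dimnames(score) <- dimnames(mi)
  structure(list(nodes = rownames(mi), mi = mi, z = score),
            class = "CLRMatrix")
}

#' Restrict expression profiles to one phenotype's samples
#'
#' @param profiles an \code{ExpressionProfiles}.
#' @param status \code{"NM"} or \code{"M"}.
#' @return \code{ExpressionProfiles} containing only that phenotype's samples.
#' @export
subset_phenotype <- function(profiles, status) {
  status <- match.arg(status, PHENOTYPES)
  keep <- names(profiles$labels)[profiles$labels == status]
  if (!length(keep)) stop("no samples with label ", status)
  expression_profiles(profiles$values[, keep, drop = FALSE],
                      profiles$node_types, profiles$labels[keep])
}

#' Infer one phenotype's regulatory network by prior-constrained CLR
#'
#' Computes the full MI and CLR matrices over all nodes appearing in the
#' candidate pair set (the CLR background uses the whole candidate node set,
#' not just each pair's endpoints), then creates the directed edge
#' regulator -> target with weight equal to the CLR score for every
#' candidate pair whose score reaches \code{weight_cutoff} (ties at the
#' cutoff are kept: only edges strictly below it are removed). Direction
#' comes solely from the prior pair's orientation; CLR itself is undirected.
#'
#' @param profiles_subset \code{ExpressionProfiles} restricted to one
#'   phenotype (see \code{\link{subset_phenotype}}).
#' @param pairs a non-empty \code{CandidatePairSet}.
#' @param cfg an \code{\link{mi_config}}.
#' @param weight_cutoff minimum retained CLR score (default 1).
#' @return A \code{\link{regulatory_network}} with the subset's phenotype.
#' @export
infer_network <- function(profiles_subset, pairs, cfg = mi_config(),
                          weight_cutoff = 1.0) {
  stopifnot(inherits(profiles_subset, "ExpressionProfiles"))
  if (!nrow(pairs)) stop("candidate pair set is empty")
  status <- unique(profiles_subset$labels)
  if (length(status) != 1L)
    stop("profiles_subset must contain samples of a single phenotype")
  if (ncol(profiles_subset$values) < 10L)
    warning("fewer than 10 samples for phenotype ", status)
  nodes <- sort(union(pairs$regulator, pairs$target))
  missing <- setdiff(nodes, rownames(profiles_subset$values))
  if (length(missing))
    stop("candidate node(s) absent from profiles: ",
         paste(head(missing, 5), collapse = ", "))
  mim <- mi_matrix(profiles_subset$values[nodes, , drop = FALSE], cfg)
  clr <- clr_scores(mim)
  w <- clr$z[cbind(pairs$regulator, pairs$target)]
  keep <- w >= weight_cutoff
  edges <- data.frame(regulator = pairs$regulator[keep],
                      target = pairs$target[keep],
                      edge_type = pairs$edge_type[keep],
                      weight = w[keep], stringsAsFactors = FALSE)
  regulatory_network(status, edges, profiles_subset$node_types)
}
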