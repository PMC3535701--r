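# Expression preprocessing: quantile normalization across samples and
# removal of the least-variable rows.

#' Quantile-normalize an expression matrix across samples
#'
#' Forces every column (sample) to share the same empirical distribution:
#' the reference distribution is the row-wise mean of the per-column sorted
#' values. Delegates to \code{limma::normalizeQuantiles} (with
#' \code{ties = TRUE}, so tied values within a column receive the reference
#' value at their mean tied rank). Row and column order are preserved.
#'
#' @param values numeric matrix (nodes x samples), no missing values.
#' @return matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(values) {
  if (anyNA(values)) stop("missing values not allowed")
  if (ncol(values) < 2L) {
    warning("single-sample matrix returned unchanged")
    return(values)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Remove the least-variable rows of an expression profile
#'
#' Drops exactly \code{floor(frac * n_rows)} rows with the smallest sample
#' standard deviation; ties are broken by node id (lexicographic) so the
#' result is deterministic.
#'
#' @param profiles an \code{ExpressionProfiles}.
#' @param frac fraction of rows to remove, in [0, 1).
#' @return filtered \code{ExpressionProfiles}.
#' @export
variance_filter <- function(profiles, frac = 0.05) {
  stopifnot(inherits(profiles, "ExpressionProfiles"))
  if (!is.numeric(frac) || frac < 0 || frac >= 1)
    stop("'frac' must lie in [0, 1)")
  n_drop <- floor(frac * nrow(profiles$values))
  if (n_drop == 0L) return(profiles)
  sds <- apply(profiles$values, 1L, sd)
  ord <- order(sds, rownames(profiles$values))
  drop_ids <- rownames(profiles$values)[ord[seq_len(n_drop)]]
  keep <- setdiff(rownames(profiles$values), drop_ids)
  expression_profiles(profiles$values[keep, , drop = FALSE],
                      profiles$node_types[keep], profiles$labels)
}

#' Quantile-normalize then variance-filter an expression profile
#'
#' Convenience wrapper applying \code{\link{quantile_normalize}} followed by
#' \code{\link{variance_filter}}.
#'
#' @inheritParams variance_filter
#' @return preprocessed \code{ExpressionProfiles}.
#' @export
preprocess_profiles <- function(profiles, frac = 0.05) {
  stopifnot(inherits(profiles, "ExpressionProfiles"))
  norm <- expression_profiles(quantile_normalize(profiles$values),
                              profiles$node_types, profiles$labels)
  variance_filter(norm, frac)
}
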