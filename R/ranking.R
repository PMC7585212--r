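#' Rank transformation with averaged ties
#'
#' Replaces each entry of \code{x} by its rank, assigning tied values the
#' average of the ranks they span: \eqn{\Phi(x)_i = |S_i| + (|E_i|+1)/2}
#' where \eqn{S_i} counts entries strictly below \eqn{x_i} and \eqn{E_i}
#' counts entries equal to it.  This is the tie-averaging rank used in
#' non-parametric statistics (and by \code{\link[base]{rank}} with
#' \code{ties.method = "average"}).
#'
#' @param x numeric vector, length at least 1.
#' @return numeric vector of ranks; the ranks always sum to \eqn{n(n+1)/2}.
#' @examples
#' rank_vector(c(17, 17, 4, 308, 17))  # 3 3 1 5 3
#' @export
rank_vector <- function(x) {
  if (length(x) == 0L) stop("rank_vector: empty input")
  if (anyNA(x)) stop("rank_vector: missing values not allowed")
  rank(x, ties.method = "average")
}

#' Rank-transform and standardize a count matrix column-wise
#'
#' Each gene column is rank-transformed, then centered and scaled to unit
#' population standard deviation (divide by \eqn{n}, not \eqn{n-1}).  Genes
#' that are constant across all cells have zero rank variance; they carry no
#' class information and are dropped, with their indices recorded.
#'
#' @param X cells x genes matrix of nonnegative counts (dense matrix or a
#'   \code{Matrix} sparse matrix); at least 2 rows.
#' @return an object of class \code{"ranked_matrix"}: a list with
#'   \code{values} (n x p' standardized rank matrix), \code{kept_genes}
#'   (column indices retained), \code{dropped_genes} (constant columns) and
#'   \code{gene_ids} (names of kept columns, if the input had any).
#' @export
rank_and_standardize <- function(X) {
  X <- as_count_matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("rank_and_standardize: need at least 2 cells")
  R <- apply(X, 2L, rank, ties.method = "average")
  mu <- colMeans(R)
  sd_pop <- sqrt(colMeans(R * R) - mu^2)
  keep <- sd_pop > 0
  if (!any(keep)) stop("no informative genes: all genes are constant across cells")
  V <- sweep(R[, keep, drop = FALSE], 2L, mu[keep], `-`)
  V <- sweep(V, 2L, sd_pop[keep], `/`)
  structure(list(values = V,
                 kept_genes = which(keep),
                 dropped_genes = which(!keep),
                 gene_ids = colnames(X)[keep]),
            class = "ranked_matrix")
}

#' Rank and center a +/-1 cluster indicator
#'
#' Returns \eqn{\bar\tau = \Phi(\tau) - \mu(\Phi(\tau))}: the ranked and
#' centered indicator used in place of \eqn{\tau} so that the correlation
#' vector becomes (proportional to) the per-gene Spearman correlation with
#' cluster membership.  The result sums to zero and takes exactly two values,
#' positive where \eqn{\tau = +1}.
#'
#' @param tau vector of +1/-1 with at least one of each sign.
#' @return centered rank vector of the same length.
#' @export
center_ranked_indicator <- function(tau) {
  if (!all(tau %in% c(-1, 1))) stop("tau must contain only +1 and -1")
  if (length(unique(tau)) < 2L) stop("tau must contain both classes")
  r <- rank(tau, ties.method = "average")
  r - mean(r)
}

#' Library-size and log normalization
#'
#' Scales each cell (row) so its total count equals \code{target_sum}, then
#' applies \code{log2(1 + x)}.  Cells with zero total are passed through
#' unchanged (filtering empty cells is the caller's responsibility).  Used
#' only in the evaluation layer; marker selection itself operates on raw
#' counts via the rank transform.
#'
#' @param X cells x genes nonnegative matrix.
#' @param target_sum row total after scaling (default 10000).
#' @param log_base base of the logarithm (default 2).
#' @return dense numeric matrix of the same dimensions.
#' @export
log_normalize <- function(X, target_sum = 10000, log_base = 2) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("log_normalize: negative entries")
  rs <- rowSums(X)
  scale <- ifelse(rs > 0, target_sum / rs, 1)
  Y <- X * scale
  log1p(Y) / log(log_base)
}

# Coerce count input (dense, sparse Matrix, data.frame) to a dense base
# matrix, validating nonnegativity.
as_count_matrix <- function(X) {
  if (inherits(X, "Matrix")) X <- as.matrix(X)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) stop("counts must be a matrix (cells x genes)")
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("counts contain missing values")
  if (any(X < 0)) stop("counts must be nonnegative")
  X
}
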