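#' Cluster indicator vector
#'
#' +1 where the label equals \code{k}, -1 elsewhere.
#'
#' @param y vector of cluster labels.
#' @param k one of the labels present in \code{y}.
#' @return numeric vector of +/-1, same length as \code{y}.
#' @export
cluster_indicator <- function(y, k) {
  if (!k %in% y) stop("cluster_indicator: class ", k, " not present in y")
  ifelse(y == k, 1, -1)
}

#' Binary (one cluster vs rest) rank-based marker selection
#'
#' The binary core: rank-transform and standardize the counts, rank and
#' center the indicator, form the correlation vector (proportional to the
#' per-gene Spearman correlation with \code{tau}), and solve the constrained
#' hyperplane problem with \code{\link{select_support}}.
#'
#' @param X cells x genes count matrix.
#' @param tau +/-1 indicator with both signs present.
#' @param s sparsity parameter (>= 1).
#' @param Xbar optional precomputed \code{\link{rank_and_standardize}} result
#'   (shared across clusters by \code{\link{rankcorr}}).
#' @return a \code{"select_solution"} augmented with \code{genes} (selected
#'   original gene indices, ordered by decreasing \eqn{|\hat\omega|}, ties by
#'   index), \code{gene_ids} (their names, if present) and
#'   \code{coefficients} (matching \eqn{\hat\omega} entries).
#' @export
rank_bin <- function(X, tau, s, Xbar = NULL) {
  if (is.null(Xbar)) Xbar <- rank_and_standardize(X)
  tau_bar <- center_ranked_indicator(tau)
  v <- correlation_vector(Xbar, tau_bar)
  sol <- select_support(v, s)
  ord <- sol$support[order(-abs(sol$omega_hat[sol$support]), sol$support)]
  sol$genes <- Xbar$kept_genes[ord]
  sol$gene_ids <- if (!is.null(Xbar$gene_ids)) Xbar$gene_ids[ord] else
    as.character(sol$genes)
  sol$coefficients <- unname(sol$omega_hat[ord])
  sol
}

#' Rank-based marker selection for a clustering (one-vs-all)
#'
#' Fits the sparse separating-hyperplane marker model: for each cluster k the
#' counts are rank-transformed (once, shared across clusters), the
#' correlation vector with the ranked indicator for k-vs-rest is
#' soft-thresholded at the exact threshold placing the normalized solution on
#' the l1 sphere of radius \eqn{\sqrt{s}}, and the nonzero coefficients are
#' that cluster's markers.  Different clusters typically yield different
#' numbers of markers at the same \code{s}; the union over clusters is the
#' marker set for the whole clustering.
#'
#' @param X cells x genes nonnegative count matrix (dense or sparse); no
#'   prior normalization is needed (or wanted) — the rank transform absorbs
#'   library-size differences in a nonparametric way.
#' @param y per-cell cluster labels (>= 2 distinct values).
#' @param s sparsity parameter, >= 1; larger s selects more markers per
#'   cluster.  Default 2.
#' @param keep_data keep the training counts/labels in the fit so that
#'   \code{predict} can build its nearest-centroid model (default TRUE).
#' @return an object of class \code{"rankcorr"} with components
#'   \code{per_cluster} (named list of per-cluster solutions, see
#'   \code{\link{rank_bin}}), \code{union} (deduplicated marker ids, ordered
#'   by first-seen cluster then gene index), \code{s}, \code{classes},
#'   \code{n_markers_per_cluster}, \code{gene_ids}, and the matrix
#'   dimensions.
#' @seealso \code{\link{predict.rankcorr}}, \code{\link{spearman_scores}}
#' @examples
#' set.seed(1)
#' X <- matrix(rpois(300, 2), 30, 10,
#'             dimnames = list(NULL, paste0("g", 1:10)))
#' X[1:15, 1] <- X[1:15, 1] + 10          # gene g1 marks cluster "a"
#' y <- rep(c("a", "b"), each = 15)
#' fit <- rankcorr(X, y, s = 1.2)
#' markers(fit)
#' @export
rankcorr <- function(X, y, s = 2, keep_data = TRUE) {
  X <- as_count_matrix(X)
  if (length(y) != nrow(X)) stop("rankcorr: length(y) must equal nrow(X)")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("rankcorr: need at least 2 clusters")
  Xbar <- rank_and_standardize(X)
  per_cluster <- lapply(classes, function(k)
    rank_bin(X, cluster_indicator(y, k), s, Xbar = Xbar))
  names(per_cluster) <- as.character(classes)
  ids <- unlist(lapply(per_cluster, `[[`, "gene_ids"), use.names = FALSE)
  fit <- structure(list(per_cluster = per_cluster,
                        union = unique(ids),
                        s = s,
                        classes = classes,
                        n_markers_per_cluster =
                          vapply(per_cluster, function(z) length(z$genes),
                                 integer(1)),
                        gene_ids = colnames(X),
                        n_cells = nrow(X), n_genes = ncol(X),
                        call = match.call()),
                   class = "rankcorr")
  if (keep_data) { fit$X <- X; fit$y <- y }
  fit
}

#' Extract marker gene lists from a fit
#'
#' @param object a \code{"rankcorr"} fit.
#' @param cluster a cluster label, or NULL for the deduplicated union.
#' @return character vector of gene ids (per-cluster lists are ordered by
#'   decreasing coefficient magnitude).
#' @export
markers <- function(object, cluster = NULL) {
  stopifnot(inherits(object, "rankcorr"))
  if (is.null(cluster)) return(object$union)
  k <- as.character(cluster)
  if (!k %in% names(object$per_cluster)) stop("unknown cluster: ", cluster)
  object$per_cluster[[k]]$gene_ids
}

#' @export
print.rankcorr <- function(x, ...) {
  cat("Rank-based marker selection (one-vs-all sparse hyperplanes)\n")
  cat(sprintf("  %d cells, %d genes, %d clusters, s = %g\n",
              x$n_cells, x$n_genes, length(x$classes), x$s))
  cat("  markers per cluster:",
      paste(sprintf("%s=%d", names(x$n_markers_per_cluster),
                    x$n_markers_per_cluster), collapse = ", "), "\n")
  cat(sprintf("  union: %d unique markers\n", length(x$union)))
  invisible(x)
}

#' @export
summary.rankcorr <- function(object, ...) {
  tab <- data.frame(
    cluster = names(object$per_cluster),
    n_markers = object$n_markers_per_cluster,
    beta_star = vapply(object$per_cluster, `[[`, numeric(1), "beta_star"),
    constraint_active = vapply(object$per_cluster, `[[`, logical(1),
                               "constraint_active"),
    top_marker = vapply(object$per_cluster,
                        function(z) z$gene_ids[1L], character(1)),
    row.names = NULL)
  structure(list(table = tab, s = object$s,
                 n_union = length(object$union)), class = "summary.rankcorr")
}

#' @export
print.summary.rankcorr <- function(x, ...) {
  cat(sprintf("Per-cluster marker summary (s = %g, union = %d genes)\n",
              x$s, x$n_union))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Coefficient matrix of a fit
#'
#' @param object a \code{"rankcorr"} fit.
#' @param ... unused.
#' @return genes x clusters matrix of hyperplane coefficients
#'   \eqn{\hat\omega} (zero off the supports); rows are all genes of the
#'   training matrix.
#' @export
coef.rankcorr <- function(object, ...) {
  p <- object$n_genes
  ids <- if (!is.null(object$gene_ids)) object$gene_ids else
    as.character(seq_len(p))
  W <- matrix(0, p, length(object$classes),
              dimnames = list(ids, names(object$per_cluster)))
  for (k in names(object$per_cluster)) {
    z <- object$per_cluster[[k]]
    W[match(z$gene_ids, ids), k] <- z$coefficients
  }
  W
}

#' Classify cells with a fitted marker model
#'
#' Trains the nearest-centroid classifier on the stored training data in the
#' log-normalized space of the fit's marker union, then assigns each new
#' cell to the class of the nearest centroid (Euclidean distance, ties to
#' the lowest class id).
#'
#' @param object a \code{"rankcorr"} fit created with \code{keep_data = TRUE}.
#' @param newdata cells x genes count matrix with the same genes as the
#'   training data; defaults to the training matrix.
#' @param ... unused.
#' @return vector of predicted cluster labels.
#' @export
predict.rankcorr <- function(object, newdata = NULL, ...) {
  if (is.null(object$X)) stop("fit was created with keep_data = FALSE")
  model <- train_ncc(object$X, object$y, object$union)
  predict_ncc(model, if (is.null(newdata)) object$X else newdata)
}

#' Plot per-cluster marker coefficients
#'
#' Horizontal barplot of the top marker coefficients for each cluster.
#'
#' @param x a \code{"rankcorr"} fit.
#' @param n_top markers shown per cluster (default 10).
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.rankcorr <- function(x, n_top = 10, ...) {
  K <- length(x$per_cluster)
  op <- graphics::par(mfrow = c(1, K), mar = c(4, 6, 2, 1))
  on.exit(graphics::par(op))
  for (k in names(x$per_cluster)) {
    z <- x$per_cluster[[k]]
    m <- seq_len(min(n_top, length(z$coefficients)))
    graphics::barplot(rev(z$coefficients[m]), names.arg = rev(z$gene_ids[m]),
                      horiz = TRUE, las = 1, main = paste("cluster", k),
                      xlab = "coefficient", ...)
  }
  invisible(x)
}

#' Absolute per-gene Spearman scores for each cluster
#'
#' For every cluster k, \code{score[j]} is the absolute Spearman rank
#' correlation between gene j and the k-vs-rest indicator.  Within a
#' cluster, the fit's marker list equals the top genes by this score, so
#' these are the method's implicit gene rankings.  Constant genes score 0.
#'
#' @param X cells x genes count matrix.
#' @param y cluster labels (>= 2 classes).
#' @return named list (one numeric vector of length p per class).
#' @export
spearman_scores <- function(X, y) {
  X <- as_count_matrix(X)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("spearman_scores: need at least 2 clusters")
  n <- nrow(X)
  Xbar <- rank_and_standardize(X)
  out <- lapply(classes, function(k) {
    tau <- cluster_indicator(y, k)
    tau_bar <- center_ranked_indicator(tau)
    sd_tau <- sqrt(mean(tau_bar^2))
    sc <- numeric(ncol(X))
    sc[Xbar$kept_genes] <-
      abs(correlation_vector(Xbar, tau_bar)) / (n * sd_tau)
    names(sc) <- colnames(X)
    sc
  })
  names(out) <- as.character(classes)
  out
}

#' Pairwise gene preference for a cluster
#'
#' Returns whichever of two genes has the larger absolute Spearman
#' correlation with the indicator \code{tau} (ties broken toward the lower
#' gene index), i.e. the gene the method would admit as a marker first.
#'
#' @param X cells x genes count matrix.
#' @param tau +/-1 indicator.
#' @param j,k gene column indices.
#' @return the preferred gene index (\code{j} or \code{k}).
#' @export
prefer_gene <- function(X, tau, j, k) {
  X <- as_count_matrix(X)
  score <- function(g) {
    x <- X[, g]
    if (length(unique(x)) < 2L) return(0)
    abs(stats::cor(rank(x), rank(tau)))
  }
  sj <- score(j); sk <- score(k)
  if (sj > sk) j else if (sk > sj) k else min(j, k)
}

#' Merge per-cluster score lists with an equal per-cluster quota
#'
#' Takes the top \code{m} genes of each cluster's score vector (ties broken
#' toward the lower gene index; a cluster offering fewer than \code{m}
#' scored genes contributes all of them) and returns the deduplicated union
#' in first-seen order.  This is the merging rule used to build whole-
#' clustering marker sets from methods that only score genes per cluster.
#'
#' @param scores list of per-cluster numeric score vectors (larger =
#'   better); names, if present, are the gene ids.
#' @param m markers requested per cluster.
#' @return vector of gene ids (names when available, else indices).
#' @export
equal_per_cluster_merge <- function(scores, m) {
  if (m < 1) stop("equal_per_cluster_merge: m must be >= 1")
  picked <- lapply(scores, function(sc) {
    keep <- which(!is.na(sc))
    keep <- keep[order(-sc[keep], keep)]
    top <- keep[seq_len(min(m, length(keep)))]
    if (!is.null(names(sc))) names(sc)[top] else top
  })
  unique(unlist(picked, use.names = FALSE))
}
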