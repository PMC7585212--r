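#' Random fold assignment for cross-validation
#'
#' Partitions \code{n} cells into \code{K} folds of as-equal-as-possible
#' size (sizes differ by at most one), uniformly at random.
#'
#' @param n number of cells.
#' @param K number of folds (default 5).
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of fold ids in \code{1..K}, length \code{n}.
#' @export
make_folds <- function(n, K = 5, seed = NULL) {
  if (n < K) stop("make_folds: n must be at least K")
  if (!is.null(seed)) set.seed(seed)
  sample(rep_len(seq_len(K), n))
}

#' Train the nearest-centroid classifier on marker genes
#'
#' Log-normalizes the training counts (library size 10000, log2(1+x)),
#' restricts to the marker genes, and stores one centroid (the mean of that
#' class's normalized rows) per training class.
#'
#' @param X_train cells x genes count matrix with gene column names.
#' @param y_train per-cell class labels; every class needs >= 1 cell.
#' @param markers gene ids (must all be columns of \code{X_train}).
#' @return object of class \code{"ncc_model"}: centroid matrix
#'   (classes x markers), marker ids, class labels.
#' @export
train_ncc <- function(X_train, y_train, markers) {
  X_train <- as_count_matrix(X_train)
  idx <- resolve_genes(markers, colnames(X_train), ncol(X_train))
  L <- log_normalize(X_train)[, idx, drop = FALSE]
  classes <- sort(unique(y_train))
  centroids <- t(vapply(classes,
                        function(k) colMeans(L[y_train == k, , drop = FALSE]),
                        numeric(ncol(L))))
  rownames(centroids) <- as.character(classes)
  structure(list(centroids = centroids, markers = markers, classes = classes),
            class = "ncc_model")
}

#' Classify cells by nearest centroid
#'
#' Each test cell is log-normalized the same way as in training, restricted
#' to the model's markers, and assigned the class of the Euclidean-nearest
#' centroid; ties go to the lowest class id.
#'
#' @param model an \code{"ncc_model"} from \code{\link{train_ncc}}.
#' @param X_test cells x genes count matrix containing all marker genes.
#' @return vector of predicted class labels (same type as training labels).
#' @export
predict_ncc <- function(model, X_test) {
  X_test <- as_count_matrix(X_test)
  idx <- resolve_genes(model$markers, colnames(X_test), ncol(X_test))
  L <- log_normalize(X_test)[, idx, drop = FALSE]
  C <- model$centroids
  # squared distances via ||x||^2 - 2 x.c + ||c||^2; ties -> first (lowest) class
  d2 <- outer(rowSums(L^2), rowSums(C^2), `+`) - 2 * tcrossprod(L, C)
  model$classes[apply(d2, 1L, which.min)]
}

resolve_genes <- function(markers, ids, p) {
  if (is.character(markers)) {
    if (is.null(ids)) stop("marker ids given but the matrix has no gene names")
    idx <- match(markers, ids)
  } else idx <- as.integer(markers)
  if (anyNA(idx) || any(idx < 1 | idx > p))
    stop("marker gene(s) absent from the count matrix")
  idx
}

#' Multi-class classification metrics
#'
#' Computes the classification error (1 - accuracy), the class-size-weighted
#' average of per-class precisions (a class never predicted contributes
#' precision 0), and the multi-class Matthews correlation coefficient
#' (Gorodkin's R_K, computed from the full confusion matrix; 0 when either
#' marginal is degenerate).
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return named list: \code{error}, \code{weighted_precision}, \code{mcc}.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("classification_metrics: empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  lev <- sort(unique(c(y_true, y_pred)))
  t_ <- factor(y_true, levels = lev); p_ <- factor(y_pred, levels = lev)
  C <- table(t_, p_)
  n <- length(y_true)
  correct <- sum(diag(C))
  pred_tot <- colSums(C); true_tot <- rowSums(C)
  prec <- ifelse(pred_tot > 0, diag(C) / pred_tot, 0)
  # Gorodkin R_K
  num <- correct * n - sum(true_tot * pred_tot)
  den <- sqrt((n^2 - sum(pred_tot^2)) * (n^2 - sum(true_tot^2)))
  list(error = 1 - correct / n,
       weighted_precision = sum(true_tot / n * prec),
       mcc = if (den > 0) num / den else 0)
}

#' Partition-agreement metrics
#'
#' Adjusted Rand index, adjusted mutual information (natural-log MI, the
#' hypergeometric-model expected MI, and the arithmetic mean of the two
#' entropies as normalizer) and the Fowlkes-Mallows score, all from the
#' pairwise contingency table.  The two labelings may use different label
#' vocabularies and different numbers of clusters; all three metrics equal 1
#' for identical partitions and ARI/AMI are approximately 0 for independent
#' random labelings.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return named list: \code{ari}, \code{ami}, \code{fms}.
#' @export
clustering_metrics <- function(labels_a, labels_b) {
  n <- length(labels_a)
  if (n == 0L) stop("clustering_metrics: empty input")
  if (length(labels_b) != n) stop("length mismatch")
  C <- table(labels_a, labels_b)
  a <- rowSums(C); b <- colSums(C)
  sum_ij <- sum(choose(C, 2)); sum_a <- sum(choose(a, 2)); sum_b <- sum(choose(b, 2))
  # ARI
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == exp_idx) 1 else (sum_ij - exp_idx) / (max_idx - exp_idx)
  # FMS
  fms <- if (sum_a > 0 && sum_b > 0) sum_ij / sqrt(sum_a * sum_b) else 0
  # AMI
  nz <- C > 0
  mi <- sum((C[nz] / n) * log(C[nz] * n / outer(a, b)[nz]))
  h_a <- -sum((a[a > 0] / n) * log(a[a > 0] / n))
  h_b <- -sum((b[b > 0] / n) * log(b[b > 0] / n))
  emi <- expected_mi(a, b, n)
  den <- (h_a + h_b) / 2 - emi
  ami <- if (abs(den) < 1e-12) 1 else (mi - emi) / den
  list(ari = ari, ami = ami, fms = fms)
}

# Expected mutual information under the hypergeometric permutation model.
expected_mi <- function(a, b, n) {
  emi <- 0
  lfn <- lfactorial(n)
  for (ai in a) {
    for (bj in b) {
      lo <- max(ai + bj - n, 1L); hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      term <- (nij / n) * log(n * nij / (ai * bj))
      lp <- lfactorial(ai) + lfactorial(bj) + lfactorial(n - ai) +
        lfactorial(n - bj) - lfn - lfactorial(nij) - lfactorial(ai - nij) -
        lfactorial(bj - nij) - lfactorial(n - ai - bj + nij)
      emi <- emi + sum(term * exp(lp))
    }
  }
  emi
}

#' Louvain clustering over a resolution grid in marker space
#'
#' Log-normalizes the counts, restricts to the marker genes, builds a
#' k-nearest-neighbour graph directly in marker space (no PCA or other
#' dimensionality reduction — the markers are already the informative
#' coordinates), runs community detection at each resolution on the grid,
#' and reports, for each agreement metric separately, the best value over
#' the grid.
#'
#' @param X cells x genes count matrix.
#' @param markers gene ids to restrict to.
#' @param ground_truth per-cell reference labels.
#' @param k_neighbors neighbours for the kNN graph (must be < n).
#' @param resolutions resolution grid (default 0.1 to 3.0 by 0.1).
#' @param cluster_fun community-detection callable
#'   \code{function(graph, resolution) -> membership vector}; defaults to
#'   igraph's Louvain implementation.
#' @return list: \code{best} (max of ari/ami/fms over the grid),
#'   \code{by_resolution} (data.frame of all grid values).
#' @export
louvain_grid_cluster <- function(X, markers, ground_truth, k_neighbors = 15,
                                 resolutions = seq(0.1, 3.0, by = 0.1),
                                 cluster_fun = igraph_louvain) {
  X <- as_count_matrix(X)
  n <- nrow(X)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of cells")
  idx <- resolve_genes(markers, colnames(X), ncol(X))
  L <- log_normalize(X)[, idx, drop = FALSE]
  g <- knn_graph(L, k_neighbors)
  rows <- lapply(resolutions, function(r) {
    m <- clustering_metrics(ground_truth, cluster_fun(g, r))
    data.frame(resolution = r, ari = m$ari, ami = m$ami, fms = m$fms)
  })
  tab <- do.call(rbind, rows)
  list(best = list(ari = max(tab$ari), ami = max(tab$ami), fms = max(tab$fms)),
       by_resolution = tab)
}

igraph_louvain <- function(graph, resolution) {
  igraph::membership(igraph::cluster_louvain(graph, resolution = resolution))
}

knn_graph <- function(L, k) {
  n <- nrow(L)
  d2 <- outer(rowSums(L^2), rowSums(L^2), `+`) - 2 * tcrossprod(L)
  diag(d2) <- Inf
  nb <- apply(d2, 1L, function(d) order(d)[seq_len(k)])
  edges <- rbind(rep(seq_len(n), each = k), as.vector(nb))
  igraph::simplify(igraph::graph_from_edgelist(t(edges), directed = FALSE))
}

#' Cross-validated evaluation of a marker selector
#'
#' Runs the 5-fold protocol: for each fold, markers are selected and the
#' nearest-centroid classifier is trained on the remaining folds only, then
#' applied to the held-out fold.  Classification metrics are computed once
#' on the concatenated whole-dataset predictions; clustering metrics (when
#' \code{louvain} is supplied) are computed on each held-out fold against
#' the reference labels restricted to it and averaged across folds, since
#' per-fold clusterings need not be compatible.
#'
#' @param X cells x genes count matrix.
#' @param y reference cluster labels.
#' @param selector \code{function(X_train, y_train, size) -> gene ids}.
#' @param sizes marker-count requests passed to the selector.
#' @param K folds (default 5).
#' @param seed fold-assignment seed.
#' @param method name recorded in the report (default "selector").
#' @param louvain NULL to skip clustering, or a list of arguments for
#'   \code{\link{louvain_grid_cluster}} (\code{k_neighbors},
#'   \code{resolutions}, \code{cluster_fun}; all optional).
#' @return object of class \code{"evaluation_report"}: \code{points} — long
#'   data.frame (method, n_markers_requested, n_markers_unique, fold,
#'   metric, value; classification rows have fold NA), \code{aggregates} —
#'   per-(method, size, metric) means across folds.
#' @export
cross_validated_evaluation <- function(X, y, selector, sizes, K = 5,
                                       seed = NULL, method = "selector",
                                       louvain = NULL) {
  X <- as_count_matrix(X)
  folds <- make_folds(nrow(X), K, seed)
  for (f in seq_len(K))
    if (!all(y %in% y[folds != f]))
      stop("class absent from the training split of fold ", f)
  rows <- list()
  for (size in sizes) {
    preds <- rep(y[1L], length(y))
    n_uni <- integer(K)
    for (f in seq_len(K)) {
      tr <- folds != f
      mk <- selector(X[tr, , drop = FALSE], y[tr], size)
      n_uni[f] <- length(unique(mk))
      model <- train_ncc(X[tr, , drop = FALSE], y[tr], mk)
      preds[!tr] <- predict_ncc(model, X[!tr, , drop = FALSE])
      if (!is.null(louvain)) {
        lv <- do.call(louvain_grid_cluster,
                      c(list(X = X[!tr, , drop = FALSE], markers = mk,
                             ground_truth = y[!tr]), louvain))
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, n_markers_requested = size,
          n_markers_unique = n_uni[f], fold = f,
          metric = c("ari", "ami", "fms"),
          value = unlist(lv$best, use.names = FALSE))
      }
    }
    cm <- classification_metrics(y, preds)
    rows[[length(rows) + 1L]] <- data.frame(
      method = method, n_markers_requested = size,
      n_markers_unique = round(mean(n_uni)), fold = NA_integer_,
      metric = names(cm), value = unlist(cm, use.names = FALSE))
  }
  points <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ method + n_markers_requested + metric,
                          data = points, FUN = mean)
  structure(list(points = points, aggregates = agg, K = K, seed = seed),
            class = "evaluation_report")
}

#' Average-of-Medians scores and method ranks
#'
#' For each method and each marker-count range, the AoM score is the mean
#' over the family's metrics of the median metric value at the evaluated
#' points whose requested marker count falls in the range (points only — no
#' interpolation between them).  Error-type metrics are converted to scores
#' (1 - error) first, so larger is uniformly better.  Ranks are then
#' assigned per range, 1 = best, ties sharing the minimum rank.
#'
#' @param report an \code{"evaluation_report"} (reports for several methods
#'   can be combined by \code{rbind}-ing their \code{aggregates}, or pass a
#'   data.frame with columns method, n_markers_requested, metric, value).
#' @param ranges list of 2-vectors \code{c(a, b)}: inclusive marker ranges.
#' @param metrics metric names forming the family (e.g.
#'   \code{c("error","weighted_precision","mcc")} or
#'   \code{c("ari","ami","fms")}).
#' @param error_metrics metric names to flip via 1 - value (default
#'   \code{"error"}).
#' @return data.frame: method, range, aom, rank.
#' @export
aom_rank <- function(report, ranges, metrics,
                     error_metrics = "error") {
  agg <- if (inherits(report, "evaluation_report")) report$aggregates else report
  agg <- agg[agg$metric %in% metrics, , drop = FALSE]
  agg$value[agg$metric %in% error_metrics] <-
    1 - agg$value[agg$metric %in% error_metrics]
  out <- list()
  for (rg in ranges) {
    lab <- paste0("[", rg[1L], ",", rg[2L], "]")
    inr <- agg[agg$n_markers_requested >= rg[1L] &
               agg$n_markers_requested <= rg[2L], , drop = FALSE]
    for (m in unique(agg$method)) {
      sub <- inr[inr$method == m, , drop = FALSE]
      if (nrow(sub) == 0L)
        stop("aom_rank: method '", m, "' has no points in range ", lab)
      med <- vapply(metrics, function(mt) {
        vals <- sub$value[sub$metric == mt]
        if (!length(vals)) stop("aom_rank: method '", m,
                                "' has no values of metric '", mt,
                                "' in range ", lab)
        stats::median(vals)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(method = m, range = lab,
                                            aom = mean(med))
    }
  }
  res <- do.call(rbind, out)
  res$rank <- stats::ave(-res$aom, res$range,
                         FUN = function(z) rank(z, ties.method = "min"))
  res
}

#' Serialize an evaluation report
#'
#' Writes the per-point metrics as a tidy long-format TSV and, when AoM
#' results are supplied, a JSON summary of scores and ranks.
#'
#' @param report an \code{"evaluation_report"}.
#' @param out_dir output directory (created if missing).
#' @param aom optional result of \code{\link{aom_rank}}.
#' @return invisibly, the paths written.
#' @export
write_evaluation <- function(report, out_dir, aom = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, "evaluation_points.tsv")
  utils::write.table(report$points, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(aom)) {
    p2 <- file.path(out_dir, "aom.json")
    jsonlite::write_json(aom, p2, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
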