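#' Configuration for the two-group UMI count simulator
#'
#' Defaults describe a droplet-style UMI experiment: gamma-distributed base
#' gene means, lognormal library-size variation, negative-binomial
#' (gamma-Poisson) counts, and a fixed fraction of genes carrying
#' multiplicative differential-expression factors drawn from a lognormal
#' with location 0.1 and scale 0.4 whose direction (factor f vs 1/f) is
#' random — the Splat two-group design, without added dropout.  The base
#' mean/library-size defaults are set so that roughly 85-90 percent of the
#' count entries are zero, the sparsity typical of droplet UMI data.
#'
#' @param n_cells number of cells (default 5000).
#' @param n_genes number of genes (default 5000).
#' @param de_fraction fraction of genes differentially expressed in group 1
#'   (default 0.10); exactly \code{round(de_fraction * n_genes)} genes are
#'   flagged.
#' @param de_location,de_scale lognormal meanlog/sdlog of the DE factor
#'   (defaults 0.1 and 0.4).
#' @param de_up_prob probability that a DE gene is up-regulated in group 1
#'   (the factor f is applied as drawn); otherwise the reciprocal 1/f is
#'   applied.  Default 0.5, the Splat convention of random direction.
#' @param mean_shape,mean_scale gamma parameters of the base gene means
#'   (defaults 0.3 and 1).
#' @param mean_min lower floor applied to base means (default 0, no floor);
#'   raise it to keep every gene's expression bounded away from zero.
#' @param dispersion negative-binomial dispersion (1/size; default 0.5).
#' @param lib_loc,lib_scale lognormal meanlog/sdlog of per-cell library
#'   sizes (defaults log(1000) and 0.3).
#' @param group_prob probability of group 1 (default 0.5); group sizes are
#'   the rounded expectations, so they are fixed given \code{n_cells}.
#' @param seed integer seed; the simulation is bit-reproducible given it.
#' @return a list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_cells = 5000, n_genes = 5000,
                              de_fraction = 0.10,
                              de_location = 0.1, de_scale = 0.4,
                              de_up_prob = 0.5,
                              mean_shape = 0.3, mean_scale = 1,
                              mean_min = 0,
                              dispersion = 0.5,
                              lib_loc = log(1000), lib_scale = 0.3,
                              group_prob = 0.5, seed = 1L) {
  cfg <- list(n_cells = n_cells, n_genes = n_genes,
              de_fraction = de_fraction,
              de_location = de_location, de_scale = de_scale,
              de_up_prob = de_up_prob,
              mean_shape = mean_shape, mean_scale = mean_scale,
              mean_min = mean_min, dispersion = dispersion,
              lib_loc = lib_loc, lib_scale = lib_scale,
              group_prob = group_prob, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_cells < 2 || n_genes < 1) stop("invalid simulation dimensions")
    if (de_fraction < 0 || de_fraction >= 1) stop("de_fraction must be in [0,1)")
    if (de_scale < 0 || mean_shape <= 0 || mean_scale <= 0 ||
        dispersion <= 0 || lib_scale < 0)
      stop("scale parameters must be positive")
    if (group_prob <= 0 || group_prob >= 1) stop("group_prob must be in (0,1)")
    if (de_up_prob < 0 || de_up_prob > 1) stop("de_up_prob must be in [0,1]")
  })
  invisible(cfg)
}

#' Simulate a two-group UMI count dataset with ground-truth DE genes
#'
#' Draws per-gene base means from a gamma distribution, flags exactly
#' \code{round(de_fraction * n_genes)} genes as differentially expressed in
#' group 1, multiplies their group-1 mean by a lognormal factor f (location
#' \code{de_location}, scale \code{de_scale}) or by 1/f with equal
#' probability, scales each cell's expected counts to its lognormal library
#' size, and draws negative-binomial counts.  No dropout is applied on top
#' of the count noise.  Many DE factors fall near 1, so a realistic share
#' of "differentially expressed" genes is barely detectable — a property of
#' this design, not a defect.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return object of class \code{"synthetic_dataset"}: \code{counts} (cells
#'   x genes integer matrix with gene/cell names), \code{group} (1 or 2 per
#'   cell), \code{de_flag} (per-gene logical; TRUE only for group-1 DE
#'   genes), \code{de_factor} (applied multiplicative factor, exactly 1
#'   where \code{de_flag} is FALSE) and the \code{config}.
#' @export
simulate_counts <- function(config = simulation_config()) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_cells; p <- config$n_genes
  base_mean <- pmax(stats::rgamma(p, shape = config$mean_shape,
                                  scale = config$mean_scale),
                    config$mean_min)
  n_de <- round(config$de_fraction * p)
  de_flag <- rep(FALSE, p)
  de_factor <- rep(1, p)
  if (n_de > 0) {
    de_idx <- sample.int(p, n_de)
    f <- stats::rlnorm(n_de, meanlog = config$de_location,
                       sdlog = config$de_scale)
    flip <- stats::runif(n_de) >= config$de_up_prob
    f[flip] <- 1 / f[flip]
    de_flag[de_idx] <- TRUE
    de_factor[de_idx] <- f
  }
  n1 <- max(1L, min(n - 1L, round(config$group_prob * n)))
  group <- rep(c(1L, 2L), c(n1, n - n1))
  lib <- stats::rlnorm(n, meanlog = config$lib_loc, sdlog = config$lib_scale)
  mean_g1 <- base_mean * de_factor
  mean_g2 <- base_mean
  size <- 1 / config$dispersion
  counts <- matrix(0L, n, p)
  for (i in seq_len(n)) {
    mg <- if (group[i] == 1L) mean_g1 else mean_g2
    lambda <- lib[i] * mg / sum(mg)
    counts[i, ] <- stats::rnbinom(p, size = size, mu = lambda)
  }
  dimnames(counts) <- list(sprintf("cell%d", seq_len(n)),
                           sprintf("gene%d", seq_len(p)))
  structure(list(counts = counts, group = group, de_flag = de_flag,
                 de_factor = de_factor, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic UMI dataset: %d cells x %d genes, groups %d/%d\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$group == 1L), sum(x$group == 2L)))
  cat(sprintf("  %d DE genes (%.1f%%), zero fraction %.2f\n",
              sum(x$de_flag), 100 * mean(x$de_flag),
              mean(x$counts == 0)))
  invisible(x)
}

#' Highly-variable gene selection by binned dispersion
#'
#' After library-size normalization, genes are placed into
#' \code{n_bins} equal-occupancy bins by mean expression; within each bin
#' the dispersion (variance/mean) is standardized by median and MAD, and
#' the \code{n_top} genes with the largest standardized dispersion are
#' returned (ties toward the lower gene index, so selections are nested in
#' \code{n_top}).
#'
#' @param X cells x genes count matrix.
#' @param n_bins mean-expression bins (default 20).
#' @param n_top genes to keep; at most the number of non-constant genes.
#' @return integer vector of selected gene column indices (named when the
#'   matrix has gene names), ordered by decreasing standardized dispersion.
#' @export
dispersion_filter <- function(X, n_bins = 20, n_top = 5000) {
  X <- as_count_matrix(X)
  L <- {
    rs <- rowSums(X)
    X * ifelse(rs > 0, mean(rs) / rs, 1)
  }
  mu <- colMeans(L)
  v <- colMeans(L^2) - mu^2
  ok <- which(v > 0 & mu > 0)
  if (n_top > length(ok))
    stop("n_top exceeds the number of non-constant genes (", length(ok), ")")
  disp <- v[ok] / mu[ok]
  bins <- cut(rank(mu[ok], ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    med <- stats::median(disp[i])
    s <- stats::mad(disp[i])
    z[i] <- (disp[i] - med) / if (s > 0) s else 1
  }
  sel <- ok[order(-z, ok)][seq_len(n_top)]
  stats::setNames(sel, colnames(X)[sel])
}

#' Uniformly random marker baseline
#'
#' For each of \code{n_clusters} clusters, draws \code{m_per_cluster} genes
#' uniformly without replacement and returns the deduplicated union — the
#' chance baseline against which selection methods are compared (its
#' expected precision against DE ground truth equals the DE fraction).
#'
#' @param p number of genes.
#' @param m_per_cluster markers drawn per cluster.
#' @param n_clusters number of clusters (default 1).
#' @param seed optional seed.
#' @return integer vector of gene indices.
#' @export
random_markers <- function(p, m_per_cluster, n_clusters = 1, seed = NULL) {
  if (m_per_cluster > p) stop("m_per_cluster cannot exceed the gene count")
  if (!is.null(seed)) set.seed(seed)
  unique(unlist(lapply(seq_len(n_clusters),
                       function(k) sample.int(p, m_per_cluster)),
                use.names = FALSE))
}

#' Marker-recovery curves against DE ground truth
#'
#' For every prefix of an ordered selection, computes precision (true DE
#' among selected / selected), TPR (selected DE / total DE) and FPR
#' (selected non-DE / total non-DE).  Computed without cross-validation:
#' with simulated ground truth every gene is test data.
#'
#' @param selected ordered gene indices or names (best first).
#' @param de_flag per-gene logical ground truth (named if \code{selected}
#'   is character).
#' @return data.frame with columns m, precision, tpr, fpr (one row per
#'   prefix length).
#' @export
marker_recovery_metrics <- function(selected, de_flag) {
  if (length(selected) == 0L) stop("no genes selected")
  if (is.character(selected)) {
    idx <- match(selected, names(de_flag))
  } else idx <- as.integer(selected)
  if (anyNA(idx) || any(idx < 1 | idx > length(de_flag)))
    stop("unknown gene id in selection")
  hits <- cumsum(de_flag[idx])
  m <- seq_along(idx)
  n_de <- sum(de_flag); n_nde <- sum(!de_flag)
  data.frame(m = m,
             precision = hits / m,
             tpr = if (n_de > 0) hits / n_de else 0,
             fpr = if (n_nde > 0) (m - hits) / n_nde else 0)
}
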