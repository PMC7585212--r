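#' Soft-thresholding operator
#'
#' \eqn{T_\beta(x)_j = sign(x_j)(|x_j| - \beta)} where \eqn{|x_j| > \beta},
#' and 0 otherwise.  Shrinks every coordinate toward zero by \eqn{\beta} and
#' zeroes those of magnitude at most \eqn{\beta}; this is the shape of the
#' exact solution of the l1/l2-constrained linear maximization solved by
#' \code{\link{select_support}}.
#'
#' @param x numeric vector.
#' @param beta nonnegative threshold.
#' @return numeric vector of the same length.
#' @export
soft_threshold <- function(x, beta) {
  if (length(beta) != 1L || is.na(beta) || beta < 0)
    stop("soft_threshold: beta must be a single nonnegative number")
  sign(x) * pmax(abs(x) - beta, 0)
}

#' Correlation vector between ranked genes and a centered indicator
#'
#' Computes \eqn{v_j = \sum_i \bar\tau_i \bar X_{ij}} over the standardized
#' rank matrix.  Dividing \eqn{v} by \eqn{n\,\sigma(\Phi(\tau))} gives
#' exactly the per-gene Spearman rank correlation with \eqn{\tau}, so the
#' genes with largest \eqn{|v_j|} are those most rank-correlated with
#' cluster membership.
#'
#' @param Xbar a \code{"ranked_matrix"} from \code{\link{rank_and_standardize}},
#'   or a plain numeric matrix with standardized columns.
#' @param tau_bar centered indicator from \code{\link{center_ranked_indicator}}.
#' @return numeric vector of length \code{ncol(Xbar)}.
#' @export
correlation_vector <- function(Xbar, tau_bar) {
  V <- if (inherits(Xbar, "ranked_matrix")) Xbar$values else Xbar
  if (length(tau_bar) != nrow(V))
    stop("correlation_vector: tau_bar length must equal the number of cells")
  drop(crossprod(V, tau_bar))
}

#' Exact solver for the l1/l2-constrained sparse hyperplane problem
#'
#' Maximizes \eqn{\langle v, \omega\rangle} over
#' \eqn{\{\|\omega\|_2 \le 1,\ \|\omega\|_1 \le \sqrt{s}\}}.  The maximizer is
#' \eqn{\hat\omega = T_{\beta^*}(v)/\|T_{\beta^*}(v)\|_2} where \eqn{\beta^*}
#' is the threshold at which the ratio
#' \eqn{f(\beta) = \|T_\beta(v)\|_1/\|T_\beta(v)\|_2} equals \eqn{\sqrt{s}}
#' (and \eqn{\beta^* = 0} when the l1 constraint is already slack at
#' \eqn{v/\|v\|_2}).  \eqn{f} is continuous and non-increasing on
#' \eqn{[0, \max|v_j|)}, and on the interval where the support is the top-k
#' magnitudes the stopping condition is a quadratic in \eqn{\beta}, so
#' \eqn{\beta^*} is found in closed form by scanning support sizes upward.
#'
#' Tied magnitudes enter or leave the support together.  If \eqn{s} is
#' smaller than the size g of the top-magnitude tie group, no threshold
#' attains the l1 sphere (\eqn{f \ge \sqrt{g}} on the whole interval); the
#' full tie group is then reported with equal weights scaled to
#' \eqn{\|\hat\omega\|_1 = \sqrt{s}}, which is a maximizer of the program.
#'
#' @param v numeric vector with at least one nonzero entry.
#' @param s sparsity parameter, \code{s >= 1}; larger values admit more
#'   nonzero coefficients.
#' @return an object of class \code{"select_solution"}: list with
#'   \code{beta_star}, \code{omega_hat}, \code{support} (sorted indices of
#'   nonzero coefficients), \code{s}, and \code{constraint_active}.
#' @export
select_support <- function(v, s) {
  if (length(s) != 1L || is.na(s) || s < 1) stop("select_support: s must be >= 1")
  a <- abs(v)
  if (all(a == 0)) stop("select_support: no signal (v is the zero vector)")
  sqs <- sqrt(s)

  nz <- which(a > 0)
  vnz <- v[nz]
  # constraint inactive: v restricted to nonzeros already inside the l1 ball
  if (sum(abs(vnz)) / sqrt(sum(vnz^2)) <= sqs + 1e-12) {
    omega <- numeric(length(v))
    omega[nz] <- vnz / sqrt(sum(vnz^2))
    return(new_select_solution(0, omega, s, constraint_active = FALSE))
  }

  # distinct magnitudes descending; tie groups are single breakpoints
  mags <- sort(unique(a[nz]), decreasing = TRUE)
  sizes <- vapply(mags, function(m) sum(a == m), integer(1))
  csize <- cumsum(sizes)            # support size with top-g groups active
  S1 <- cumsum(mags * sizes)        # sum of active magnitudes
  S2 <- cumsum(mags^2 * sizes)      # sum of active squared magnitudes

  for (g in seq_along(mags)) {
    k  <- csize[g]
    hi <- mags[g]
    lo <- if (g < length(mags)) mags[g + 1L] else 0
    # on [lo, hi): ||T_b||_1 = S1 - k b, ||T_b||_2^2 = S2 - 2 S1 b + k b^2;
    # f(b) = sqrt(s) is k(k-s) b^2 - 2 S1 (k-s) b + (S1^2 - s S2) = 0
    A <- k * (k - s); B <- -2 * S1[g] * (k - s); C <- S1[g]^2 - s * S2[g]
    roots <- quad_roots(A, B, C)
    for (b in sort(roots[roots >= lo - 1e-12 & roots < hi])) {
      beta <- max(lo, b)
      tv <- soft_threshold(v, beta)
      # a quadratic root can correspond to f(b) = -sqrt(s); keep genuine ones
      if (abs(sum(abs(tv)) / sqrt(sum(tv^2)) - sqs) < 1e-8 * max(1, sqs)) {
        omega <- tv / sqrt(sum(tv^2))
        return(new_select_solution(beta, omega, s, constraint_active = TRUE))
      }
    }
    # s exactly matching a degenerate group (f constant at sqrt(s) here)
    if (abs(A) < 1e-12 && abs(B) < 1e-12 && abs(C) < 1e-9 * max(1, S2[g])) {
      tv <- soft_threshold(v, lo)
      omega <- tv / sqrt(sum(tv^2))
      return(new_select_solution(lo, omega, s, constraint_active = TRUE))
    }
  }

  # s below the top tie-group size: f never reaches sqrt(s); report the full
  # tie group with equal weights on the l1 sphere (a maximizer of the program)
  gsz <- sizes[1L]
  top <- which(a == mags[1L])
  omega <- numeric(length(v))
  omega[top] <- sign(v[top]) * sqs / gsz
  beta <- if (length(mags) > 1L) mags[2L] else 0
  new_select_solution(beta, omega, s, constraint_active = TRUE)
}

new_select_solution <- function(beta_star, omega_hat, s, constraint_active) {
  structure(list(beta_star = beta_star,
                 omega_hat = omega_hat,
                 support = which(omega_hat != 0),
                 s = s,
                 constraint_active = constraint_active),
            class = "select_solution")
}

quad_roots <- function(A, B, C) {
  if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) return(numeric(0))
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) {
    if (disc > -1e-9 * max(B^2, 1)) disc <- 0 else return(numeric(0))
  }
  r <- sqrt(disc)
  c((-B - r) / (2 * A), (-B + r) / (2 * A))
}

#' Quasi-standardization of count columns (SPA variant)
#'
#' Each gene column becomes a convex combination of its centered and its
#' fully standardized version, weighted by
#' \eqn{\alpha^{2(1-|\rho_j|)}\lambda} where \eqn{\rho_j} is the Pearson
#' correlation of the column with the +/-1 indicator \code{tau}: genes
#' highly correlated with the labels keep their raw scale (times
#' \eqn{\lambda}), uncorrelated high-expression genes are downweighted to
#' unit variance.  Constant columns are dropped as in
#' \code{\link{rank_and_standardize}}.
#'
#' @param X cells x genes count matrix.
#' @param tau +/-1 indicator with both signs present.
#' @param alpha weight base in (0,1).
#' @param lambda positive scale for the centered term.
#' @return a \code{"ranked_matrix"}-shaped list (values, kept_genes,
#'   dropped_genes, gene_ids); columns are quasi-standardized, not ranked.
#' @export
spa_standardize <- function(X, tau, alpha, lambda) {
  X <- as_count_matrix(X)
  if (!all(tau %in% c(-1, 1)) || length(unique(tau)) < 2L)
    stop("tau must contain both +1 and -1")
  if (length(tau) != nrow(X)) stop("tau length must equal the number of cells")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (lambda <= 0) stop("lambda must be positive")
  n <- nrow(X)
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(X * X) - mu^2)
  keep <- sd_pop > 0
  if (!any(keep)) stop("no informative genes: all genes are constant across cells")
  Xc <- sweep(X[, keep, drop = FALSE], 2L, mu[keep], `-`)
  tc <- tau - mean(tau)
  rho <- drop(crossprod(Xc, tc)) / (n * sd_pop[keep] * sqrt(mean(tc^2)))
  w <- alpha^(2 * (1 - abs(rho)))
  V <- sweep(Xc, 2L, w * lambda, `*`) +
       sweep(sweep(Xc, 2L, sd_pop[keep], `/`), 2L, 1 - w, `*`)
  structure(list(values = V,
                 kept_genes = which(keep),
                 dropped_genes = which(!keep),
                 gene_ids = colnames(X)[keep]),
            class = "ranked_matrix")
}
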