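# Small programmatic fixtures shared across test files.

toy_counts <- function(n = 30, p = 10, seed = 1, lambda = 2) {
  set.seed(seed)
  X <- matrix(rpois(n * p, lambda), n, p,
              dimnames = list(sprintf("c%d", 1:n), sprintf("g%d", 1:p)))
  X
}

# Two well-separated classes: class "a" overexpresses the first gene block,
# class "b" the second.
separable_counts <- function(n_per = 20, p = 12, shift = 25, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  X <- matrix(rpois(n * p, 2), n, p,
              dimnames = list(NULL, sprintf("g%d", 1:p)))
  X[1:n_per, 1:3] <- X[1:n_per, 1:3] + shift
  X[(n_per + 1):n, 4:6] <- X[(n_per + 1):n, 4:6] + shift
  list(X = X, y = rep(c("a", "b"), each = n_per))
}

# The 6-cell toy where gene 1 perfectly tracks tau.
tracking_toy <- function() {
  X <- cbind(g1 = c(5, 6, 7, 0, 0, 0),
             g2 = c(0, 7, 5, 6, 0, 0),
             g3 = c(6, 0, 0, 7, 5, 0))
  list(X = X, tau = c(1, 1, 1, -1, -1, -1))
}
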