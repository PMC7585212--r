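# Independent numerical oracle for the l1/l2-constrained linear program:
# maximize <v, w> subject to ||w||_2 <= 1, ||w||_1 <= sqrt(s).
# Projected-gradient ascent with Dykstra's alternating projection onto the
# intersection of the two balls.  Deliberately shares nothing with the
# package's closed-form threshold search.

proj_l2_ball <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm <= 1) x else x / nrm
}

# Euclidean projection onto {||x||_1 <= r} (Duchi et al. simplex projection).
proj_l1_ball <- function(x, r) {
  if (sum(abs(x)) <= r) return(x)
  u <- sort(abs(x), decreasing = TRUE)
  css <- cumsum(u)
  k <- max(which(u > (css - r) / seq_along(u)))
  theta <- (css[k] - r) / k
  sign(x) * pmax(abs(x) - theta, 0)
}

proj_intersection <- function(x, r, iter = 200) {
  p <- numeric(length(x)); q <- numeric(length(x))
  y <- x
  for (t in seq_len(iter)) {
    y1 <- proj_l2_ball(y + p); p <- y + p - y1
    y  <- proj_l1_ball(y1 + q, r); q <- y1 + q - y
    if (max(abs(y - y1)) < 1e-12) break
  }
  y
}

oracle_l1l2_max <- function(v, s, iters = 2000, step = NULL) {
  r <- sqrt(s)
  if (is.null(step)) step <- 2 / max(abs(v))
  w <- proj_intersection(v / sqrt(sum(v^2)), r)
  best <- w; best_obj <- sum(v * w)
  for (t in seq_len(iters)) {
    w <- proj_intersection(w + (step / sqrt(t)) * v, r)
    obj <- sum(v * w)
    if (obj > best_obj) { best <- w; best_obj <- obj }
  }
  best
}

# Batch convex-programming oracle: sequential quadratic programming (scipy
# SLSQP) on the split-variable form
#   max <v, wp - wm>  s.t.  ||wp - wm||_2 <= 1, sum(wp + wm) <= sqrt(s),
#                           wp, wm >= 0.
# An active-set method, so it identifies the support sharply even when
# magnitudes are nearly tied (where projected gradient crawls along a face).
# `instances` is a list of list(v = ..., s = ...); returns a list of solution
# vectors.
oracle_batch_slsqp <- function(instances) {
  infile <- tempfile(fileext = ".json"); outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(instances, function(it)
    list(v = it$v, s = it$s)), infile, digits = NA, auto_unbox = TRUE)
  script <- '
import json, sys
import numpy as np
from scipy.optimize import minimize
inp, outp = sys.argv[1], sys.argv[2]
with open(inp) as fh:
    instances = json.load(fh)
res = []
for it in instances:
    v = np.asarray(it["v"], dtype=float)
    r = float(it["s"]) ** 0.5
    p = v.size
    obj = lambda z: -(v @ (z[:p] - z[p:]))
    jac = lambda z: np.concatenate([-v, v])
    cons = [
        {"type": "ineq",
         "fun": lambda z: 1.0 - np.sum((z[:p] - z[p:]) ** 2),
         "jac": lambda z: np.concatenate([-2 * (z[:p] - z[p:]),
                                           2 * (z[:p] - z[p:])])},
        {"type": "ineq", "fun": lambda z: r - np.sum(z),
         "jac": lambda z: -np.ones(2 * p)},
    ]
    z0 = np.zeros(2 * p)
    top = int(np.argmax(np.abs(v)))
    if v[top] >= 0: z0[top] = min(1.0, r)
    else: z0[p + top] = min(1.0, r)
    sol = minimize(obj, z0, jac=jac, method="SLSQP", bounds=[(0, None)] * (2 * p),
                   constraints=cons, options={"maxiter": 500, "ftol": 1e-14})
    w = sol.x[:p] - sol.x[p:]
    res.append(w.tolist())
with open(outp, "w") as fh:
    json.dump(res, fh)
'
  status <- system2("python", c("-c", shQuote(script), infile, outfile))
  if (status != 0) stop("python oracle failed")
  out <- jsonlite::read_json(outfile, simplifyVector = FALSE)
  lapply(out, function(w) unlist(w))
}

# Random feasible points in the intersection, for objective-dominance checks.
random_feasible <- function(p, s, n = 1000) {
  r <- sqrt(s)
  W <- matrix(rnorm(n * p), n, p)
  t(apply(W, 1, function(w) proj_intersection(w, r, iter = 50)))
}
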