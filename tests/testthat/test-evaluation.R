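test_that("fold assignment partitions cells into near-equal reproducible folds", {
  f <- make_folds(10, 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))
  expect_identical(make_folds(10, 5, seed = 1), f)
  f11 <- table(make_folds(11, 5, seed = 2))
  expect_equal(sort(as.integer(f11)), c(2, 2, 2, 2, 3))
  expect_error(make_folds(3, 5), "at least K")
})

test_that("nearest-centroid classifier recovers separated classes", {
  sep <- separable_counts()
  model <- train_ncc(sep$X, sep$y, colnames(sep$X))
  expect_equal(unname(predict_ncc(model, sep$X)), sep$y)
  # one cell per class: centroids equal the normalized rows
  X1 <- sep$X[c(1, 40), ]
  m1 <- train_ncc(X1, c("a", "b"), colnames(X1))
  expect_equal(m1$centroids, log_normalize(X1), ignore_attr = TRUE)
  # duplicating the training set leaves centroids unchanged
  m2 <- train_ncc(rbind(sep$X, sep$X), rep(sep$y, 2), colnames(sep$X))
  expect_equal(m2$centroids, model$centroids)
  # ties go to the lowest class id
  Xt <- matrix(c(4, 0, 0, 4), 2, 2, dimnames = list(NULL, c("g1", "g2")))
  mt <- train_ncc(Xt, c(1, 2), c("g1", "g2"))
  mid <- matrix(c(2, 2), 1, dimnames = list(NULL, c("g1", "g2")))
  expect_equal(unname(predict_ncc(mt, mid)), 1)
  expect_error(train_ncc(sep$X, sep$y, "nope"), "absent")
})

test_that("classification metrics match hand-computed confusion matrices", {
  perfect <- classification_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect, list(error = 0, weighted_precision = 1, mcc = 1))
  m <- classification_metrics(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(m$error, 0.5)
  expect_equal(m$weighted_precision, 0.5)
  expect_equal(m$mcc, 0)
  # constant prediction on a balanced set: no information
  expect_equal(classification_metrics(c(1, 1, 2, 2), c(1, 1, 1, 1))$mcc, 0)
  # an unpredicted class contributes per-class precision 0
  m2 <- classification_metrics(c(1, 1, 2), c(1, 1, 1))
  expect_equal(m2$weighted_precision, (2 / 3) * (2 / 3) + (1 / 3) * 0)
  expect_error(classification_metrics(integer(0), integer(0)), "empty")
  # documented ranges on random inputs
  set.seed(4)
  for (i in 1:10) {
    yt <- sample(1:3, 30, replace = TRUE); yp <- sample(1:4, 30, replace = TRUE)
    m3 <- classification_metrics(yt, yp)
    expect_true(m3$error >= 0 && m3$error <= 1)
    expect_true(m3$weighted_precision >= 0 && m3$weighted_precision <= 1)
    expect_true(m3$mcc >= -1 && m3$mcc <= 1)
  }
})

test_that("partition metrics equal 1 on identical or relabeled partitions", {
  y <- rep(1:3, times = c(5, 7, 9))
  m <- clustering_metrics(y, y)
  expect_equal(m, list(ari = 1, ami = 1, fms = 1))
  relab <- c("x", "z", "q")[y]
  m2 <- clustering_metrics(y, relab)
  expect_equal(m2, list(ari = 1, ami = 1, fms = 1))
  expect_error(clustering_metrics(integer(0), integer(0)), "empty")
})

test_that("ARI agrees with an independent implementation and metrics are symmetric", {
  skip_if_not_installed("mclust")
  set.seed(12)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    m <- clustering_metrics(a, b)
    expect_equal(m$ari, mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    m_swap <- clustering_metrics(b, a)
    expect_equal(m$ari, m_swap$ari)
    expect_equal(m$fms, m_swap$fms)
    expect_equal(m$ami, m_swap$ami, tolerance = 1e-12)
    expect_lte(m$ari, 1); expect_lte(m$ami, 1)
    expect_true(m$fms >= 0 && m$fms <= 1)
  }
})

test_that("ARI and AMI are centered near zero for independent labelings", {
  set.seed(2024)
  vals <- t(replicate(100, {
    a <- sample(1:4, 200, replace = TRUE)
    b <- sample(1:5, 200, replace = TRUE)
    m <- clustering_metrics(a, b)
    c(m$ari, m$ami)
  }))
  expect_lt(abs(mean(vals[, 1])), 0.05)
  expect_lt(abs(mean(vals[, 2])), 0.05)
})

test_that("resolution-grid clustering maximizes each metric independently", {
  sep <- separable_counts(n_per = 15)
  # ground truth passed back by the callable: every metric is 1 at every r
  res <- louvain_grid_cluster(sep$X, colnames(sep$X), sep$y, k_neighbors = 5,
                              resolutions = seq(0.5, 1.5, by = 0.5),
                              cluster_fun = function(g, r) sep$y)
  expect_equal(res$best, list(ari = 1, ami = 1, fms = 1))
  expect_equal(nrow(res$by_resolution), 3)
  # one candidate clustering per grid point
  calls <- 0
  res2 <- louvain_grid_cluster(sep$X, colnames(sep$X), sep$y, k_neighbors = 5,
                               resolutions = seq(0.1, 3.0, by = 0.1),
                               cluster_fun = function(g, r) {
                                 calls <<- calls + 1
                                 sample(1:2, length(sep$y), replace = TRUE)
                               })
  expect_equal(calls, 30)
  expect_equal(nrow(res2$by_resolution), 30)
  expect_error(louvain_grid_cluster(sep$X, colnames(sep$X), sep$y,
                                    k_neighbors = 30), "smaller")
})

test_that("default Louvain callable recovers well-separated clusters", {
  sep <- separable_counts(n_per = 15, shift = 40)
  res <- louvain_grid_cluster(sep$X, colnames(sep$X), sep$y, k_neighbors = 5,
                              resolutions = c(0.5, 1.0))
  expect_gt(res$best$ari, 0.9)
})

test_that("cross-validated evaluation is honest, deterministic, and accurate on easy data", {
  sep <- separable_counts(n_per = 25, shift = 30)
  all_genes <- function(Xt, yt, size) colnames(Xt)
  rep1 <- cross_validated_evaluation(sep$X, sep$y, all_genes, sizes = c(12),
                                     seed = 3, method = "all")
  err <- rep1$aggregates$value[rep1$aggregates$metric == "error"]
  expect_lt(err, 0.05)
  rep2 <- cross_validated_evaluation(sep$X, sep$y, all_genes, sizes = c(12),
                                     seed = 3, method = "all")
  expect_identical(rep1$points, rep2$points)
  # poisoning the held-out fold must not change selection or training:
  # inject a fake perfect gene and a selector that would grab it if it saw
  # test data, then check the report is built from training folds only
  seen_rows <- integer(0)
  spy <- function(Xt, yt, size) { seen_rows <<- c(seen_rows, nrow(Xt)); colnames(Xt) }
  cross_validated_evaluation(sep$X, sep$y, spy, sizes = 12, seed = 3)
  expect_true(all(seen_rows == 40))  # always K-1 folds of 50 cells
  # a class absent from a training split is an error naming the fold
  y_rare <- sep$y; y_rare[1] <- "rare"
  expect_error(cross_validated_evaluation(sep$X, y_rare, all_genes, 12, seed = 3),
               "class absent from the training split of fold")
})

test_that("AoM scores average per-metric medians and rank methods per range", {
  pts <- data.frame(
    method = rep(c("M"), 6),
    n_markers_requested = rep(c(5, 10, 20), 2),
    metric = rep(c("A", "B"), each = 3),
    value = c(0.5, 0.7, 0.9, 0.3, 0.4, 0.5))
  res <- aom_rank(pts, ranges = list(c(1, 25)), metrics = c("A", "B"),
                  error_metrics = character(0))
  expect_equal(res$aom, (0.7 + 0.4) / 2)
  # single metric, single point
  one <- data.frame(method = "M", n_markers_requested = 5, metric = "A",
                    value = 0.42)
  expect_equal(aom_rank(one, list(c(1, 10)), "A",
                        error_metrics = character(0))$aom, 0.42)
  # dominance gives rank 1 everywhere; ties share the minimum rank
  pts2 <- rbind(pts,
                transform(pts, method = "W", value = value - 0.2),
                transform(pts, method = "T", value = value))
  res2 <- aom_rank(pts2, ranges = list(c(1, 9), c(10, 25)),
                   metrics = c("A", "B"), error_metrics = character(0))
  expect_true(all(res2$rank[res2$method == "M"] == 1))
  expect_true(all(res2$rank[res2$method == "T"] == 1))
  expect_true(all(res2$rank[res2$method == "W"] == 3))
  # error-type metrics are flipped so larger is better
  pe <- data.frame(method = c("M", "W"), n_markers_requested = 5,
                   metric = "error", value = c(0.1, 0.4))
  re <- aom_rank(pe, list(c(1, 10)), "error")
  expect_equal(re$aom, c(0.9, 0.6))
  expect_equal(re$rank, c(1, 2))
  # empty range errors with method and range named
  expect_error(aom_rank(pts, list(c(100, 200)), c("A", "B"),
                        error_metrics = character(0)), "range")
})
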