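mat1d <- function(v) matrix(v, ncol = 1, dimnames = list(paste0("s", seq_along(v)), "f"))

test_that("positive-subject subsetting drops the target column and negatives", {
  X <- cbind(f1 = c(1, 0, 1, 0, 1, 1, 0, 0, 1, 1),
             f2 = rep(c(0, 1), 5),
             hiv = c(1, 1, 0, 0, 1, 0, 0, 1, 0, 0))
  rownames(X) <- sprintf("s%02d", 1:10)
  out <- subset_positive(X, "hiv")
  expect_equal(nrow(out), 4)
  expect_false("hiv" %in% colnames(out))
  all_pos <- X; all_pos[, "hiv"] <- 1
  expect_equal(nrow(subset_positive(all_pos, "hiv")), 10)
  few <- X; few[, "hiv"] <- c(1, 1, rep(0, 8))
  expect_error(subset_positive(few, "hiv"), "fewer than 3")
})

test_that("kNN graph matches the hand-computed 1-D neighbourhoods", {
  X <- mat1d(c(0, 1, 10, 11))
  g <- knn_graph(X, 1)
  el <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_setequal(el, c("s1-s2", "s3-s4"))
  expect_false(igraph::is_connected(g))
  full <- knn_graph(X, 3)
  expect_equal(igraph::ecount(full), choose(4, 2))
  # structural bounds for arbitrary k
  set.seed(6)
  Xr <- matrix(rbinom(200, 1, 0.5), 20, 10,
               dimnames = list(sprintf("r%02d", 1:20), NULL))
  for (k in c(1, 3, 5)) {
    gk <- knn_graph(Xr, k)
    expect_true(igraph::is_simple(gk))
    expect_gte(min(igraph::degree(gk)), 1)
    expect_lte(igraph::ecount(gk), 20 * k)
    expect_gte(igraph::ecount(gk), floor(20 * k / 2))
  }
})

test_that("minimum-k search returns the smallest connecting k", {
  g <- min_k_connected(mat1d(c(0, 1, 10, 11)))
  expect_equal(igraph::graph_attr(g, "parameter"), 2)
  expect_true(igraph::is_connected(g))
  # two identical subjects plus one distant: brute-force minimality
  X <- mat1d(c(0, 0, 5))
  g2 <- min_k_connected(X)
  kstar <- igraph::graph_attr(g2, "parameter")
  expect_true(igraph::is_connected(g2))
  if (kstar > 1)
    expect_false(igraph::is_connected(knn_graph(X, kstar - 1)))
  g3 <- min_k_connected(mat1d(c(0, 3)))
  expect_equal(igraph::graph_attr(g3, "parameter"), 1)
  expect_equal(igraph::ecount(g3), 1)
})

test_that("subject correlation matches the Pearson formula", {
  a <- c(1, 0, 1, 1, 0)
  b <- c(1, 1, 0, 1, 0)
  X <- rbind(a = a, b = b)
  cm <- subject_correlation(X)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cm["a", "b"], hand)
  expect_equal(diag(cm), c(a = 1, b = 1))
  X2 <- rbind(a = a, b = a)
  expect_equal(subject_correlation(X2)["a", "b"], 1)
  X3 <- rbind(a = a, z = rep(1, 5))
  expect_warning(cm3 <- subject_correlation(X3), "zero-variance")
  expect_equal(cm3["a", "z"], 0)
})

test_that("correlation thresholding places exactly the edges above threshold", {
  cm <- matrix(c(1, 0.9, 0.2, 0.4,
                 0.9, 1, 0.6, 0.1,
                 0.2, 0.6, 1, 0.55,
                 0.4, 0.1, 0.55, 1), 4, 4,
               dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  g <- ct_graph(cm, 0.5)
  el <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_setequal(el, c("s1-s2", "s2-s3", "s3-s4"))
  expect_equal(igraph::ecount(ct_graph(cm, 1)), 0)
  expect_equal(igraph::ecount(ct_graph(cm, 0.05)), choose(4, 2))
  # edge count is non-increasing in the threshold
  counts <- sapply(seq(0, 1, 0.1), function(t) igraph::ecount(ct_graph(cm, t)))
  expect_true(all(diff(counts) <= 0))
})

test_that("soft-thresholding kernel", {
  expect_equal(soft_threshold(0.5, 0.5), 0)
  expect_equal(soft_threshold(-2, 0.5), -1.5)
  expect_equal(soft_threshold(c(1, -0.2, 0.7), 0.3), c(0.7, 0, 0.4))
})

test_that("MB null model: penalty above the largest marginal correlation gives no edges", {
  set.seed(8)
  X <- matrix(rnorm(5 * 200), 5, 200, dimnames = list(paste0("v", 1:5), NULL))
  cm <- subject_correlation(X)
  lam <- max(abs(cm[upper.tri(cm)])) * 1.1
  expect_equal(igraph::ecount(mb_graph(X, lam)), 0)
})

test_that("MB recovers the chain at a mid-path penalty", {
  d <- generate_gaussian_precision(500, 5, "chain", seed = 10)
  path <- inference_path(t(d$samples), "mb")
  f1 <- sapply(path$graphs, edge_recovery_f1, true_edges = d$edges)
  expect_equal(max(f1), 1)
})

test_that("glasso null models give empty graphs", {
  s_diag <- diag(c(1, 2, 3))
  dimnames(s_diag) <- list(paste0("v", 1:3), paste0("v", 1:3))
  f <- glasso_fit(s_diag, 0.05)
  expect_equal(sum(abs(f$theta[upper.tri(f$theta)]) > 1e-8), 0)
  set.seed(12)
  X <- matrix(rnorm(4 * 100), 4, 100, dimnames = list(paste0("v", 1:4), NULL))
  s <- subject_correlation(X)
  rho <- max(abs(s[upper.tri(s)])) * 1.01
  expect_equal(igraph::ecount(glasso_graph(X, rho)), 0)
})

test_that("glasso solution satisfies the stationarity (KKT) conditions", {
  s <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.4,
                0.2, 0.4, 1), 3, 3)
  rho <- 0.1
  f <- glasso_fit(s, rho, tol = 1e-8)
  resid <- f$w - s
  for (i in 1:2) for (j in (i + 1):3) {
    th <- f$theta[i, j]
    if (abs(th) > 1e-8) {
      expect_lt(abs(resid[i, j] - rho * sign(th)), 1e-6)
    } else {
      expect_lte(abs(resid[i, j]), rho + 1e-6)
    }
  }
  # estimated covariance is positive definite
  expect_gt(min(eigen(f$w, symmetric = TRUE, only.values = TRUE)$values), 0)
  # precision is the inverse of the estimated covariance
  expect_lt(max(abs(f$w %*% f$theta - diag(3))), 1e-4)
})

test_that("sparsest-connected CT sits just at the connectivity threshold", {
  set.seed(14)
  X <- rbind(matrix(rbinom(8 * 30, 1, 0.8), 8, 30),
             matrix(rbinom(8 * 30, 1, 0.2), 8, 30))
  rownames(X) <- sprintf("s%02d", 1:16)
  g <- sparsest_connected(X, "ct")
  expect_true(igraph::is_connected(g))
  thr <- igraph::graph_attr(g, "parameter")
  cm <- subject_correlation(X)
  vals <- sort(unique(cm[upper.tri(cm)]), decreasing = TRUE)
  pos <- which(vals == thr)
  if (pos > 1)
    expect_false(igraph::is_connected(ct_graph(cm, vals[pos - 1])))
})

test_that("penalized paths are monotone and sparsest-connected is connected", {
  d <- generate_gaussian_precision(200, 8, "random", seed = 20)
  for (m in c("mb", "glasso")) {
    path <- inference_path(t(d$samples), m, n_path = 12)
    counts <- sapply(path$graphs, igraph::ecount)
    expect_true(all(diff(counts) >= 0))
    g <- sparsest_connected(t(d$samples), m, n_path = 12)
    expect_true(igraph::is_connected(g) ||
                  isTRUE(igraph::graph_attr(g, "warning")))
    expect_true(igraph::is_simple(g))
  }
})
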