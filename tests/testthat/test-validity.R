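toy_two_clusters <- function() {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  rownames(X) <- paste0("s", 1:4)
  labs <- setNames(c(0, 0, 1, 1), rownames(X))
  list(X = X, labs = labs)
}

test_that("hand-computed toy values for all five indices", {
  X_db <- matrix(c(0, 2, 10, 12), ncol = 1)
  labs_db <- c(1, 1, 2, 2)
  expect_equal(davies_bouldin(X_db, labs_db), 0.2)
  t2 <- toy_two_clusters()
  expect_equal(calinski_harabasz(t2$X, t2$labs), 200)
  # full hand computation: outer points (0, 11) have a = 1, b = 10.5;
  # inner points (1, 10) have a = 1, b = 9.5
  expect_equal(silhouette_index(t2$X, t2$labs), (9.5 / 10.5 + 8.5 / 9.5) / 2)
  expect_equal(hubert_levine_c(t2$X, t2$labs), 0)
  expect_equal(baker_hubert_gamma(t2$X, t2$labs), 1)
  # adversarial labels: the only within pair (0-10) is larger than every
  # between pair (0-5, 10-5)
  X_bad <- matrix(c(0, 10, 5), ncol = 1)
  labs_bad <- c(0, 0, 1)
  expect_equal(baker_hubert_gamma(X_bad, labs_bad), -1)
  expect_equal(hubert_levine_c(X_bad, labs_bad), 1)
})

test_that("degenerate inputs are flagged", {
  X <- matrix(rep(c(0, 5), each = 4), ncol = 1)
  labs <- rep(1:2, 4)  # both clusters have the same centroid
  expect_warning(davies_bouldin(X, labs), "coincident")
  X2 <- matrix(rep(c(0, 0, 5, 5)), ncol = 1)
  expect_warning(v <- calinski_harabasz(X2, c(1, 1, 2, 2)), "zero within")
  expect_equal(v, Inf)
  Xs <- matrix(rep(1, 6), ncol = 1)
  expect_warning(s <- silhouette_index(Xs, c(1, 1, 2, 2, 3, 3)), "identical")
  expect_equal(s, 0)
})

test_that("each point in its own cluster scores silhouette 0 by convention", {
  set.seed(2)
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(silhouette_index(X, 1:5), 0)
})

test_that("all five indices match brute-force oracles on random instances", {
  for (s in 1:20) {
    inst <- random_instance(s)
    expect_equal(davies_bouldin(inst$X, inst$labs),
                 oracle_davies_bouldin(inst$X, inst$labs), tolerance = 1e-10)
    expect_equal(silhouette_index(inst$X, inst$labs),
                 oracle_silhouette(inst$X, inst$labs), tolerance = 1e-10)
    expect_equal(calinski_harabasz(inst$X, inst$labs),
                 oracle_calinski_harabasz(inst$X, inst$labs), tolerance = 1e-10)
    expect_equal(baker_hubert_gamma(inst$X, inst$labs),
                 oracle_gamma(inst$X, inst$labs), tolerance = 1e-10)
    expect_equal(hubert_levine_c(inst$X, inst$labs),
                 oracle_c_index(inst$X, inst$labs), tolerance = 1e-10)
  }
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(31)
  X <- matrix(rnorm(60), 30, 2)
  labs <- sample(1:3, 30, replace = TRUE)
  ref <- mean(cluster::silhouette(labs, dist(X))[, "sil_width"])
  expect_equal(silhouette_index(X, labs), ref, tolerance = 1e-10)
})

test_that("indices are invariant to label renaming and translation of X", {
  inst <- random_instance(99)
  perm <- setNames(sample(100:103), as.character(sort(unique(inst$labs))))
  relab <- perm[as.character(inst$labs)]
  shifted <- inst$X + 7.5
  for (f in list(davies_bouldin, silhouette_index, calinski_harabasz,
                 baker_hubert_gamma, hubert_levine_c)) {
    v <- f(inst$X, inst$labs)
    expect_equal(f(inst$X, relab), v, tolerance = 1e-12)
    expect_equal(f(shifted, inst$labs), v, tolerance = 1e-8)
  }
})

test_that("planted labels beat random labels on every index, every seed", {
  for (s in 1:20) {
    set.seed(s)
    n <- 30
    X <- rbind(matrix(rnorm(n / 2 * 3, mean = 0), n / 2, 3),
               matrix(rnorm(n / 2 * 3, mean = 4), n / 2, 3))
    truth <- rep(1:2, each = n / 2)
    rand <- sample(truth)
    sc_t <- score_clustering(X, truth, "truth")
    sc_r <- score_clustering(X, rand, "random")
    expect_lt(sc_t$davies_bouldin, sc_r$davies_bouldin)
    expect_gt(sc_t$silhouette, sc_r$silhouette)
    expect_gt(sc_t$calinski_harabasz, sc_r$calinski_harabasz)
    expect_gt(sc_t$baker_hubert, sc_r$baker_hubert)
    expect_lt(sc_t$hubert_levine, sc_r$hubert_levine)
  }
})

test_that("a dominant scorecard takes all five points", {
  sc <- data.frame(
    id = c("good", "bad"),
    davies_bouldin = c(0.5, 2), silhouette = c(0.8, 0.1),
    calinski_harabasz = c(50, 10), baker_hubert = c(0.9, 0.2),
    hubert_levine = c(0.05, 0.4))
  r <- rank_clusterings(sc)
  expect_equal(unname(r$points["good"]), 5L)
  expect_equal(r$winner, "good")
  expect_equal(sum(r$points), 5L)
})

test_that("points ties are resolved by pairwise index-majority comparison", {
  sc <- data.frame(
    id = c("a", "b", "c"),
    davies_bouldin = c(0.5, 0.9, 1.5),   # a best
    silhouette = c(0.3, 0.6, 0.2),       # b best
    calinski_harabasz = c(40, 30, 20),   # a best
    baker_hubert = c(0.3, 0.5, 0.2),     # b best
    hubert_levine = c(0.32, 0.31, 0.1))  # c best -> points a=2, b=2, c=1
  r <- rank_clusterings(sc)
  expect_equal(unname(r$points[c("a", "b", "c")]), c(2L, 2L, 1L))
  # pairwise a vs b across the five indices: a better on db, ch; b better
  # on sil, bh, hl -> b wins the tie-break
  expect_equal(r$winner, "b")
  expect_true(any(grepl("points tie", r$tiebreak_log)))
  expect_true(any(grepl("pairwise", r$tiebreak_log)))
})

test_that("an exact index tie withholds that point", {
  sc <- data.frame(
    id = c("a", "b"),
    davies_bouldin = c(1, 1),            # exact tie: no point
    silhouette = c(0.5, 0.4),
    calinski_harabasz = c(10, 20),
    baker_hubert = c(0.5, 0.1),
    hubert_levine = c(0.2, 0.3))
  r <- rank_clusterings(sc)
  expect_equal(sum(r$points), 4L)
  expect_true(any(grepl("davies_bouldin.*withheld", r$tiebreak_log)))
})
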