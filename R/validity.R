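# Internal cluster validity indices, computed in feature space: Euclidean
# distances on the subjects' (selected-feature) vectors, with labels from
# any clustering of the corresponding subject graph.

check_xy <- function(X, labels) {
  labs <- partition_labels(labels)
  X <- as.matrix(X)
  if (!is.null(names(labs)) && !is.null(rownames(X)))
    labs <- labs[rownames(X)]
  if (length(labs) != nrow(X) || anyNA(labs))
    stop("labels must cover exactly the rows of X")
  list(X = X, labs = as.integer(factor(labs)))
}

#' Davies-Bouldin index (lower is better)
#'
#' Mean over clusters of the worst-case similarity ratio
#' `(sigma_i + sigma_j) / d(c_i, c_j)`, where `sigma` is the mean
#' Euclidean distance of a cluster's points to its centroid and `c` the
#' centroid. Coincident centroids make a ratio infinite; the index is
#' returned as `Inf` with a degenerate-clustering warning.
#'
#' @param X numeric subjects x features matrix.
#' @param labels a [partition()] or named/plain label vector over rows.
#' @return the index value.
#' @export
davies_bouldin <- function(X, labels) {
  z <- check_xy(X, labels)
  k <- max(z$labs)
  if (k < 2) stop("need at least 2 clusters")
  cent <- rowsum(z$X, z$labs) / as.vector(table(z$labs))
  sig <- vapply(seq_len(k), function(i) {
    pts <- z$X[z$labs == i, , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[i, ])^2)))
  }, numeric(1))
  dc <- as.matrix(dist(cent))
  if (any(dc[upper.tri(dc)] == 0))
    warning("degenerate clustering: coincident centroids")
  r <- outer(sig, sig, "+") / dc
  diag(r) <- -Inf
  mean(apply(r, 1, max))
}

#' Silhouette index (higher is better)
#'
#' Mean over points of `(b - a) / max(a, b)` with `a` the mean
#' within-cluster distance and `b` the smallest mean distance to another
#' cluster; points in singleton clusters score 0 (so the all-singletons
#' partition scores 0).
#'
#' @inheritParams davies_bouldin
#' @return mean silhouette width in \[-1, 1\].
#' @export
silhouette_index <- function(X, labels) {
  z <- check_xy(X, labels)
  n <- nrow(z$X)
  k <- max(z$labs)
  if (k < 2) stop("need at least 2 clusters")
  d <- as.matrix(dist(z$X))
  if (all(d == 0)) {
    warning("all points identical; silhouette 0 by convention")
    return(0)
  }
  sizes <- as.vector(table(z$labs))
  # mean distance of each point to each cluster
  md <- rowsum(t(d), z$labs)  # k x n sums
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- z$labs[i]
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- md[ci, i] / (sizes[ci] - 1)
    b <- min((md[, i] / sizes)[-ci])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Calinski-Harabasz index (higher is better)
#'
#' `[B / (k - 1)] / [W / (n - k)]` with `B` the between-cluster and `W`
#' the within-cluster sum of squared Euclidean distances to the
#' respective centroids. Zero within-cluster variance returns `Inf` with
#' a degenerate-clustering warning.
#'
#' @inheritParams davies_bouldin
#' @return the index value.
#' @export
calinski_harabasz <- function(X, labels) {
  z <- check_xy(X, labels)
  n <- nrow(z$X)
  k <- max(z$labs)
  if (k < 2 || k > n - 1) stop("need 2 <= k <= n-1 clusters")
  grand <- colMeans(z$X)
  sizes <- as.vector(table(z$labs))
  cent <- rowsum(z$X, z$labs) / sizes
  B <- sum(sizes * rowSums(sweep(cent, 2, grand)^2))
  W <- sum(vapply(seq_len(k), function(i) {
    pts <- z$X[z$labs == i, , drop = FALSE]
    sum(sweep(pts, 2, cent[i, ])^2)
  }, numeric(1)))
  if (W == 0) {
    warning("degenerate clustering: zero within-cluster variance")
    return(Inf)
  }
  (B / (k - 1)) / (W / (n - k))
}

# split pairwise distances into within- and between-cluster pairs
pair_distances <- function(X, labs) {
  d <- dist(X)
  n <- attr(d, "Size")
  pr <- combn(n, 2)
  within <- labs[pr[1, ]] == labs[pr[2, ]]
  list(d = as.vector(d), within = within)
}

#' Baker-Hubert Gamma (higher is better)
#'
#' Rank correlation between distance and cluster co-membership:
#' `Gamma = (s_plus - s_minus) / (s_plus + s_minus)`, where `s_plus`
#' counts (within-pair, between-pair) distance comparisons with the
#' within-pair distance strictly smaller, and `s_minus` those with it
#' strictly larger.
#'
#' @inheritParams davies_bouldin
#' @return Gamma in \[-1, 1\]; 0 with a warning when all comparisons tie.
#' @export
baker_hubert_gamma <- function(X, labels) {
  z <- check_xy(X, labels)
  pd <- pair_distances(z$X, z$labs)
  dw <- pd$d[pd$within]
  db <- pd$d[!pd$within]
  if (length(dw) == 0 || length(db) == 0)
    stop("need at least one within-cluster and one between-cluster pair")
  sb <- sort(db)
  # for each within distance: #between strictly larger / strictly smaller
  n_le <- findInterval(dw, sb)              # between <= dw
  n_lt <- findInterval(dw, sb, left.open = TRUE)  # between < dw
  s_plus <- sum(length(sb) - n_le)
  s_minus <- sum(n_lt)
  if (s_plus + s_minus == 0) {
    warning("all distance comparisons tie; Gamma 0")
    return(0)
  }
  (s_plus - s_minus) / (s_plus + s_minus)
}

#' Hubert-Levine C-index (lower is better)
#'
#' `C = (S_w - S_min) / (S_max - S_min)` with `S_w` the sum of
#' within-cluster pairwise distances, and `S_min`/`S_max` the sums of the
#' `N_w` smallest/largest distances among all pairs (`N_w` = number of
#' within-cluster pairs).
#'
#' @inheritParams davies_bouldin
#' @return C in \[0, 1\]; 0 with a warning when all pair sums coincide.
#' @export
hubert_levine_c <- function(X, labels) {
  z <- check_xy(X, labels)
  pd <- pair_distances(z$X, z$labs)
  nw <- sum(pd$within)
  if (nw == 0 || nw == length(pd$d))
    stop("need at least one within-cluster and one between-cluster pair")
  sw <- sum(pd$d[pd$within])
  ds <- sort(pd$d)
  smin <- sum(ds[seq_len(nw)])
  smax <- sum(ds[seq(length(ds) - nw + 1, length(ds))])
  if (smax == smin) {
    warning("all pair-distance sums coincide; C-index 0 by convention")
    return(0)
  }
  (sw - smin) / (smax - smin)
}

#' Score a clustering with all five validity indices
#'
#' @inheritParams davies_bouldin
#' @param id identifier for the clustering (e.g. "knn_louvain_15").
#' @return one-row data.frame (class `scorecard`) with columns `id`,
#'   `davies_bouldin`, `silhouette`, `calinski_harabasz`, `baker_hubert`,
#'   `hubert_levine`.
#' @export
score_clustering <- function(X, labels, id = "clustering") {
  out <- data.frame(
    id = id,
    davies_bouldin = davies_bouldin(X, labels),
    silhouette = silhouette_index(X, labels),
    calinski_harabasz = calinski_harabasz(X, labels),
    baker_hubert = baker_hubert_gamma(X, labels),
    hubert_levine = hubert_levine_c(X, labels),
    stringsAsFactors = FALSE)
  class(out) <- c("scorecard", class(out))
  out
}

INDEX_DIRECTIONS <- c(davies_bouldin = -1, silhouette = 1,
                      calinski_harabasz = 1, baker_hubert = 1,
                      hubert_levine = -1)

#' Points-based ranking of clusterings over the five indices
#'
#' For each index the single best scorecard earns one point (minimum for
#' Davies-Bouldin and Hubert-Levine, maximum for the other three); an
#' exact tie on an index withholds that point (logged). The clustering
#' with the most points wins; a points tie is broken by comparing the
#' tied clusterings pairwise across all five indices and awarding each
#' pairwise win to the clustering better on the majority of indices, the
#' overall winner being the one with the most pairwise wins (a residual
#' tie falls back to input order, logged).
#'
#' @param scorecards data.frame of scorecards ([score_clustering()] rows).
#' @return object of class `rank_result`: list with `points` (named
#'   integer vector), `winner` (id), `index_winners`, `tiebreak_log`, and
#'   the input `scorecards`.
#' @export
rank_clusterings <- function(scorecards) {
  sc <- as.data.frame(scorecards)
  if (nrow(sc) < 2) stop("ranking needs at least 2 scorecards")
  idx <- names(INDEX_DIRECTIONS)
  if (!all(idx %in% names(sc))) stop("scorecards missing index columns")
  if (anyNA(sc[idx]) || any(!is.finite(as.matrix(sc[idx]))))
    stop("all five indices must be finite for every scorecard")
  points <- setNames(integer(nrow(sc)), sc$id)
  index_winners <- setNames(rep(NA_character_, length(idx)), idx)
  log <- character(0)
  for (m in idx) {
    v <- sc[[m]] * INDEX_DIRECTIONS[m]
    best <- which(v == max(v))
    if (length(best) > 1) {
      log <- c(log, paste0(m, ": exact tie between ",
                           paste(sc$id[best], collapse = ", "),
                           "; point withheld"))
    } else {
      points[best] <- points[best] + 1L
      index_winners[m] <- sc$id[best]
    }
  }
  top <- which(points == max(points))
  if (length(top) == 1) {
    winner <- names(points)[top]
  } else {
    log <- c(log, paste0("points tie between ",
                         paste(names(points)[top], collapse = ", ")))
    wins <- setNames(integer(length(top)), names(points)[top])
    for (a in seq_along(top)) for (b in seq_along(top)) {
      if (a >= b) next
      ia <- top[a]; ib <- top[b]
      va <- as.numeric(sc[ia, idx]) * INDEX_DIRECTIONS
      vb <- as.numeric(sc[ib, idx]) * INDEX_DIRECTIONS
      better_a <- sum(va > vb)
      better_b <- sum(vb > va)
      if (better_a > better_b) wins[a] <- wins[a] + 1L
      else if (better_b > better_a) wins[b] <- wins[b] + 1L
      log <- c(log, paste0("pairwise ", sc$id[ia], " vs ", sc$id[ib], ": ",
                           better_a, "-", better_b))
    }
    cand <- which(wins == max(wins))
    if (length(cand) > 1)
      log <- c(log, "residual tie; falling back to input order")
    winner <- names(wins)[cand[1]]
  }
  structure(list(points = points, winner = winner,
                 index_winners = index_winners, tiebreak_log = log,
                 scorecards = sc),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat("rank_result: winner =", x$winner, "\n")
  pts <- sort(x$points, decreasing = TRUE)
  for (nm in names(pts)) cat(sprintf("  %-28s %d point(s)\n", nm, pts[nm]))
  if (length(x$tiebreak_log)) cat("  tie-break log:\n   ",
                                  paste(x$tiebreak_log, collapse = "\n    "), "\n")
  invisible(x)
}
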