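# Build an igraph subject graph from an edge index matrix (2 x m or m x 2,
# vertex indices into `ids`). Simple, undirected, with method metadata.
subject_graph <- function(edge_idx, ids, method, parameter,
                          warning_flag = FALSE) {
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (length(edge_idx)) {
    if (is.matrix(edge_idx) && ncol(edge_idx) == 2) edge_idx <- t(edge_idx)
    g <- igraph::add_edges(g, as.vector(edge_idx))
  }
  g <- igraph::simplify(g)
  g <- igraph::set_graph_attr(g, "method", method)
  g <- igraph::set_graph_attr(g, "parameter", parameter)
  g <- igraph::set_graph_attr(g, "connected_flag",
                              igraph::is_connected(g) && length(ids) > 0)
  if (warning_flag) g <- igraph::set_graph_attr(g, "warning", TRUE)
  g
}

#' Restrict a feature matrix to the positive subjects of a target
#'
#' Keeps the rows with target value 1 and removes the target column from
#' the feature columns used for network inference.
#'
#' @param matrix complete 0/1 subjects x features matrix.
#' @param target name of a binary column of `matrix`.
#' @return the positive-subject submatrix without the target column.
#' @export
subset_positive <- function(matrix, target) {
  if (!target %in% colnames(matrix)) stop("target column not found: ", target)
  v <- matrix[, target]
  if (!all(v %in% c(0, 1))) stop("target column is not binary")
  pos <- v == 1
  if (sum(pos) < 3) stop("fewer than 3 positive subjects for ", target)
  matrix[pos, setdiff(colnames(matrix), target), drop = FALSE]
}

#' k-nearest-neighbour subject graph
#'
#' Connects every subject to its `k` nearest neighbours under Euclidean
#' distance on the feature vectors, taking the undirected union (so a
#' node's degree may exceed `k` when neighbour relations are asymmetric).
#' Distance ties are broken by subject order (row index).
#'
#' @param matrix numeric subjects x features matrix.
#' @param k neighbourhood size, 1 <= k <= n-1.
#' @return an igraph subject graph with method `"knn"`, parameter `k`.
#' @export
knn_graph <- function(matrix, k) {
  n <- nrow(matrix)
  if (k < 1 || k > n - 1) stop("k must lie in [1, n-1]")
  d <- as.matrix(dist(matrix))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n)[-i])  # ties: lower row index first
    nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
    edges[[i]] <- rbind(i, nb)
  }
  subject_graph(do.call(cbind, edges), rownames(matrix), "knn", k)
}

#' Minimum-k connected kNN graph
#'
#' Returns the kNN union graph at the smallest `k` for which it is
#' connected; minimality is certified on every call by checking that the
#' graph at `k - 1` is disconnected.
#'
#' @param matrix numeric subjects x features matrix (n >= 2).
#' @return an igraph subject graph; graph attribute `parameter` holds the
#'   selected k.
#' @export
min_k_connected <- function(matrix) {
  n <- nrow(matrix)
  if (n < 2) stop("need at least 2 subjects")
  prev <- NULL
  for (k in seq_len(n - 1)) {
    g <- knn_graph(matrix, k)
    if (igraph::is_connected(g)) {
      if (k > 1) stopifnot(!igraph::is_connected(prev))
      return(g)
    }
    prev <- g
  }
  g  # k = n-1 is complete, always connected
}

#' Pearson correlation between subject response vectors
#'
#' @param matrix numeric subjects x features matrix (>= 2 features).
#' @return symmetric subjects x subjects correlation matrix with unit
#'   diagonal; correlations involving a zero-variance subject vector are
#'   set to 0 with a warning.
#' @export
subject_correlation <- function(matrix) {
  if (ncol(matrix) < 2) stop("need at least 2 features per subject")
  cm <- suppressWarnings(cor(t(matrix)))
  if (anyNA(cm)) {
    warning("zero-variance subject vectors: correlations set to 0")
    cm[is.na(cm)] <- 0
  }
  diag(cm) <- 1
  dimnames(cm) <- list(rownames(matrix), rownames(matrix))
  cm
}

#' Correlation-thresholding graph
#'
#' Places an edge between subjects i and j iff `corr[i, j] > threshold`.
#'
#' @param corr symmetric correlation matrix (e.g. [subject_correlation()]).
#' @param threshold edge threshold.
#' @return an igraph subject graph with method `"ct"`.
#' @export
ct_graph <- function(corr, threshold) {
  idx <- which(corr > threshold & upper.tri(corr), arr.ind = TRUE)
  subject_graph(t(unname(idx)), rownames(corr), "ct", threshold)
}

#' Soft-thresholding operator
#'
#' `S(z, t) = sign(z) * max(|z| - t, 0)`, the elementwise kernel of the
#' lasso coordinate-descent update.
#'
#' @param z numeric input.
#' @param t nonnegative threshold.
#' @return thresholded value(s).
#' @export
soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Standardize rows-as-variables input for the lasso methods: returns an
# observations x variables matrix with unit-variance columns; zero-variance
# variables are flagged.
standardize_rows <- function(matrix) {
  x <- t(matrix)  # observations (features) x variables (subjects)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  zv <- s == 0
  s[zv] <- 1
  x <- sweep(sweep(x, 2, mu), 2, s, "/")
  list(x = x, zero_variance = zv)
}

# Shared nodewise-lasso machinery: returns, for each penalty in `penalties`
# (descending), the OR-combined neighbourhood edge index matrix.
mb_edge_sets <- function(matrix, penalties) {
  st <- standardize_rows(matrix)
  x <- st$x
  p <- ncol(x)
  penalties <- sort(penalties, decreasing = TRUE)
  adj <- lapply(seq_along(penalties), function(i) list())
  for (j in seq_len(p)) {
    if (st$zero_variance[j]) next
    others <- which(!st$zero_variance & seq_len(p) != j)
    if (length(others) < 2) next
    fit <- glmnet::glmnet(x[, others, drop = FALSE], x[, j],
                          family = "gaussian", lambda = penalties,
                          standardize = TRUE, intercept = TRUE)
    b <- as.matrix(fit$beta)
    for (i in seq_len(ncol(b))) {
      nb <- others[abs(b[, i]) > 1e-8]
      if (length(nb))
        adj[[i]][[length(adj[[i]]) + 1L]] <- rbind(j, nb)
    }
  }
  lapply(adj, function(a) if (length(a)) do.call(cbind, a) else matrix(0L, 2, 0))
}

#' Meinshausen-Buhlmann neighbourhood-selection graph
#'
#' Fits a lasso regression of each node's (standardized) response vector
#' on all other nodes'; a nonzero coefficient makes the regressor a
#' neighbour. Neighbourhoods are combined with the OR rule into an
#' undirected simple graph. Rows of `matrix` are the graph's nodes and
#' columns act as observations.
#'
#' @param matrix numeric nodes x observations matrix.
#' @param penalty lasso penalty (glmnet lambda), > 0.
#' @return an igraph subject graph with method `"mb"`.
#' @export
mb_graph <- function(matrix, penalty) {
  if (penalty <= 0) stop("penalty must be positive")
  es <- mb_edge_sets(matrix, penalty)
  subject_graph(es[[1]], rownames(matrix), "mb", penalty)
}

#' Graphical lasso subject graph
#'
#' Estimates an L1-penalized sparse inverse covariance matrix over the
#' rows of `matrix` (block coordinate descent, one lasso subproblem per
#' variable; see [glasso_fit()]) and places an edge wherever the
#' off-diagonal precision entry exceeds 1e-8 in magnitude. The working
#' covariance is the subject correlation matrix.
#'
#' @param matrix numeric nodes x observations matrix.
#' @param penalty L1 penalty rho, > 0.
#' @return an igraph subject graph with method `"glasso"`.
#' @export
glasso_graph <- function(matrix, penalty) {
  if (penalty <= 0) stop("penalty must be positive")
  s <- subject_correlation(matrix)
  fit <- glasso_fit(s, penalty)
  edge_idx <- which(abs(fit$theta) > 1e-8 & upper.tri(fit$theta), arr.ind = TRUE)
  subject_graph(t(unname(edge_idx)), rownames(matrix), "glasso", penalty)
}

#' Graphical lasso estimator
#'
#' Solves `max_Theta log det Theta - tr(S Theta) - rho ||Theta||_1`
#' (off-diagonal penalty applied to all entries) by block coordinate
#' descent: each column of the working covariance `W` is updated by
#' solving a lasso subproblem with coordinate descent and
#' soft-thresholding, cycling until the mean absolute change in `W` falls
#' below `tol` times the mean absolute off-diagonal of `S`.
#'
#' @param s covariance (or correlation) matrix.
#' @param rho penalty, > 0.
#' @param maxit outer iteration cap; non-convergence is an error.
#' @param tol relative convergence tolerance.
#' @param warm optional warm start: a previous fit's `$w` and `$beta`.
#' @return list with `w` (estimated covariance, positive definite),
#'   `theta` (precision estimate), `beta`, `iterations`, `converged`.
#' @export
glasso_fit <- function(s, rho, maxit = 200L, tol = 1e-5, warm = NULL) {
  s <- as.matrix(s)
  if (rho <= 0) stop("rho must be positive")
  w0 <- if (!is.null(warm)) warm$w else matrix(0, 0, 0)
  b0 <- if (!is.null(warm)) warm$beta else matrix(0, 0, 0)
  res <- glasso_cpp(s, rho, as.integer(maxit), tol, w0, b0)
  if (!res$converged)
    stop("graphical lasso failed to converge in ", maxit,
         " iterations (rho=", rho, ", tol=", tol, ")")
  dimnames(res$w) <- dimnames(res$theta) <- dimnames(s)
  res
}

#' Inference along a monotone parameter path
#'
#' Computes graphs along a decreasing-sparsity path: for `"ct"`, the
#' descending unique off-diagonal correlations as thresholds; for `"mb"`
#' and `"glasso"`, a 30-point logarithmic penalty path from the null
#' penalty (empty graph) down to `path_min_ratio` times it.
#'
#' @param matrix numeric nodes x observations matrix.
#' @param method `"mb"`, `"glasso"` or `"ct"`.
#' @param n_path number of path points for the penalized methods.
#' @param path_min_ratio smallest penalty as a fraction of the null
#'   penalty.
#' @param stop_when_connected if TRUE, the path is truncated at the first
#'   connected graph (sparsest-connected search).
#' @return list with `graphs` (list of igraph graphs, sparsest first) and
#'   `parameters`.
#' @export
inference_path <- function(matrix, method = c("mb", "glasso", "ct"),
                           n_path = 30L, path_min_ratio = 0.1,
                           stop_when_connected = FALSE) {
  method <- match.arg(method)
  ids <- rownames(matrix)
  if (method == "ct") {
    cm <- subject_correlation(matrix)
    vals <- sort(unique(cm[upper.tri(cm)]), decreasing = TRUE)
    params <- if (length(vals) > 200)
      unname(quantile(vals, seq(1, 0, length.out = n_path), type = 1))
    else vals
    graphs <- list()
    for (t in params) {
      g <- ct_graph(cm, t)
      graphs[[length(graphs) + 1L]] <- g
      if (stop_when_connected && igraph::is_connected(g)) break
    }
    return(list(graphs = graphs, parameters = params[seq_along(graphs)]))
  }
  cm <- subject_correlation(matrix)
  lam_max <- max(abs(cm[upper.tri(cm)]))
  if (lam_max <= 0) lam_max <- 1
  params <- exp(seq(log(lam_max), log(lam_max * path_min_ratio),
                    length.out = n_path))
  if (method == "mb") {
    es <- mb_edge_sets(matrix, params)
    graphs <- list()
    for (i in seq_along(params)) {
      g <- subject_graph(es[[i]], ids, "mb", params[i])
      graphs[[length(graphs) + 1L]] <- g
      if (stop_when_connected && igraph::is_connected(g)) break
    }
    return(list(graphs = graphs, parameters = params[seq_along(graphs)]))
  }
  # glasso: warm-started sweep from sparsest (largest rho) down
  graphs <- list()
  warm <- NULL
  for (i in seq_along(params)) {
    fit <- glasso_fit(cm, params[i], warm = warm)
    warm <- fit
    edge_idx <- which(abs(fit$theta) > 1e-8 & upper.tri(fit$theta), arr.ind = TRUE)
    g <- subject_graph(t(unname(edge_idx)), ids, "glasso", params[i])
    graphs[[length(graphs) + 1L]] <- g
    if (stop_when_connected && igraph::is_connected(g)) break
  }
  list(graphs = graphs, parameters = params[seq_along(graphs)])
}

#' Sparsest connected graph along an inference path
#'
#' Scans the method's monotone parameter path from sparsest to densest
#' and returns the first (sparsest) connected graph, mirroring the
#' minimum-k rule used for kNN graphs. If no path point is connected, the
#' densest graph is returned with graph attribute `warning = TRUE`.
#'
#' @inheritParams inference_path
#' @return an igraph subject graph.
#' @export
sparsest_connected <- function(matrix, method = c("mb", "glasso", "ct"),
                               n_path = 30L, path_min_ratio = 0.1) {
  method <- match.arg(method)
  if (method == "ct") {
    # connectivity is monotone in the threshold (edge sets are nested),
    # so the exact sparsest-connected threshold is found by binary search
    # over the descending unique off-diagonal correlations
    cm <- subject_correlation(matrix)
    vals <- sort(unique(cm[upper.tri(cm)]), decreasing = TRUE)
    lo <- 1L; hi <- length(vals)
    if (!igraph::is_connected(ct_graph(cm, vals[hi]))) {
      g <- ct_graph(cm, vals[hi])
      warning("no connected graph on the ct path; returning the densest point")
      return(igraph::set_graph_attr(g, "warning", TRUE))
    }
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (igraph::is_connected(ct_graph(cm, vals[mid]))) hi <- mid else lo <- mid + 1L
    }
    return(ct_graph(cm, vals[hi]))
  }
  # a zero-variance subject vector is an isolated node for both lasso
  # methods at every penalty, so connectivity is unreachable: jump
  # straight to the densest path point instead of scanning
  if (any(apply(matrix, 1, sd) == 0)) {
    cm <- suppressWarnings(subject_correlation(matrix))
    lam_max <- max(abs(cm[upper.tri(cm)]))
    if (lam_max <= 0) lam_max <- 1
    pen <- lam_max * path_min_ratio
    g <- if (method == "mb") suppressWarnings(mb_graph(matrix, pen))
         else suppressWarnings(glasso_graph(matrix, pen))
    warning("no connected graph on the ", method,
            " path; returning the densest path point")
    return(igraph::set_graph_attr(g, "warning", TRUE))
  }
  path <- inference_path(matrix, method, n_path, path_min_ratio,
                         stop_when_connected = TRUE)
  g <- path$graphs[[length(path$graphs)]]
  if (!igraph::is_connected(g)) {
    warning("no connected graph on the ", method,
            " path; returning the densest path point")
    g <- igraph::set_graph_attr(g, "warning", TRUE)
  }
  g
}
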