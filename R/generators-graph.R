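#' Sample a planted-partition graph
#'
#' Draws an undirected simple graph in which node pairs inside the same
#' planted block are connected with probability `p_in` and pairs in
#' different blocks with probability `p_out` (`p_out < p_in`).
#'
#' @param n_nodes number of nodes.
#' @param n_clusters number of equal-sized (up to remainder) blocks.
#' @param p_in,p_out within/between-block edge probabilities.
#' @param seed integer seed.
#' @return a list with `graph` (an igraph subject graph, method
#'   `"planted"`) and `partition` (the planted [partition()] ground truth).
#' @export
generate_planted_graph <- function(n_nodes, n_clusters, p_in, p_out, seed = 1L) {
  if (p_out > p_in || (p_out == p_in && p_in > 0))
    stop("p_out must be strictly smaller than p_in")
  if (p_in > 1 || p_out < 0) stop("p_in and p_out must be probabilities")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  sizes <- rep(n_nodes %/% n_clusters, n_clusters)
  rem <- n_nodes - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  labels <- rep(seq_len(n_clusters), times = sizes)
  ids <- sprintf("N%03d", seq_len(n_nodes))
  pr <- combn(n_nodes, 2)
  same <- labels[pr[1, ]] == labels[pr[2, ]]
  p <- ifelse(same, p_in, p_out)
  keep <- runif(ncol(pr)) < p
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  igraph::V(g)$name <- ids
  if (any(keep)) g <- igraph::add_edges(g, as.vector(pr[, keep, drop = FALSE]))
  g <- igraph::set_graph_attr(g, "method", "planted")
  g <- igraph::set_graph_attr(g, "parameter", p_in)
  part <- partition(setNames(labels - 1L, ids), method = "planted", seed = seed)
  list(graph = g, partition = part)
}

#' Gaussian samples with a known sparse precision matrix
#'
#' Builds a sparse positive-definite precision matrix (a chain, or a
#' random sparse pattern), draws `n_samples` rows from the corresponding
#' zero-mean multivariate normal, and returns the true conditional
#' independence graph, for benchmarking the lasso-based inference methods.
#'
#' @param n_samples number of draws (rows).
#' @param n_variables number of variables (columns), at least 2.
#' @param structure `"chain"` (edges i -- i+1, partial correlation 0.4) or
#'   `"random"` (each pair an edge with probability 0.15, weights
#'   +/- 0.3; the diagonal is jittered upward until positive definite).
#' @param seed integer seed.
#' @return list with `samples` (n x p matrix), `edges` (2-column matrix of
#'   true edges, i < j), `precision` and `covariance`.
#' @export
generate_gaussian_precision <- function(n_samples, n_variables,
                                        structure = c("chain", "random"),
                                        seed = 1L) {
  structure <- match.arg(structure)
  if (n_variables < 2) stop("n_variables must be at least 2")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  p <- n_variables
  omega <- diag(p)
  if (structure == "chain") {
    for (i in seq_len(p - 1)) omega[i, i + 1] <- omega[i + 1, i] <- -0.4
  } else {
    pr <- combn(p, 2)
    on_edge <- runif(ncol(pr)) < 0.15
    w <- sample(c(-0.3, 0.3), ncol(pr), replace = TRUE)
    for (e in which(on_edge)) {
      i <- pr[1, e]; j <- pr[2, e]
      omega[i, j] <- omega[j, i] <- w[e]
    }
    # jitter the diagonal until positive definite
    while (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) < 0.05)
      diag(omega) <- diag(omega) + 0.1
  }
  if (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("internal error: precision matrix not positive definite")
  sigma <- solve(omega)
  L <- chol(sigma)
  z <- matrix(rnorm(n_samples * p), n_samples, p)
  x <- z %*% L
  colnames(x) <- sprintf("V%02d", seq_len(p))
  ed <- which(abs(omega) > 1e-12 & upper.tri(omega), arr.ind = TRUE)
  colnames(ed) <- c("i", "j")
  list(samples = x, edges = unname(ed), precision = omega, covariance = sigma)
}

#' Edge-recovery F1 score of an inferred graph against a true edge set
#'
#' @param graph an igraph graph whose vertices are ordered/named like the
#'   variables indexing `true_edges`.
#' @param true_edges 2-column matrix of true edges (vertex indices, i < j).
#' @return F1 = 2 * precision * recall / (precision + recall); 0 when the
#'   inferred graph has no edges.
#' @export
edge_recovery_f1 <- function(graph, true_edges) {
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) == 0) return(0)
  est <- key(el[, 1], el[, 2])
  tru <- key(true_edges[, 1], true_edges[, 2])
  tp <- length(intersect(est, tru))
  if (tp == 0) return(0)
  prec <- tp / length(est)
  rec <- tp / length(tru)
  2 * prec * rec / (prec + rec)
}
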