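#' Cluster composition profiles with small-cluster suppression
#'
#' For every cluster, computes the percentage of members with value 1 for
#' each feature. Clusters smaller than `min_size` are flagged suppressed:
#' their percentages are withheld from the human-readable output (print
#' and CSV), which reports their sizes only, protecting small groups of
#' subjects from re-identification.
#'
#' @param X numeric 0/1 subjects x features matrix.
#' @param labels a [partition()] or label vector over the rows of X.
#' @param min_size suppression threshold (default 10: clusters with fewer
#'   than 10 members are suppressed).
#' @return object of class `cluster_profiles`: list with `percent`
#'   (features x clusters matrix, suppressed clusters NA), `sizes`,
#'   `suppressed` (logical), `min_size`.
#' @export
profile_clusters <- function(X, labels, min_size = 10) {
  labs <- partition_labels(labels)
  X <- as.matrix(X)
  if (!is.null(names(labs)) && !is.null(rownames(X))) labs <- labs[rownames(X)]
  if (length(labs) != nrow(X) || anyNA(labs))
    stop("labels must cover exactly the rows of X")
  cl <- sort(unique(labs))
  sizes <- vapply(cl, function(c) sum(labs == c), integer(1))
  pct <- vapply(cl, function(c)
    100 * colMeans(X[labs == c, , drop = FALSE]), numeric(ncol(X)))
  if (is.null(dim(pct))) pct <- matrix(pct, nrow = ncol(X))
  dimnames(pct) <- list(colnames(X), paste0("cluster_", cl))
  suppressed <- sizes < min_size
  full <- pct
  full[, suppressed] <- NA_real_
  structure(list(percent = full, percent_all = pct, sizes = setNames(sizes, colnames(full)),
                 suppressed = setNames(suppressed, colnames(full)),
                 min_size = min_size),
            class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, max_features = 12, ...) {
  vis <- !x$suppressed
  cat("cluster_profiles:", length(x$sizes), "clusters (",
      sum(x$suppressed), "suppressed, size <", x$min_size, ")\n")
  cat("  sizes:", paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = " "), "\n")
  if (any(vis)) {
    m <- round(x$percent[seq_len(min(max_features, nrow(x$percent))), vis, drop = FALSE], 1)
    print(m)
  }
  invisible(x)
}

#' Write cluster profiles as CSV (features as rows, clusters as columns)
#'
#' Suppressed clusters are omitted from the percentage columns; their
#' sizes are still recorded in the `size` header row.
#'
#' @param profiles a [profile_clusters()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  vis <- !profiles$suppressed
  m <- profiles$percent[, vis, drop = FALSE]
  out <- rbind(size = profiles$sizes[vis], m)
  write.csv(data.frame(feature = rownames(out), out, check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

#' Agreement between a clustering's profiles and the planted profiles
#'
#' Matches each non-suppressed cluster to its majority planted cluster
#' (the planted label held by most of its members) and compares, feature
#' by feature, the cluster's majority response (percentage above 50) with
#' the planted cluster's empirical majority response. Returns the
#' size-weighted mean agreement over non-suppressed clusters.
#'
#' @param X numeric 0/1 subjects x features matrix.
#' @param labels clustering to assess.
#' @param truth named planted-cluster labels covering the rows of X.
#' @param min_size clusters below this size are ignored.
#' @return agreement fraction in \[0, 1\].
#' @export
profile_agreement <- function(X, labels, truth, min_size = 10) {
  labs <- partition_labels(labels)
  X <- as.matrix(X)
  if (!is.null(names(labs))) labs <- labs[rownames(X)]
  truth <- truth[rownames(X)]
  stopifnot(!anyNA(labs), !anyNA(truth))
  planted_major <- do.call(rbind, lapply(split(seq_len(nrow(X)), truth),
    function(ix) colMeans(X[ix, , drop = FALSE]) > 0.5))
  agree <- 0; wt <- 0
  for (c in unique(labs)) {
    ix <- which(labs == c)
    if (length(ix) < min_size) next
    major <- colMeans(X[ix, , drop = FALSE]) > 0.5
    tmaj <- names(which.max(table(truth[ix])))
    a <- mean(major == planted_major[tmaj, ])
    agree <- agree + length(ix) * a
    wt <- wt + length(ix)
  }
  if (wt == 0) stop("no cluster reaches min_size")
  agree / wt
}

#' Smallest possible recruitment-chain length
#'
#' For a respondent-driven sample in which every participant recruits
#' `branching` others, the shortest chain reaching `n_participants`
#' people has length `log_branching(n_participants)`.
#'
#' @param n_participants number of participants reached (>= 1).
#' @param branching recruits per participant (>= 2).
#' @return the chain length (real number).
#' @export
min_chain_length <- function(n_participants, branching) {
  if (n_participants < 1) stop("n_participants must be at least 1")
  if (branching < 2) stop("branching must be at least 2")
  log(n_participants) / log(branching)
}

#' Export / read a cluster-annotated graph as GraphML
#'
#' Writes the graph with node attributes `subject_id` and `cluster` so
#' that downstream tools can visualize the clustering; the companion
#' reader restores the same edge set and labels (lossless round trip).
#'
#' @param graph an igraph subject graph.
#' @param labels a [partition()] or named label vector covering the
#'   graph's nodes.
#' @param path output path.
#' @return `path` invisibly (writer); a list `graph`, `labels` (reader).
#' @export
export_annotated_graph <- function(graph, labels, path) {
  labs <- partition_labels(labels)
  ids <- igraph::V(graph)$name
  if (!all(ids %in% names(labs))) stop("labels must cover all graph nodes")
  g <- igraph::set_vertex_attr(graph, "subject_id", value = ids)
  g <- igraph::set_vertex_attr(g, "cluster", value = as.integer(labs[ids]))
  ok <- tryCatch({ igraph::write_graph(g, path, format = "graphml"); TRUE },
                 error = function(e)
                   stop("failed to write GraphML to ", path, ": ",
                        conditionMessage(e)))
  invisible(path)
}

#' @rdname export_annotated_graph
#' @export
read_annotated_graph <- function(path) {
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e)
                  stop("failed to read GraphML from ", path, ": ",
                       conditionMessage(e)))
  ids <- igraph::vertex_attr(g, "subject_id")
  igraph::V(g)$name <- ids
  labs <- setNames(igraph::vertex_attr(g, "cluster"), ids)
  list(graph = g, labels = labs)
}

#' Write an edge-list TSV for a subject graph
#'
#' @param graph an igraph subject graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write.table(el, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
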