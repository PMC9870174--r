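#' Partition of a subject graph
#'
#' @param labels named integer-ish vector (names = subject ids); labels
#'   are renumbered to contiguous integers starting at 0, preserving
#'   first-appearance order.
#' @param method one of `"louvain"`, `"leiden"`, `"nbr_vat"`,
#'   `"nbr_integrity"` (or a bookkeeping string).
#' @param attack_set optional attack set (for the NBR methods).
#' @param seed seed used by the clustering run.
#' @return object of class `partition` with fields `labels`, `method`,
#'   `attack_set`, `n_clusters`, `seed`.
#' @export
partition <- function(labels, method = "manual", attack_set = NULL, seed = NA_integer_) {
  if (is.null(names(labels))) stop("labels must be named by subject id")
  lv <- unique(labels)
  relab <- setNames(seq_along(lv) - 1L, as.character(lv))
  labs <- setNames(unname(relab[as.character(labels)]), names(labels))
  structure(list(labels = labs, method = method, attack_set = attack_set,
                 n_clusters = length(lv), seed = seed),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition (", x$method, "): ", length(x$labels), " subjects in ",
      x$n_clusters, " clusters\n", sep = "")
  sz <- sort(table(x$labels), decreasing = TRUE)
  cat("  sizes:", paste(head(as.integer(sz), 12), collapse = ", "),
      if (length(sz) > 12) "..." else "", "\n")
  invisible(x)
}

# coerce a partition or named vector to a named label vector
partition_labels <- function(labels) {
  if (inherits(labels, "partition")) labels$labels else labels
}

as_membership_partition <- function(graph, membership, method, seed,
                                    attack_set = NULL) {
  partition(setNames(as.integer(membership) - min(as.integer(membership)),
                     igraph::V(graph)$name),
            method = method, attack_set = attack_set, seed = seed)
}

#' Louvain modularity clustering
#'
#' Modularity-maximizing multilevel (local moving + aggregation)
#' heuristic, delegated to igraph, at resolution 1. The number of
#' clusters is decided by the algorithm.
#'
#' @param graph an igraph subject graph with at least one edge.
#' @param seed integer seed (the heuristic's vertex sweeps are random).
#' @return a [partition()] with method `"louvain"`.
#' @export
louvain_partition <- function(graph, seed = 1L) {
  if (igraph::ecount(graph) < 1) stop("louvain requires at least one edge")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  cl <- igraph::cluster_louvain(graph, resolution = 1)
  as_membership_partition(graph, igraph::membership(cl), "louvain", seed)
}

#' Leiden modularity clustering
#'
#' Louvain with a refinement phase; communities are guaranteed to induce
#' connected subgraphs, which is asserted on every call. Delegated to
#' igraph with the modularity objective at resolution 1.
#'
#' @inheritParams louvain_partition
#' @return a [partition()] with method `"leiden"`.
#' @export
leiden_partition <- function(graph, seed = 1L) {
  if (igraph::ecount(graph) < 1) stop("leiden requires at least one edge")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = 1, n_iterations = 3)
  part <- as_membership_partition(graph, igraph::membership(cl), "leiden", seed)
  stopifnot(communities_connected(graph, part))
  part
}

# every community induces a connected subgraph?
communities_connected <- function(graph, part) {
  labs <- partition_labels(part)
  all(vapply(split(names(labs), labs), function(memb) {
    igraph::is_connected(igraph::induced_subgraph(graph, memb))
  }, logical(1)))
}

#' Resilience-based node-removal clustering (NBR-Clust)
#'
#' Finds an attack set approximately minimizing the chosen resilience
#' measure ([greedy_attack_set()]), removes it, and takes the remaining
#' connected components as clusters. Attack-set nodes are then assigned
#' to the adjacent cluster with which they share the most edges (ties:
#' larger cluster, then lower label); nodes with no clustered neighbour
#' get their own cluster. Disconnected input is clustered one connected
#' component at a time (components with fewer than 3 nodes become
#' clusters directly).
#'
#' @param graph an igraph subject graph.
#' @param measure `"vat"` or `"integrity"`.
#' @param max_fraction attack-set size cap (see [greedy_attack_set()]).
#' @return a [partition()] with method `"nbr_vat"` or `"nbr_integrity"`
#'   and the attack set recorded.
#' @export
nbr_clust <- function(graph, measure = c("vat", "integrity"),
                      max_fraction = 0.25) {
  measure <- match.arg(measure)
  comp <- igraph::components(graph)
  labels <- integer(0)
  attack <- character(0)
  next_label <- 0L
  for (ci in seq_len(comp$no)) {
    memb <- igraph::V(graph)$name[comp$membership == ci]
    if (length(memb) < 3) {
      labels[memb] <- next_label
      next_label <- next_label + 1L
      next
    }
    sub <- igraph::induced_subgraph(graph, memb)
    rv <- greedy_attack_set(sub, measure, max_fraction)
    S <- rv$attack_set
    if (length(S) >= length(memb)) stop("attack set covers all nodes")
    attack <- c(attack, S)
    rest <- setdiff(memb, S)
    rg <- igraph::induced_subgraph(sub, rest)
    rc <- igraph::components(rg)
    labs <- setNames(next_label + rc$membership - 1L, igraph::V(rg)$name)
    next_label <- next_label + rc$no
    labs <- reassign_attack_nodes(sub, labs, S)
    next_label <- max(next_label, max(labs) + 1L)
    labels[names(labs)] <- labs
  }
  partition(labels[igraph::V(graph)$name],
            method = paste0("nbr_", measure), attack_set = attack)
}

# assign attack-set nodes to neighbouring clusters by edge majority;
# ties -> larger cluster, then lower label; repeat so nodes whose only
# neighbours are other attack nodes attach once those are placed; a node
# with no labeled neighbour at all becomes its own cluster.
reassign_attack_nodes <- function(graph, labs, S) {
  pending <- S
  repeat {
    placed <- character(0)
    sizes <- table(labs)
    for (v in pending) {
      nb <- igraph::V(graph)$name[as.integer(igraph::neighbors(graph, v))]
      nb_lab <- labs[intersect(nb, names(labs))]
      if (length(nb_lab) == 0) next
      cnt <- table(nb_lab)
      cand <- names(cnt)[cnt == max(cnt)]
      if (length(cand) > 1) {
        csz <- sizes[cand]
        csz[is.na(csz)] <- 0
        cand <- cand[csz == max(csz)]
        if (length(cand) > 1) cand <- cand[order(as.integer(cand))][1]
      }
      labs[v] <- as.integer(cand)
      placed <- c(placed, v)
    }
    pending <- setdiff(pending, placed)
    if (length(pending) == 0 || length(placed) == 0) break
  }
  if (length(pending)) {
    nl <- max(labs) + 1L
    for (v in pending) { labs[v] <- nl; nl <- nl + 1L }
  }
  labs
}

#' Cluster a subject graph with one of the four study methods
#'
#' @param graph an igraph subject graph.
#' @param method `"louvain"`, `"leiden"`, `"nbr_vat"` or
#'   `"nbr_integrity"`.
#' @param seed seed for the modularity heuristics.
#' @return a [partition()].
#' @export
cluster_graph <- function(graph, method = c("louvain", "leiden", "nbr_vat",
                                            "nbr_integrity"), seed = 1L) {
  method <- match.arg(method)
  switch(method,
         louvain = louvain_partition(graph, seed),
         leiden = leiden_partition(graph, seed),
         nbr_vat = nbr_clust(graph, "vat"),
         nbr_integrity = nbr_clust(graph, "integrity"))
}

#' Write a partition as CSV plus JSON metadata
#'
#' Two-column CSV (`subject_id`, `cluster`) and a `<path>.meta.json` with
#' the method, seed, cluster count and attack set.
#'
#' @param part a [partition()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "partition"))
  write.csv(data.frame(subject_id = names(part$labels),
                       cluster = unname(part$labels)),
            path, row.names = FALSE)
  meta <- list(method = part$method, n_clusters = part$n_clusters,
               seed = part$seed, attack_set = part$attack_set)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
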