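# Size of the largest connected component of graph minus the node set S
# (0 when nothing remains).
cmax_after_removal <- function(graph, S) {
  keep <- setdiff(igraph::V(graph)$name, S)
  if (length(keep) == 0) return(0L)
  sub <- igraph::induced_subgraph(graph, keep)
  max(igraph::components(sub)$csize)
}

# Constructor: asserts the defining identity of each measure.
resilience_value <- function(measure, graph, S) {
  n <- igraph::vcount(graph)
  S <- as.character(S)
  cmax <- cmax_after_removal(graph, S)
  if (measure == "integrity") {
    value <- length(S) + cmax
    stopifnot(value == length(S) + cmax)
  } else if (measure == "vat") {
    if (length(S) == 0) stop("VAT requires a nonempty attack set")
    if (length(S) >= n) stop("VAT requires a strict subset of the vertices")
    value <- length(S) / (n - length(S) - cmax + 1)
    stopifnot(isTRUE(all.equal(value, length(S) / (n - length(S) - cmax + 1))))
  } else stop("unknown measure: ", measure)
  structure(list(measure = measure, value = value, attack_set = S,
                 cmax = cmax, n = n),
            class = "resilience_value")
}

#' @export
print.resilience_value <- function(x, ...) {
  cat(x$measure, "=", format(x$value), "with |S| =", length(x$attack_set),
      "and largest remaining component", x$cmax, "\n")
  invisible(x)
}

#' Integrity of a graph under a given attack set
#'
#' Evaluates `|S| + Cmax(V - S)`, where `Cmax` is the size of the largest
#' connected component remaining after deleting the attack set `S`.
#'
#' @param graph an igraph subject graph.
#' @param S character vector of node names (may be empty).
#' @return a `resilience_value` (fields `value`, `attack_set`, `cmax`).
#' @export
integrity_of <- function(graph, S = character(0)) {
  stopifnot(all(S %in% igraph::V(graph)$name))
  resilience_value("integrity", graph, S)
}

#' Vertex attack tolerance of a graph under a given attack set
#'
#' Evaluates `|S| / (|V| - |S| - Cmax(V - S) + 1)`: the attack-set size
#' relative to the number of nodes stranded outside the largest remaining
#' component (plus one). `S` must be a nonempty strict subset of the
#' vertices (the empty set would trivially minimize the measure).
#'
#' @inheritParams integrity_of
#' @return a `resilience_value`.
#' @export
vat_of <- function(graph, S) {
  stopifnot(all(S %in% igraph::V(graph)$name))
  resilience_value("vat", graph, S)
}

# Enumerate connected components over an adjacency list restricted to
# `keep` (logical); returns max component size. Much faster than building
# igraph subgraphs inside the exponential brute-force search.
adj_cmax <- function(adj, keep) {
  n <- length(adj)
  seen <- !keep
  best <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    size <- 0L
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
    }
    if (size > best) best <- size
  }
  best
}

#' Exact minimum of a resilience measure by subset enumeration
#'
#' Enumerates every admissible attack set (all subsets for integrity;
#' nonempty strict subsets for VAT) on graphs with at most 15 nodes and
#' returns the global minimum. Ties are broken toward the smaller attack
#' set, then lexicographically by node names. Intended as a testing
#' oracle for [greedy_attack_set()].
#'
#' @param graph an igraph graph with at most 15 nodes.
#' @param measure `"vat"` or `"integrity"`.
#' @return a `resilience_value` attaining the global minimum.
#' @export
brute_force_min <- function(graph, measure = c("vat", "integrity")) {
  measure <- match.arg(measure)
  ids <- igraph::V(graph)$name
  n <- length(ids)
  if (n > 15) stop("brute force refused for graphs with more than 15 nodes")
  adj <- lapply(seq_len(n), function(i)
    as.integer(igraph::neighbors(graph, i)))
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    inS <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0
    k <- sum(inS)
    if (measure == "vat" && (k == 0 || k == n)) next
    cmax <- adj_cmax(adj, !inS)
    value <- if (measure == "integrity") k + cmax
             else k / (n - k - cmax + 1)
    cand <- list(value = value, k = k, S = sort(ids[inS]))
    if (is.null(best) || value < best$value - 1e-12 ||
        (abs(value - best$value) <= 1e-12 &&
         (k < best$k || (k == best$k &&
          paste(cand$S, collapse = ",") < paste(best$S, collapse = ","))))) {
      best <- cand
    }
  }
  resilience_value(measure, graph, best$S)
}

#' Greedy betweenness-prefix attack set
#'
#' Approximate minimization of a resilience measure: nodes are removed one
#' at a time in order of (recomputed) betweenness centrality, ties broken
#' by node order; every prefix of this removal sequence (the empty prefix
#' included for integrity) is a candidate attack set, up to
#' `ceiling(n / 4)` nodes, and the prefix with the smallest measure value
#' is returned. The result is always an upper bound on the exact minimum.
#'
#' @param graph a connected igraph graph with at least 3 nodes.
#' @param measure `"vat"` or `"integrity"`.
#' @param max_fraction prefix-length cap as a fraction of n.
#' @return a `resilience_value` for the best prefix.
#' @export
greedy_attack_set <- function(graph, measure = c("vat", "integrity"),
                              max_fraction = 0.25) {
  measure <- match.arg(measure)
  n <- igraph::vcount(graph)
  if (n < 3) stop("greedy attack search needs at least 3 nodes")
  if (!igraph::is_connected(graph)) stop("greedy attack search expects a connected graph")
  cap <- ceiling(n * max_fraction)
  work <- graph
  prefix <- character(0)
  best <- if (measure == "integrity") integrity_of(graph, character(0)) else NULL
  for (step in seq_len(cap)) {
    bt <- igraph::betweenness(work)
    pick <- igraph::V(work)$name[which.max(bt)]  # which.max: first = lowest index
    prefix <- c(prefix, pick)
    work <- igraph::delete_vertices(work, pick)
    rv <- resilience_value(measure, graph, prefix)
    if (is.null(best) || rv$value < best$value) best <- rv
  }
  best
}
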