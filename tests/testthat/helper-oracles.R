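# Independent brute-force oracles and small graph fixtures used across
# the test files. All oracles are written as plain loops over the
# definitions, deliberately sharing no code with the package internals.

euclid <- function(a, b) sqrt(sum((a - b)^2))

oracle_davies_bouldin <- function(X, labs) {
  labs <- as.integer(factor(labs))
  k <- max(labs)
  cent <- lapply(1:k, function(i) colMeans(X[labs == i, , drop = FALSE]))
  sig <- sapply(1:k, function(i) {
    pts <- X[labs == i, , drop = FALSE]
    mean(apply(pts, 1, euclid, b = cent[[i]]))
  })
  db <- 0
  for (i in 1:k) {
    worst <- -Inf
    for (j in 1:k) {
      if (j == i) next
      r <- (sig[i] + sig[j]) / euclid(cent[[i]], cent[[j]])
      if (r > worst) worst <- r
    }
    db <- db + worst
  }
  db / k
}

oracle_silhouette <- function(X, labs) {
  labs <- as.integer(factor(labs))
  n <- nrow(X)
  s <- numeric(n)
  for (i in 1:n) {
    same <- which(labs == labs[i] & seq_len(n) != i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(sapply(same, function(j) euclid(X[i, ], X[j, ])))
    b <- Inf
    for (cl in setdiff(unique(labs), labs[i])) {
      others <- which(labs == cl)
      m <- mean(sapply(others, function(j) euclid(X[i, ], X[j, ])))
      if (m < b) b <- m
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_calinski_harabasz <- function(X, labs) {
  labs <- as.integer(factor(labs))
  n <- nrow(X); k <- max(labs)
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (cl in 1:k) {
    pts <- X[labs == cl, , drop = FALSE]
    cent <- colMeans(pts)
    B <- B + nrow(pts) * sum((cent - grand)^2)
    for (r in seq_len(nrow(pts))) W <- W + sum((pts[r, ] - cent)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

oracle_gamma <- function(X, labs) {
  n <- nrow(X)
  dw <- c(); db <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- euclid(X[i, ], X[j, ])
    if (labs[i] == labs[j]) dw <- c(dw, d) else db <- c(db, d)
  }
  sp <- 0; sm <- 0
  for (a in dw) for (b in db) {
    if (a < b) sp <- sp + 1
    if (a > b) sm <- sm + 1
  }
  (sp - sm) / (sp + sm)
}

oracle_c_index <- function(X, labs) {
  n <- nrow(X)
  all_d <- c(); dw <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- euclid(X[i, ], X[j, ])
    all_d <- c(all_d, d)
    if (labs[i] == labs[j]) dw <- c(dw, d)
  }
  nw <- length(dw)
  sorted <- sort(all_d)
  smin <- sum(sorted[1:nw])
  smax <- sum(rev(sorted)[1:nw])
  (sum(dw) - smin) / (smax - smin)
}

# -- fixtures ----------------------------------------------------------

star_graph <- function(leaves = 5) {
  g <- igraph::make_star(leaves + 1, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("hub", paste0("leaf", seq_len(leaves)))
  g
}

path_graph5 <- function() {
  g <- igraph::make_ring(5, circular = FALSE)
  igraph::V(g)$name <- paste0("p", 1:5)
  g
}

# two 5-cliques joined through one bridge node (11 nodes)
bridge_graph <- function() {
  g <- igraph::make_empty_graph(11, directed = FALSE)
  igraph::V(g)$name <- c(paste0("a", 1:5), paste0("b", 1:5), "bridge")
  for (i in 1:4) for (j in (i + 1):5) {
    g <- igraph::add_edges(g, c(i, j))
    g <- igraph::add_edges(g, c(5 + i, 5 + j))
  }
  igraph::add_edges(g, c(1, 11, 6, 11))
}

clique_graph <- function(n = 6) {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0("k", seq_len(n))
  g
}

random_connected_graph <- function(n, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, runif(1, 0.25, 0.6))
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# random labeled instance for the validity-index oracles
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(10:40, 1)
  p <- sample(2:5, 1)
  k <- sample(2:4, 1)
  X <- matrix(rnorm(n * p), n, p)
  repeat {
    labs <- sample(1:k, n, replace = TRUE)
    if (length(unique(labs)) >= 2) break
  }
  list(X = X, labs = labs)
}

# the six clustering score rows printed for the correlation-thresholding
# HIV graphs (Louvain vs NBR-integrity at 15/20/64 attributes)
printed_scorecards <- function() {
  data.frame(
    id = c("louvain_15", "louvain_20", "louvain_64",
           "integrity_15", "integrity_20", "integrity_64"),
    davies_bouldin = c(6.5642, 5.5995, 4.4396, 3.9165, 2.8065, 1.2588),
    silhouette = c(-0.2268, 0.0407, 0.0304, -0.2125, -0.1429, 0.2572),
    calinski_harabasz = c(8.3909, 18.7714, 18.2146, 2.9952, 5.3985, 13.8216),
    baker_hubert = c(0.1874, 0.3495, 0.1927, -0.1096, 0.1375, 0.8112),
    hubert_levine = c(0.4581, 0.3985, 0.3735, 0.5888, 0.5088, 0.1389),
    stringsAsFactors = FALSE)
}
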