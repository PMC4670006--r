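# Independent brute-force oracles used across the suite. Each is written
# from the definition, not from the implementation path it checks.

# longest constant run, quadratic scan: from every start, walk as far as the
# value persists
oracle_longest_run <- function(labels, value) {
  n <- length(labels)
  best <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != value) next
    j <- i
    while (j <= n && labels[j] == value) j <- j + 1L
    if (j - i > best) best <- j - i
  }
  best
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n)
# selections; the class is taken as elements 1..K
oracle_hyper_upper <- function(N, K, n, k) {
  if (k <= 0) return(1)
  if (n == 0L) return(0)
  sel <- utils::combn(N, n)
  counts <- colSums(matrix(sel <= K, nrow = n))
  mean(counts >= k)
}

# Benjamini-Hochberg by the step-up recursion written out by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, ps[i] * m / i)
    q[i] <- running
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# all simple paths between two nodes by depth-first search over an
# adjacency list (named list: node -> character vector of neighbors)
all_simple_paths_oracle <- function(adj, s, t) {
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (nb in adj[[last]]) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  walk(s)
  paths
}

# unnormalized betweenness by enumerating every shortest path between every
# unordered pair and crediting interior nodes with path fractions
oracle_betweenness <- function(edges, nodes) {
  adj <- stats::setNames(lapply(nodes, function(v) {
    c(edges$b[edges$a == v], edges$a[edges$b == v])
  }), nodes)
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  nn <- length(nodes)
  for (si in seq_len(nn - 1L)) {
    for (ti in (si + 1L):nn) {
      paths <- all_simple_paths_oracle(adj, nodes[si], nodes[ti])
      if (length(paths) == 0L) next
      lens <- vapply(paths, length, integer(1))
      sp <- paths[lens == min(lens)]
      for (p in sp) {
        interior <- p[-c(1L, length(p))]
        for (v in interior) btw[v] <- btw[v] + 1 / length(sp)
      }
    }
  }
  btw
}

# random connected labelled graph with at most `max_n` nodes, as a
# canonical edge-list data.frame
random_connected_edges <- function(max_n = 8L, p = 0.4) {
  repeat {
    n <- sample(3:max_n, 1L)
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0L) {
      igraph::V(g)$name <- paste0("n", seq_len(n))
      el <- igraph::as_edgelist(g)
      return(edge_list(el[, 1], el[, 2]))
    }
  }
}
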