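# Independent oracles, deliberately implemented from scratch (adjacency
# lists + queue-based BFS, dense linear algebra), never via the package's
# own code paths.

# hop distances from one source by plain BFS over an edge data frame
bfs_oracle <- function(edges, nodes, source) {
  adj <- lapply(setNames(vector("list", length(nodes)), nodes), identity)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  dist
}

# closest-proximity formula evaluated directly from BFS distances
closest_oracle <- function(edges, nodes, A, B) {
  dA <- vapply(A, function(a) min(bfs_oracle(edges, nodes, a)[B]), 0)
  dB <- vapply(B, function(b) min(bfs_oracle(edges, nodes, b)[A]), 0)
  (sum(dA) + sum(dB)) / (length(A) + length(B))
}

# dense fixed-point solves for the two propagation schemes:
#   p = damping * W p + (1 - damping) v  and  p = (1-gamma) W p + gamma p0
solve_propagation <- function(graph, v, damping) {
  W <- as.matrix(netrepurpose:::transition_matrix(graph))
  n <- nrow(W)
  p <- solve(diag(n) - damping * W, (1 - damping) * v)
  setNames(p / sum(p), rownames(W))
}

solve_rwr <- function(graph, p0, gamma) {
  W <- as.matrix(netrepurpose:::transition_matrix(graph))
  n <- nrow(W)
  setNames(solve(diag(n) - (1 - gamma) * W, gamma * p0), rownames(W))
}

# an Erdos-Renyi-ish random connected test graph as an interactome
random_test_graph <- function(n, p_edge, seed) {
  g <- netrepurpose:::with_seed(seed, {
    gg <- igraph::sample_gnp(n, p_edge)
    igraph::V(gg)$name <- sprintf("n%03d", seq_len(n))
    comp <- igraph::components(gg)
    igraph::induced_subgraph(gg, names(comp$membership)[
      comp$membership == which.max(comp$csize)])
  })
  g
}

# naive Wang similarity written independently: enumerate all ancestor paths
# and keep the best product per ancestor
naive_wang <- function(parent_edges, weights, t1, t2) {
  svals <- function(t) {
    s <- c(1); names(s) <- t
    frontier <- list(list(term = t, val = 1))
    while (length(frontier)) {
      cur <- frontier[[1]]; frontier <- frontier[-1]
      rows <- parent_edges[parent_edges$term == cur$term, , drop = FALSE]
      if (!nrow(rows)) next
      for (r in seq_len(nrow(rows))) {
        v <- cur$val * weights[[rows$relation[r]]]
        p <- rows$parent[r]
        if (is.na(s[p]) || v > s[p]) {
          s[p] <- v
          frontier[[length(frontier) + 1]] <- list(term = p, val = v)
        }
      }
    }
    s
  }
  s1 <- svals(t1); s2 <- svals(t2)
  common <- intersect(names(s1), names(s2))
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

naive_bma <- function(M) (mean(apply(M, 1, max)) + mean(apply(M, 2, max))) / 2
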