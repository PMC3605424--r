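# Independent oracles based on adjacency-matrix algebra: triangles through a
# node from diag(A^3), common neighbours of an edge from A^2. These share no
# code path with the package's igraph/neighbour-list implementations.

oracle_clustering <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
}

oracle_ecc <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  k <- rowSums(A)
  A2 <- A %*% A
  el <- igraph::as_edgelist(net)
  vapply(seq_len(nrow(el)), function(i) {
    u <- el[i, 1]; v <- el[i, 2]
    denom <- min(k[u], k[v]) - 1
    if (denom <= 0) 0 else A2[u, v] / denom
  }, numeric(1))
}

# G(n, p) graph with named vertices, reproducible from `seed`
random_named_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("P%03d", seq_len(n))
  g
}

# clique of named nodes as a 2-column edge matrix
clique_el <- function(ids) t(utils::combn(ids, 2))

# constant-profile-free expression matrix where every protein shares one
# profile (pairwise PCC = 1)
identical_expression <- function(ids, s = 8) {
  base <- sin(seq_len(s))
  matrix(rep(base, each = length(ids)), nrow = length(ids),
         dimnames = list(ids, sprintf("S%d", seq_len(s))))
}
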