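test_that("score_table ranks by score descending with lexicographic tie-break", {
  tab <- score_table(c(B = 2, A = 2, C = 5, D = 1), "x")
  expect_identical(tab$protein, c("C", "A", "B", "D"))
  expect_identical(tab$rank, 1:4)
})

test_that("DC and CC wrap the topology metrics and rank deterministically", {
  g <- ppi_network(clique_el(c("A", "B", "C")), nodes = "ISO")
  d <- dc(g)
  expect_identical(d$protein, c("A", "B", "C", "ISO"))
  expect_equal(d$score, c(2, 2, 2, 0))
  cc <- cc_measure(g)
  expect_equal(cc$score[cc$protein == "A"], 1)
  expect_equal(cc$score[cc$protein == "ISO"], 0)
})

test_that("SoECC on canonical graphs", {
  k3 <- ppi_network(clique_el(c("A", "B", "C")))
  expect_equal(soecc(k3)$score, rep(2, 3))          # two incident edges, ECC 1
  k4 <- ppi_network(clique_el(c("A", "B", "C", "D")))
  expect_equal(soecc(k4)$score, rep(3, 4))          # three incident edges, ECC 1
  star <- ppi_network(cbind("HUB", sprintf("L%d", 1:5)))
  expect_equal(soecc(star)$score, rep(0, 6))
})

test_that("SoPCC sums and cancels per-edge correlations", {
  net <- ppi_network(rbind(c("U", "P"), c("U", "M")))
  expr <- rbind(U = c(1, 2, 3, 5), P = c(2, 4, 6, 10), M = -c(1, 2, 3, 5))
  colnames(expr) <- sprintf("S%d", 1:4)
  sp <- sopcc(net, expr)
  v <- stats::setNames(sp$score, sp$protein)
  expect_equal(v[["U"]], 0)        # +1 and -1 cancel
  expect_equal(v[["P"]], 1)
})

test_that("PeC annihilates on bridges and equals 2 on co-expressed triangles", {
  k3 <- ppi_network(clique_el(c("A", "B", "C")))
  expr <- identical_expression(c("A", "B", "C"))
  expect_equal(pec(k3, expr)$score, rep(2, 3))
  # bridge-only node: every incident ECC is 0
  path <- ppi_network(rbind(c("A", "B"), c("B", "C")))
  pe <- pec(path, identical_expression(c("A", "B", "C")))
  expect_equal(pe$score, rep(0, 3))
  # zero PCC everywhere: scores vanish regardless of topology
  zero_expr <- matrix(0, 3, 4, dimnames = list(c("A", "B", "C"), sprintf("S%d", 1:4)))
  expect_equal(pec(k3, zero_expr)$score, rep(0, 3))
})

test_that("CoEWC weights neighbours' clustering, not the node's own", {
  # star whose leaves all have CC = 0: centre scores 0 whatever the PCCs
  star <- ppi_network(cbind("HUB", sprintf("L%d", 1:6)))
  expr <- identical_expression(igraph::V(star)$name)
  co <- coewc(star, expr)
  expect_equal(co$score, rep(0, 7))
  # isolated node scores 0
  iso <- ppi_network(clique_el(c("A", "B", "C")), nodes = "Z")
  co2 <- coewc(iso, identical_expression(c("A", "B", "C", "Z")))
  expect_equal(co2$score[co2$protein == "Z"], 0)
})

test_that("CoEWC decomposes as the PCC/neighbour-CC dot product on random graphs", {
  for (seed in c(3, 17, 42)) {
    g <- random_named_graph(35, 0.12, seed = seed)
    set.seed(seed + 1000)
    expr <- matrix(stats::rnorm(35 * 9), nrow = 35,
                   dimnames = list(igraph::V(g)$name, sprintf("S%d", 1:9)))
    tab <- coewc(g, expr)
    cc <- clustering_coefficient(g)
    got <- stats::setNames(tab$score, tab$protein)
    for (u in igraph::V(g)$name) {
      nb <- names(igraph::neighbors(g, u))
      want <- coewc_from_components(
        vapply(nb, function(v) pcc(expr[u, ], expr[v, ]), numeric(1)),
        cc[nb]
      )
      expect_equal(got[[u]], want, tolerance = 1e-12, info = paste("seed", seed, u))
    }
  }
})

test_that("CoEWC, SoPCC and DC coincide on clique unions with identical profiles", {
  g <- ppi_network(rbind(clique_el(sprintf("A%d", 1:4)),
                         clique_el(sprintf("B%d", 1:5)),
                         clique_el(sprintf("C%d", 1:3))))
  expr <- identical_expression(igraph::V(g)$name)
  d <- dc(g)
  expect_identical(coewc(g, expr)$protein, d$protein)
  expect_equal(coewc(g, expr)$score, d$score)
  expect_equal(sopcc(g, expr)$score, d$score)
})

test_that("relabelling nodes permutes scores consistently", {
  g <- random_named_graph(25, 0.2, seed = 8)
  set.seed(9)
  expr <- matrix(stats::rnorm(25 * 8), nrow = 25,
                 dimnames = list(igraph::V(g)$name, sprintf("S%d", 1:8)))
  relabel <- stats::setNames(sprintf("Q%03d", sample(25)), igraph::V(g)$name)
  el <- igraph::as_edgelist(g)
  g2 <- ppi_network(cbind(relabel[el[, 1]], relabel[el[, 2]]))
  expr2 <- expr
  rownames(expr2) <- relabel[rownames(expr)]
  for (fn in list(function(n, e) dc(n), soecc, function(n, e) coewc(n, e))) {
    t1 <- if (identical(fn, soecc)) fn(g) else fn(g, expr)
    t2 <- if (identical(fn, soecc)) fn(g2) else fn(g2, expr2)
    v1 <- stats::setNames(t1$score, t1$protein)
    v2 <- stats::setNames(t2$score, t2$protein)
    expect_equal(unname(v2[relabel[names(v1)]]), unname(v1), tolerance = 1e-12)
  }
})

test_that("compute_measures validates names and expression requirements", {
  g <- ppi_network(clique_el(c("A", "B", "C")))
  expect_error(compute_measures(g, measures = "pagerank"), "unknown measure")
  expect_error(compute_measures(g, measures = "coewc"), "require an expression")
  out <- compute_measures(g, measures = c("dc", "soecc"))
  expect_named(out, c("dc", "soecc"))
})
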