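# The six ranking measures. Every measure returns a score_table whose
# ranking is deterministic: score descending, ties broken by ascending
# protein ID (C-locale radix order).

#' Build a ranked score table
#'
#' @param values Named numeric vector of per-protein scores.
#' @param measure Measure name (e.g. `"CoEWC"`).
#' @return A data frame of class `score_table` with columns `rank`,
#'   `protein`, `score`, sorted by score descending with lexicographic
#'   tie-breaking on protein ID.
#' @export
score_table <- function(values, measure) {
  if (is.null(names(values)) || anyNA(names(values))) {
    stop("scores must be named by protein ID")
  }
  o <- order(-values, names(values), method = "radix")
  tab <- data.frame(rank = seq_along(values),
                    protein = names(values)[o],
                    score = unname(values)[o],
                    stringsAsFactors = FALSE)
  attr(tab, "measure") <- measure
  class(tab) <- c("score_table", "data.frame")
  tab
}

#' @export
print.score_table <- function(x, n = 10L, ...) {
  cat(sprintf("score_table: %s, %d proteins\n", attr(x, "measure"), nrow(x)))
  print.data.frame(utils::head(x, n), row.names = FALSE, ...)
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Degree centrality (DC)
#'
#' @param net PPI network (igraph graph with vertex names).
#' @return A [score_table()].
#' @export
dc <- function(net) {
  score_table(node_degree(net), "DC")
}

#' Clustering-coefficient centrality (CC)
#'
#' Ranks proteins by their own local clustering coefficient.
#'
#' @inheritParams dc
#' @return A [score_table()].
#' @export
cc_measure <- function(net) {
  score_table(clustering_coefficient(net), "CC")
}

#' Sum of edge clustering coefficients (SoECC)
#'
#' SoECC(u) = sum of ECC(u,v) over the neighbours v of u.
#'
#' @inheritParams dc
#' @param variant ECC variant passed to [edge_clustering()].
#' @return A [score_table()].
#' @export
soecc <- function(net, variant = c("standard", "plus_one")) {
  e <- edge_clustering(net, variant)
  score_table(node_sum_over_edges(net, e$ecc), "SoECC")
}

#' Sum of Pearson correlations (SoPCC)
#'
#' SoPCC(u) = sum of PCC(u,v) over the neighbours v of u.
#'
#' @inheritParams dc
#' @param expr Expression matrix (rows = proteins, columns = samples).
#' @return A [score_table()].
#' @export
sopcc <- function(net, expr) {
  p <- edge_pcc(net, expr)
  score_table(node_sum_over_edges(net, p$pcc), "SoPCC")
}

#' PeC: sum of ECC x PCC over incident edges
#'
#' PeC(u) = sum of ECC(u,v) * PCC(u,v) over the neighbours v of u; it
#' rewards proteins that are both co-clustered and co-expressed with their
#' partners.
#'
#' @inheritParams soecc
#' @param expr Expression matrix (rows = proteins, columns = samples).
#' @return A [score_table()].
#' @export
pec <- function(net, expr, variant = c("standard", "plus_one")) {
  p <- edge_pcc(net, expr)$pcc
  e <- edge_clustering(net, variant)$ecc
  score_table(node_sum_over_edges(net, p * e), "PeC")
}

#' CoEWC: co-expression weighted by the neighbour's clustering coefficient
#'
#' CoEWC(u) = sum over the neighbours v of u of PCC(u,v) * CC(v). Unlike
#' SoECC and PeC, the clustering weight belongs to the *neighbour*, not to
#' the edge or the protein itself: a party hub scores highly because its
#' partners sit in its own dense module, and a date hub scores highly
#' because each partner sits in some dense module, while a star-like hub
#' whose partners are unconnected singletons scores near 0. Proteins with
#' no neighbours score 0.
#'
#' @inheritParams dc
#' @param expr Expression matrix (rows = proteins, columns = samples).
#' @return A [score_table()].
#' @export
coewc <- function(net, expr) {
  vn <- igraph::V(net)$name
  s <- stats::setNames(numeric(length(vn)), vn)
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    p <- edge_pcc(net, expr)$pcc
    cc <- clustering_coefficient(net)
    a <- tapply(p * cc[el[, 2]], el[, 1], sum)  # contribution to `from`
    s[names(a)] <- s[names(a)] + a
    b <- tapply(p * cc[el[, 1]], el[, 2], sum)  # contribution to `to`
    s[names(b)] <- s[names(b)] + b
  }
  score_table(s, "CoEWC")
}

#' CoEWC score of one protein from per-neighbour components
#'
#' Evaluates the defining sum directly from a protein's per-neighbour
#' Pearson correlations and the neighbours' clustering coefficients. Useful
#' for worked examples where the components are known.
#'
#' @param pcc Numeric vector: PCC between the protein and each neighbour.
#' @param cc Numeric vector: each neighbour's clustering coefficient, in the
#'   same order.
#' @return The CoEWC score, `sum(pcc * cc)`.
#' @export
coewc_from_components <- function(pcc, cc) {
  if (length(pcc) != length(cc)) stop("pcc and cc must have equal length")
  sum(pcc * cc)
}

#' Compute a set of centrality measures
#'
#' @inheritParams coewc
#' @param measures Character vector drawn from
#'   `c("dc", "cc", "soecc", "sopcc", "pec", "coewc")`.
#' @param variant ECC variant for the ECC-based measures.
#' @return Named list of [score_table()]s.
#' @export
compute_measures <- function(net, expr = NULL,
                             measures = c("dc", "cc", "soecc", "sopcc", "pec", "coewc"),
                             variant = "standard") {
  known <- c("dc", "cc", "soecc", "sopcc", "pec", "coewc")
  bad <- setdiff(measures, known)
  if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
  needs_expr <- c("sopcc", "pec", "coewc")
  if (is.null(expr) && any(measures %in% needs_expr)) {
    stop("measures ", paste(intersect(measures, needs_expr), collapse = ", "),
         " require an expression matrix")
  }
  out <- lapply(measures, function(m) {
    switch(m,
      dc    = dc(net),
      cc    = cc_measure(net),
      soecc = soecc(net, variant),
      sopcc = sopcc(net, expr),
      pec   = pec(net, expr, variant),
      coewc = coewc(net, expr)
    )
  })
  stats::setNames(out, measures)
}
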