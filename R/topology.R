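# Structural metrics on the PPI graph. Degree and the local clustering
# coefficient are delegated to igraph; the edge clustering coefficient is
# computed here (no igraph primitive exists for it).

#' Degree of every protein
#'
#' @param net PPI network (igraph graph with vertex names).
#' @return Named numeric vector, one entry per protein; isolated proteins
#'   score 0.
#' @export
node_degree <- function(net) {
  igraph::degree(net)
}

#' Local clustering coefficient of every protein
#'
#' CC(u) = 2 e_u / (k_u (k_u - 1)) where e_u is the number of interactions
#' among the k_u neighbours of u. Proteins with k_u <= 1 are assigned 0 so
#' that degenerate nodes flow through downstream scoring.
#'
#' @inheritParams node_degree
#' @return Named numeric vector in [0, 1].
#' @export
clustering_coefficient <- function(net) {
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  stats::setNames(cc, igraph::V(net)$name)
}

#' Number of common neighbours of two proteins
#'
#' Counts |N(u) ∩ N(v)|; u and v themselves are never counted (the graph is
#' simple, so neither belongs to its own neighbourhood).
#'
#' @inheritParams node_degree
#' @param u,v Protein IDs present in the network.
#' @return Integer count.
#' @export
common_neighbors <- function(net, u, v) {
  vn <- igraph::V(net)$name
  if (!u %in% vn) stop("unknown protein: ", u)
  if (!v %in% vn) stop("unknown protein: ", v)
  nu <- names(igraph::neighbors(net, u))
  nv <- names(igraph::neighbors(net, v))
  length(intersect(nu, nv))
}

#' Edge clustering coefficient of every interaction
#'
#' ECC(u,v) = |N(u) ∩ N(v)| / min(k_u - 1, k_v - 1), the fraction of
#' possible triangles through the edge that are realised; it measures how
#' strongly the two interacting proteins are co-clustered. When the
#' denominator is 0 (an endpoint of degree 1) the value is 0. The
#' `"plus_one"` variant adds 1 to the numerator (the Radicchi form).
#'
#' @inheritParams node_degree
#' @param variant `"standard"` (default) or `"plus_one"`.
#' @return Data frame with columns `from`, `to`, `ecc`, one row per edge in
#'   igraph edge order.
#' @export
edge_clustering <- function(net, variant = c("standard", "plus_one")) {
  variant <- match.arg(variant)
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0L) {
    return(data.frame(from = character(0), to = character(0), ecc = numeric(0),
                      stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(net)
  nb <- lapply(igraph::as_adj_list(net), names)
  names(nb) <- igraph::V(net)$name
  z <- mapply(function(u, v) length(intersect(nb[[u]], nb[[v]])),
              el[, 1], el[, 2], USE.NAMES = FALSE)
  if (variant == "plus_one") z <- z + 1
  denom <- pmin(deg[el[, 1]], deg[el[, 2]]) - 1
  val <- ifelse(denom <= 0, 0, z / denom)
  data.frame(from = el[, 1], to = el[, 2], ecc = unname(val),
             stringsAsFactors = FALSE)
}

#' Largest connected component of a PPI network
#'
#' @inheritParams node_degree
#' @return The induced subgraph on the largest component (ties broken by the
#'   component containing the lexicographically smallest protein ID).
#' @export
largest_component <- function(net) {
  comp <- igraph::components(net)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    firsts <- vapply(big, function(b) {
      min(igraph::V(net)$name[comp$membership == b])
    }, character(1))
    big <- big[order(firsts, method = "radix")[1]]
  }
  igraph::induced_subgraph(net, which(comp$membership == big))
}

# Fold per-edge values into per-node sums (each edge contributes its value to
# both endpoints). `edge_values` is aligned with igraph::as_edgelist(net).
node_sum_over_edges <- function(net, edge_values) {
  el <- igraph::as_edgelist(net)
  vn <- igraph::V(net)$name
  s <- stats::setNames(numeric(length(vn)), vn)
  if (nrow(el)) {
    a <- tapply(edge_values, el[, 1], sum)
    s[names(a)] <- s[names(a)] + a
    b <- tapply(edge_values, el[, 2], sum)
    s[names(b)] <- s[names(b)] + b
  }
  s
}
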