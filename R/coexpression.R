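# Co-expression of interacting proteins, measured by the Pearson
# correlation of their expression profiles across samples.

#' Pearson correlation of two expression profiles
#'
#' Standard sample Pearson correlation. If either profile has zero standard
#' deviation the correlation is undefined and 0 is returned; this covers
#' proteins without expression data, which carry the all-zero profile.
#'
#' @param x,y Numeric vectors of equal length (>= 2 samples).
#' @return A value in [-1, 1].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("expression profiles differ in length")
  if (length(x) < 2L) stop("need at least 2 samples to correlate")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Rows of `expr` restricted/extended to `ids` (zero rows for proteins absent
# from the matrix), centred and scaled so that rowSums(Z[u,] * Z[v,]) is the
# Pearson correlation of u and v. Zero-variance rows become zero rows.
standardized_profiles <- function(expr, ids) {
  stopifnot(is.matrix(expr))
  s <- ncol(expr)
  if (s < 2L) stop("expression matrix needs at least 2 samples")
  M <- matrix(0, nrow = length(ids), ncol = s, dimnames = list(ids, colnames(expr)))
  hit <- intersect(ids, rownames(expr))
  M[hit, ] <- expr[hit, , drop = FALSE]
  Mc <- M - rowMeans(M)
  ss <- sqrt(rowSums(Mc^2))
  Z <- Mc / ss
  Z[ss == 0, ] <- 0
  Z
}

#' Pearson correlation for every interacting pair
#'
#' Applies [pcc()] to the expression profiles of the two endpoints of every
#' edge. Proteins absent from the expression matrix use the all-zero profile
#' and therefore correlate 0 with every partner.
#'
#' @param net PPI network (igraph graph with vertex names).
#' @param expr Expression matrix (rows = proteins, columns = samples).
#' @return Data frame with columns `from`, `to`, `pcc`, one row per edge in
#'   igraph edge order.
#' @export
edge_pcc <- function(net, expr) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0L) {
    return(data.frame(from = character(0), to = character(0), pcc = numeric(0),
                      stringsAsFactors = FALSE))
  }
  Z <- standardized_profiles(expr, igraph::V(net)$name)
  v <- rowSums(Z[el[, 1], , drop = FALSE] * Z[el[, 2], , drop = FALSE])
  v <- pmax(pmin(v, 1), -1)
  data.frame(from = el[, 1], to = el[, 2], pcc = unname(v),
             stringsAsFactors = FALSE)
}
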