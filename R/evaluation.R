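# Ranking evaluation: top-k essential counts, jackknife cumulative curves
# with a trapezoidal AUC, seeded random baselines, and pairwise overlap
# analysis between measures.

#' Essential proteins among the top k of a ranking
#'
#' @param tab A [score_table()].
#' @param essential Character vector of essential protein IDs. Proteins not
#'   in this set are non-essential by definition.
#' @param k Number of top-ranked proteins to select.
#' @return List with `k`, `predicted` (the top-k IDs in rank order),
#'   `true_positive_count`, and `precision`.
#' @export
top_k <- function(tab, essential, k) {
  stopifnot(inherits(tab, "score_table"))
  if (k < 1L || k > nrow(tab)) {
    stop(sprintf("k = %d out of range [1, %d]", k, nrow(tab)))
  }
  predicted <- tab$protein[seq_len(k)]
  tp <- sum(predicted %in% essential)
  list(k = as.integer(k), predicted = predicted,
       true_positive_count = tp, precision = tp / k)
}

# Trapezoidal area under the cumulative step curve over ranks 1..length(cum).
auc_trapezoid <- function(cum) {
  n <- length(cum)
  if (n < 2L) return(0)
  sum((cum[-1] + cum[-n]) / 2)
}

#' Jackknife cumulative essential-count curve
#'
#' Walks the ranking from the highest to the lowest score and records, at
#' every rank r, how many essential proteins occur among the top r. Curves
#' for different measures are compared by the area under the curve (AUC),
#' computed by the trapezoidal rule over ranks 1..`max_rank`.
#'
#' @inheritParams top_k
#' @param max_rank Deepest rank to include (defaults to the whole ranking).
#' @return An object of class `jackknife_curve`: list with `cumulative`
#'   (integer vector of length `max_rank`), `auc`, and `measure`.
#' @export
jackknife <- function(tab, essential, max_rank = nrow(tab)) {
  stopifnot(inherits(tab, "score_table"))
  if (max_rank < 1L || max_rank > nrow(tab)) {
    stop(sprintf("max_rank = %d out of range [1, %d]", max_rank, nrow(tab)))
  }
  hits <- tab$protein[seq_len(max_rank)] %in% essential
  cum <- cumsum(hits)
  structure(list(cumulative = cum, auc = auc_trapezoid(cum),
                 measure = attr(tab, "measure")),
            class = "jackknife_curve")
}

#' @export
print.jackknife_curve <- function(x, ...) {
  n <- length(x$cumulative)
  cat(sprintf("jackknife_curve: %s, %d ranks, %d essential at depth, AUC = %g\n",
              if (is.null(x$measure)) "?" else x$measure,
              n, x$cumulative[n], x$auc))
  invisible(x)
}

#' Random-ranking baseline curves
#'
#' Builds jackknife curves for uniformly shuffled orderings of the protein
#' list, the null against which a centrality measure's curve is judged.
#'
#' @param net PPI network (igraph graph) or a character vector of protein
#'   IDs.
#' @param essential Character vector of essential protein IDs.
#' @param max_rank Deepest rank to include.
#' @param n_shuffles Number of independent shuffles.
#' @param seed Integer seed; the whole set of curves is reproducible from
#'   it.
#' @return List of `n_shuffles` `jackknife_curve` objects.
#' @export
random_baseline <- function(net, essential, max_rank, n_shuffles = 10L, seed = 1L) {
  ids <- if (inherits(net, "igraph")) igraph::V(net)$name else as.character(net)
  ids <- sort(ids, method = "radix")
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  if (max_rank < 1L || max_rank > length(ids)) stop("max_rank out of range")
  set.seed(seed)
  lapply(seq_len(n_shuffles), function(i) {
    ord <- sample(ids)
    cum <- cumsum(ord[seq_len(max_rank)] %in% essential)
    structure(list(cumulative = cum, auc = auc_trapezoid(cum),
                   measure = sprintf("random_%03d", i)),
              class = "jackknife_curve")
  })
}

#' Overlap and difference between the top-k sets of two measures
#'
#' Computes the intersection of the two top-k sets and, for each
#' symmetric-difference set (proteins picked by one measure but not the
#' other), the fraction that is essential — the basis for judging which
#' measure's exclusive picks are better.
#'
#' @param tab_a,tab_b Two [score_table()]s covering at least `k` proteins.
#' @param essential Character vector of essential protein IDs.
#' @param k Top-k cutoff.
#' @return List with `measures`, `k`, `common_count`, `only_a`, `only_b`
#'   (ID vectors), and `essential_fraction_only_a` / `_b` (`NaN` when a
#'   difference set is empty).
#' @export
overlap_analysis <- function(tab_a, tab_b, essential, k) {
  stopifnot(inherits(tab_a, "score_table"), inherits(tab_b, "score_table"))
  if (k > nrow(tab_a) || k > nrow(tab_b)) stop("k exceeds a ranking length")
  a <- tab_a$protein[seq_len(k)]
  b <- tab_b$protein[seq_len(k)]
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  ess_frac <- function(x) if (length(x)) mean(x %in% essential) else NaN
  list(measures = c(attr(tab_a, "measure"), attr(tab_b, "measure")),
       k = as.integer(k),
       common_count = length(intersect(a, b)),
       only_a = only_a, only_b = only_b,
       essential_fraction_only_a = ess_frac(only_a),
       essential_fraction_only_b = ess_frac(only_b))
}

#' Score of the protein at a given rank
#'
#' Reference values for comparing otherwise incommensurable measures: the
#' score held by the protein at a fixed depth of each measure's descending
#' ranking.
#'
#' @inheritParams top_k
#' @param rank Rank (1 = highest score).
#' @return The score at that rank.
#' @export
reference_value <- function(tab, rank) {
  stopifnot(inherits(tab, "score_table"))
  if (rank < 1L || rank > nrow(tab)) {
    stop(sprintf("rank = %d out of range [1, %d]", rank, nrow(tab)))
  }
  tab$score[rank]
}
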