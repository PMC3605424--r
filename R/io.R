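#' Construct a PPI network from an edge table
#'
#' Builds an undirected simple graph of protein IDs. Self-interactions and
#' duplicate records of the same unordered pair are dropped, mirroring the
#' standard cleaning applied to DIP exports before centrality analysis.
#'
#' @param edges Two-column character matrix or data frame of interacting
#'   protein IDs. Extra columns are ignored.
#' @param nodes Optional character vector of additional protein IDs kept as
#'   isolated nodes.
#' @param report If `TRUE`, emit a `message()` with node/edge counts and the
#'   numbers of dropped self-interactions and duplicates.
#' @return An undirected simple [igraph][igraph::graph_from_data_frame] graph
#'   with vertex names, carrying graph attributes `dropped_self` and
#'   `dropped_dup`.
#' @export
ppi_network <- function(edges, nodes = NULL, report = FALSE) {
  el <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(el) <- "character"
  endpoints <- as.vector(el)  # self-loop endpoints stay as isolated nodes
  self <- el[, 1] == el[, 2]
  n_self <- sum(self)
  el <- el[!self, , drop = FALSE]
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  el <- el[!dup, , drop = FALSE]
  ids <- sort(unique(c(endpoints, nodes)), method = "radix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = FALSE, vertices = ids
  )
  g <- igraph::set_graph_attr(g, "dropped_self", n_self)
  g <- igraph::set_graph_attr(g, "dropped_dup", n_dup)
  if (report) {
    message(sprintf(
      "PPI network: %d proteins, %d interactions (%d self-interactions, %d duplicate records dropped)",
      length(ids), nrow(el), n_self, n_dup
    ))
  }
  g
}

#' Read a PPI network from a two-column edge list
#'
#' Parses a DIP-style tab/whitespace-separated edge list of protein
#' identifiers. Blank lines and lines starting with `#` are skipped; columns
#' beyond the second are ignored. Self-interactions and repeated interactions
#' are filtered on load and the dropped counts are reported.
#'
#' @inheritParams ppi_network
#' @param path Path to the edge-list file.
#' @return An undirected simple igraph graph (see [ppi_network()]).
#' @export
read_ppi <- function(path, nodes = NULL) {
  if (!file.exists(path)) stop("PPI edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("empty PPI edge list: ", path)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nfield <- vapply(toks, length, integer(1))
  if (any(nfield < 2L)) {
    stop(sprintf(
      "malformed edge list line %d in %s: fewer than 2 fields",
      keep[which(nfield < 2L)[1]], path
    ))
  }
  el <- t(vapply(toks, function(x) x[1:2], character(2)))
  ppi_network(el, nodes = nodes, report = TRUE)
}

#' Write a PPI network as a two-column edge list
#'
#' Edges are written in canonical order (each pair sorted, pairs sorted
#' lexicographically) so output is byte-reproducible.
#'
#' @param net PPI network (igraph graph with vertex names).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(net, path) {
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    o <- order(a, b, method = "radix")
    out <- data.frame(a[o], b[o])
  } else {
    out <- data.frame(character(0), character(0))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-expression matrix
#'
#' Expects a tab/whitespace-separated file whose header row lists the sample
#' names (optionally preceded by a label for the ID column) and whose data
#' rows contain a protein/gene ID followed by one numeric expression level
#' per sample. Missing values (`NA` fields) are rejected: only whole-protein
#' absence is supported downstream, where an absent protein maps to the
#' all-zero profile.
#'
#' @param path Path to the expression file.
#' @return A numeric matrix, rows named by protein ID, columns by sample.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop("expression file needs a header and at least one data row: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  s <- length(rows[[1]]) - 1L
  if (s < 1L) stop("expression data row 1 has no expression fields")
  if (!length(header) %in% c(s, s + 1L)) {
    stop(sprintf("header has %d fields but data rows imply %d samples", length(header), s))
  }
  samples <- utils::tail(header, s)
  ids <- character(length(rows))
  mat <- matrix(NA_real_, nrow = length(rows), ncol = s)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != s + 1L) {
      stop(sprintf("expression data row %d has %d fields; expected %d", i, length(f), s + 1L))
    }
    ids[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric expression value '%s' at data row %d, sample column %d",
                   f[j + 1L], i, j))
    }
    mat[i, ] <- v
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    warning("duplicate expression IDs (last occurrence kept): ",
            paste(dups, collapse = ", "))
    last <- !duplicated(ids, fromLast = TRUE)
    mat <- mat[last, , drop = FALSE]
    ids <- ids[last]
  }
  dimnames(mat) <- list(ids, samples)
  mat
}

#' Write a gene-expression matrix
#'
#' @param expr Numeric matrix with protein IDs as row names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  samples <- colnames(expr)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(expr)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("protein", samples), collapse = "\t"), con)
  body <- apply(expr, 1, function(x) paste(format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = "\t"))
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

#' Look up an expression profile with the zero-imputation policy
#'
#' Proteins present in the PPI network but absent from the expression matrix
#' are assigned the all-zero profile, which forces their Pearson correlation
#' with any partner to 0.
#'
#' @param expr Expression matrix from [read_expression()].
#' @param id Protein ID.
#' @return Numeric vector of length `ncol(expr)`.
#' @export
expr_profile <- function(expr, id) {
  stopifnot(is.matrix(expr), length(id) == 1L)
  if (id %in% rownames(expr)) {
    expr[id, ]
  } else {
    stats::setNames(numeric(ncol(expr)), colnames(expr))
  }
}

#' Read a list of protein IDs (one per line)
#'
#' Blank lines and `#` comments are skipped. Used for the reference set of
#' essential proteins.
#'
#' @param path Path to the ID list.
#' @return Character vector of unique IDs.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop("ID list not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- unique(lines[!grepl("^(#|$)", lines)])
  if (length(ids) == 0L) stop("empty ID list: ", path)
  ids
}

#' Write a score table as tab-separated (rank, protein, score)
#'
#' Scores are printed with six decimal places; the row order is the table's
#' deterministic ranking.
#'
#' @param tab A [score_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(tab, path) {
  stopifnot(inherits(tab, "score_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("rank\tprotein\tscore", con)
  writeLines(sprintf("%d\t%s\t%.6f", tab$rank, tab$protein, tab$score), con)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path Path to the score TSV.
#' @param measure Measure name to attach; defaults to the file base name.
#' @return A `score_table` in the file's order.
#' @export
read_scores <- function(path, measure = NULL) {
  if (!file.exists(path)) stop("score table not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("rank", "protein", "score") %in% names(d))) {
    stop("score table must have columns rank, protein, score: ", path)
  }
  if (is.null(measure)) measure <- sub("\\.[^.]*$", "", basename(path))
  d <- d[order(d$rank), c("rank", "protein", "score")]
  rownames(d) <- NULL
  attr(d, "measure") <- measure
  class(d) <- c("score_table", "data.frame")
  d
}
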