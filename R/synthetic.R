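# Synthetic networks with planted party, date and noisy hubs, plus coupled
# expression profiles with a controlled pairwise Pearson correlation. These
# emulate the modular ("organised modularity") structure of the yeast
# interactome: party hubs inside one dense module, date hubs bridging
# several modules, and star-like noisy hubs whose partners are unconnected.

#' A small modular toy network
#'
#' Three complete sub-networks (cliques) D, E and F of sizes 20, 30 and 40,
#' a connector node C adjacent to one member of each clique (D1, E1, F1) and
#' to two peripheral nodes A and B, each of which has a single pendant
#' partner (A1, B1). C is a prototypical date hub: its clique-side
#' neighbours have high clustering coefficients while A and B do not, so a
#' neighbour-clustering weighting emphasises the edges C-D1, C-E1, C-F1
#' over A-C and B-C.
#'
#' @return A PPI network (igraph graph) with 95 nodes.
#' @export
toy_modular_network <- function() {
  clique_edges <- function(ids) t(utils::combn(ids, 2))
  d <- sprintf("D%d", 1:20)
  e <- sprintf("E%d", 1:30)
  f <- sprintf("F%d", 1:40)
  el <- rbind(clique_edges(d), clique_edges(e), clique_edges(f),
              c("A", "A1"), c("B", "B1"), c("A", "C"), c("B", "C"),
              c("C", "D1"), c("C", "E1"), c("C", "F1"))
  ppi_network(el)
}

#' Specification for a planted-hub synthetic data set
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: two hubs of each class, all with matched degree 12; twelve
#' background cliques of size 6 for date hubs to bridge; expression with 36
#' samples and a target hub-neighbour correlation of 0.8 over noise with
#' standard deviation 0.2.
#'
#' @param clique_sizes Sizes of the background cliques that date hubs attach
#'   to. Party hubs get a dedicated clique of size `noisy_hub_degree + 1`
#'   each, so that all planted hub classes are degree-matched.
#' @param n_party_hubs,n_date_hubs,n_noisy_hubs Number of hubs per class.
#' @param noisy_hub_degree Degree of every planted hub.
#' @param target_pcc_signal Target Pearson correlation between a party/date
#'   hub and each of its neighbours, in (0, 1].
#' @param noise_sd Standard deviation of the independent noise mixed into
#'   neighbour profiles.
#' @param n_samples Number of expression samples (>= 3).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(clique_sizes = rep(6L, 12L),
                           n_party_hubs = 2L, n_date_hubs = 2L,
                           n_noisy_hubs = 2L, noisy_hub_degree = 12L,
                           target_pcc_signal = 0.8, noise_sd = 0.2,
                           n_samples = 36L, seed = 1L) {
  spec <- list(clique_sizes = as.integer(clique_sizes),
               n_party_hubs = as.integer(n_party_hubs),
               n_date_hubs = as.integer(n_date_hubs),
               n_noisy_hubs = as.integer(n_noisy_hubs),
               noisy_hub_degree = as.integer(noisy_hub_degree),
               target_pcc_signal = target_pcc_signal,
               noise_sd = noise_sd,
               n_samples = as.integer(n_samples),
               seed = as.integer(seed))
  bad <- character(0)
  counts <- c("n_party_hubs", "n_date_hubs", "n_noisy_hubs")
  for (f in counts) if (spec[[f]] < 0L) bad <- c(bad, f)
  if (spec$noisy_hub_degree < 1L) bad <- c(bad, "noisy_hub_degree")
  if (spec$n_samples < 3L) bad <- c(bad, "n_samples")
  if (!(spec$target_pcc_signal > 0 && spec$target_pcc_signal <= 1)) {
    bad <- c(bad, "target_pcc_signal")
  }
  if (spec$noise_sd <= 0) bad <- c(bad, "noise_sd")
  if (any(spec$clique_sizes < 2L)) bad <- c(bad, "clique_sizes")
  if (length(bad)) {
    stop("invalid synthetic_spec field(s): ", paste(unique(bad), collapse = ", "))
  }
  if (spec$n_date_hubs > 0L && length(spec$clique_sizes) < spec$noisy_hub_degree) {
    stop(sprintf(
      "clique sizes too small to host requested hubs: date hubs of degree %d need %d background cliques, have %d",
      spec$noisy_hub_degree, spec$noisy_hub_degree, length(spec$clique_sizes)
    ))
  }
  class(spec) <- "synthetic_spec"
  spec
}

# Mixing weight alpha such that cor(alpha*Z + (1-alpha)*N(0, sd^2), Z) = r
# in population: alpha/(1-alpha) = r*sd/sqrt(1-r^2).
mixing_alpha <- function(r, sd) {
  if (r >= 1) return(1)
  a <- r * sd / sqrt(1 - r^2)
  a / (1 + a)
}

#' Generate a planted-hub network with coupled expression
#'
#' Builds a PPI network containing: one dedicated clique of size
#' `noisy_hub_degree + 1` per party hub (the hub is a member, so all its
#' partners are mutually connected); the background cliques of
#' `clique_sizes`; one date hub per request, attached to one member of each
#' of `noisy_hub_degree` distinct background cliques; and noisy hubs as
#' star centres with pairwise non-adjacent fresh leaves. Expression
#' profiles: each party/date hub carries a latent standard-normal profile,
#' each of its neighbours mixes that latent signal with independent noise
#' so that the population correlation equals `target_pcc_signal`; all other
#' proteins (including noisy hubs and their leaves) carry independent
#' noise. Party and date hubs are labelled essential, everything else
#' non-essential.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `labeled_network` with elements `network`,
#'   `expression`, `essential`, `roles` (named character vector:
#'   party/date/noisy/background), and `spec`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  s <- spec$n_samples
  r <- spec$target_pcc_signal
  alpha <- mixing_alpha(r, spec$noise_sd)

  clique_edges <- function(ids) {
    if (length(ids) < 2L) return(matrix(character(0), ncol = 2))
    t(utils::combn(ids, 2))
  }

  el <- matrix(character(0), ncol = 2)
  roles <- character(0)
  hub_neighbors <- list()  # hub ID -> neighbour IDs coupled to its latent

  # party hubs, each inside a dedicated clique of size degree+1
  for (i in seq_len(spec$n_party_hubs)) {
    hub <- sprintf("PH%02d", i)
    members <- sprintf("PH%02d_M%02d", i, seq_len(spec$noisy_hub_degree))
    el <- rbind(el, clique_edges(c(hub, members)))
    roles[hub] <- "party"
    roles[members] <- "background"
    hub_neighbors[[hub]] <- members
  }

  # background cliques
  bg <- lapply(seq_along(spec$clique_sizes), function(j) {
    sprintf("BG%02d_M%02d", j, seq_len(spec$clique_sizes[j]))
  })
  for (members in bg) {
    el <- rbind(el, clique_edges(members))
    roles[members] <- "background"
  }

  # date hubs: one member of each of `noisy_hub_degree` distinct cliques;
  # different hubs attach to different members where clique size allows,
  # so each attachment point couples to a single hub latent
  for (i in seq_len(spec$n_date_hubs)) {
    hub <- sprintf("DH%02d", i)
    targets <- vapply(bg[seq_len(spec$noisy_hub_degree)], function(members) {
      members[((i - 1L) %% length(members)) + 1L]
    }, character(1))
    el <- rbind(el, cbind(hub, targets))
    roles[hub] <- "date"
    hub_neighbors[[hub]] <- targets
  }

  # noisy hubs: star centres with fresh, pairwise non-adjacent leaves
  for (i in seq_len(spec$n_noisy_hubs)) {
    hub <- sprintf("NH%02d", i)
    leaves <- sprintf("NH%02d_L%02d", i, seq_len(spec$noisy_hub_degree))
    el <- rbind(el, cbind(hub, leaves))
    roles[hub] <- "noisy"
    roles[leaves] <- "background"
  }

  net <- ppi_network(el, nodes = names(roles))
  ids <- igraph::V(net)$name

  # expression: independent noise everywhere, then hub-latent coupling
  expr <- matrix(stats::rnorm(length(ids) * s), nrow = length(ids),
                 dimnames = list(ids, sprintf("S%02d", seq_len(s))))
  for (hub in names(hub_neighbors)) {
    latent <- stats::rnorm(s)
    expr[hub, ] <- latent
    for (v in hub_neighbors[[hub]]) {
      expr[v, ] <- alpha * latent + (1 - alpha) * stats::rnorm(s, sd = spec$noise_sd)
    }
  }

  essential <- sort(names(roles)[roles %in% c("party", "date")], method = "radix")
  structure(list(network = net, expression = expr,
                 essential = essential, roles = roles[ids], spec = spec),
            class = "labeled_network")
}

#' @export
print.labeled_network <- function(x, ...) {
  tab <- table(factor(x$roles, levels = c("party", "date", "noisy", "background")))
  cat(sprintf(
    "labeled_network: %d proteins, %d interactions, %d samples; hubs: %d party, %d date, %d noisy; %d essential\n",
    igraph::vcount(x$network), igraph::ecount(x$network), ncol(x$expression),
    tab[["party"]], tab[["date"]], tab[["noisy"]], length(x$essential)))
  invisible(x)
}

#' Randomly perturb a PPI network
#'
#' Emulates the incompleteness (false negatives) and noise (false
#' positives) of experimentally determined interactomes: removes
#' `floor(remove_frac * |E|)` uniformly chosen edges, then adds
#' `floor(add_frac * |E|)` uniformly chosen non-edges (counts relative to
#' the original edge set). Never introduces self-loops or duplicates.
#'
#' @param net PPI network (igraph graph with vertex names).
#' @param add_frac,remove_frac Fractions in [0, 1).
#' @param seed Integer seed.
#' @return The perturbed network.
#' @export
perturb_network <- function(net, add_frac = 0, remove_frac = 0, seed = 1L) {
  if (add_frac < 0 || add_frac >= 1 || remove_frac < 0 || remove_frac >= 1) {
    stop("add_frac and remove_frac must lie in [0, 1)")
  }
  set.seed(seed)
  m <- igraph::ecount(net)
  n_rm <- floor(remove_frac * m)
  n_add <- floor(add_frac * m)
  g <- net
  if (n_rm > 0L) {
    g <- igraph::delete_edges(g, sample(m, n_rm))
  }
  if (n_add > 0L) {
    vn <- igraph::V(g)$name
    n <- length(vn)
    max_new <- n * (n - 1) / 2 - igraph::ecount(g)
    if (n_add > max_new) stop("not enough non-edges to add")
    added <- 0L
    seen <- character(0)
    while (added < n_add) {
      pair <- sort(vn[sample.int(n, 2L)])
      key <- paste(pair, collapse = "\r")
      if (key %in% seen || igraph::are_adjacent(g, pair[1], pair[2])) next
      g <- igraph::add_edges(g, pair)
      seen <- c(seen, key)
      added <- added + 1L
    }
  }
  g
}
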