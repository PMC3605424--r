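---
title: "CoEWC: model, design choices and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CoEWC: model, design choices and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coewc)
```

## The model

A PPI network is an undirected simple graph $G(V, E)$ over protein IDs;
gene expression gives each protein $u$ a profile
$Ge(u) = (g(u,1), \dots, g(u,s))$ over $s$ samples. Three ingredients:

* **PCC** — the sample Pearson correlation of two profiles, the standard
  proxy for co-expression. Interacting proteins that are co-expressed tend
  to share a functional module.
* **CC** — the local clustering coefficient
  $CC(u) = 2 e_u / (k_u (k_u - 1))$, the fraction of realised links among
  $u$'s $k_u$ neighbours; it measures how module-embedded $u$ is.
* **ECC** — the edge clustering coefficient
  $ECC(u,v) = |N(u) \cap N(v)| / \min(k_u - 1, k_v - 1)$, the saturation
  of possible triangles through an edge (used by the comparison measures
  SoECC and PeC).

CoEWC scores a protein by its partners' module membership, weighted by
co-expression:

$$\mathrm{CoEWC}(u) = \sum_{v \in N(u)} \mathrm{PCC}(u, v)\,\mathrm{CC}(v).$$

The weight deliberately belongs to the *neighbour*, not to the edge or the
protein itself. A party hub sits inside one dense module: its partners
have high CC and correlate with it, so both terms are large. A date hub
bridges several modules: its own CC is near zero (its partners are not
interconnected), but *each partner* sits in some dense module, so the
neighbour-CC weights are still large. A star-like noisy hub has partners
of degree ≤ 1 with CC = 0, annihilating every term regardless of
correlation. Edge-centric weights (ECC, as in SoECC/PeC) cannot make this
distinction for date hubs, because a bridge edge has no common neighbours.

The six measures exposed (`dc`, `cc_measure`, `soecc`, `sopcc`, `pec`,
`coewc`) all return a `score_table` ranked by score descending with ties
broken by ascending protein ID — the ID order is locale-independent
(radix), so top-$k$ sets are reproducible across machines.

## Conventions for degenerate inputs

These are forced by the data-cleaning policy, not free choices:

* Proteins with no expression record carry the all-zero profile; the
  Pearson correlation is undefined on a zero-variance profile and is set
  to 0, the only value that keeps such proteins scoreable.
* $CC(u) = 0$ for $k_u \le 1$ and $ECC(u,v) = 0$ when
  $\min(k_u, k_v) = 1$; denominators of 0 never raise errors, so
  degenerate nodes flow through scoring and ranking.
* Isolated proteins score 0 under every measure.
* Normalising the correlation by $s$ or $s-1$ cancels in the ratio; the
  standard sample correlation is computed.
* Self-interactions and repeated interaction records are dropped at load
  time (their endpoints are kept as nodes); scoring uses the full loaded
  network including small components, with restriction to the largest
  component available as an explicit option (`largest_component()`, or the
  CLI flag `--largest-component`), defaulting off.

The ECC variant question is genuinely open in the literature; the form
above (numerator $|N(u)\cap N(v)|$) is the default because it saturates at
1 exactly when an edge's triangle capacity is exhausted, which matches how
co-clustered neighbours behave in dense modules. The Radicchi form
(numerator $+1$) is available as `variant = "plus_one"` on every
ECC-consuming function.

## Evaluation protocol

Proteins are ranked per measure; `top_k()` counts reference essential
proteins among the first $k$; `jackknife()` walks the ranking and records
the cumulative essential count at every rank, summarised by the area under
that step curve. The integration rule is the trapezoid over ranks
$1..\mathrm{max\_rank}$ (a configurable prefix, default the whole
ranking); AUC values are therefore comparable only at equal depth and
protein-set size. `random_baseline()` builds the same curves for uniform
shuffles of the protein list; under the null the cumulative count at rank
$r$ is hypergeometric with mean $r\,|\mathrm{ess}|/|V|$, which the test
suite checks at 200 shuffles. Proteins missing from the essential list are
non-essential by definition; there is no "unknown" class.
`overlap_analysis()` intersects two measures' top-$k$ sets and reports the
essential fraction of each exclusive set, the protocol for arguing that
one measure's private picks are better. `reference_value()` returns the
score at a fixed rank, for placing an individual protein against a
measure's depth-$k$ cutoff.

## The synthetic generator

Real interactome + expression data are external downloads, so the test
bed is synthetic and encodes the hub taxonomy directly. Defaults (the
study conditions used by every test):

| parameter | default | meaning |
|---|---|---|
| `n_party_hubs`, `n_date_hubs`, `n_noisy_hubs` | 2, 2, 2 | hubs per class |
| `noisy_hub_degree` | 12 | degree of **every** planted hub |
| `clique_sizes` | 12 × 6 | background cliques date hubs bridge |
| `target_pcc_signal` | 0.8 | hub–neighbour population PCC |
| `noise_sd` | 0.2 | sd of independent noise in neighbour profiles |
| `n_samples` | 36 | expression samples, mirroring a typical yeast metabolic-cycle compendium |

Structure: each party hub is a member of a dedicated clique of size
`noisy_hub_degree + 1`; each date hub attaches to one member of each of
`noisy_hub_degree` distinct background cliques; each noisy hub is a star
centre with fresh pairwise non-adjacent leaves. Giving party hubs a
dedicated clique sized by the hub degree — rather than reusing
`clique_sizes` — keeps all three hub classes exactly degree-matched, which
is what makes "degree cannot separate them, CoEWC can" a sharp, binary
claim. Structurally, $CC(\text{party}) = 1$, $CC(\text{date}) = 0$, and a
date hub's partners have $CC = 10/15 = 2/3$ (a 6-clique member plus the
bridge edge), so expected scores are ≈ $12 \times 0.8 \times 1 = 9.6$
(party), ≈ $6.4$ (date) and ≈ $0$ (noisy).

Expression: each party/date hub carries a latent standard-normal profile
$z$; each of its partners gets $\alpha z + (1-\alpha)\,\varepsilon$ with
$\varepsilon \sim N(0, \sigma^2)$ and $\alpha$ solved from
$\alpha/(1-\alpha) = r\sigma/\sqrt{1-r^2}$ so the *population* correlation
equals `target_pcc_signal` $= r$ exactly; everything else is independent
noise. Party and date hubs are labelled essential with probability 1 and
noisy hubs non-essential — the premise that both hub classes are similarly
likely to be essential, made deterministic so acceptance is binary.
Generation is fully reproducible from `seed`.

The small `toy_modular_network()` (three cliques of 20, 30 and 40, a
connector C touching one member of each plus two peripheral nodes) is the
minimal structure where neighbour-clustering weighting and edge-clustering
weighting disagree: C's clique-side partners have CC of 0.9, 0.933 and
0.95 while the peripheral partners have CC 0, so CoEWC weights the
clique-side edges; ECC on those same bridge edges is 0.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: false positive/negative interactions at realistic
rates (only `perturb_network()` offers uniform edge noise, with no degree
bias), overlapping modules, heavy-tailed degree distributions, expression
measured on a shared time course with autocorrelation, and partial overlap
between the network's and the expression data's protein sets beyond
whole-protein absence.

## Problem sizes and numerics

Tests run on graphs of ≤ 126 nodes (planted-hub battery of 20 seeds), the
95-node toy network, 100 random graphs of ≤ 50 nodes for exact oracle
equivalence against adjacency-matrix triangle counting, and 200 shuffles
for the baseline null — sizes at which brute-force oracles are exact and
the whole suite runs in seconds. Scores are doubles throughout;
correlations are clamped to $[-1, 1]$; score TSVs are written at 6
decimals. Exact score ties are resolved lexicographically, but note that
floating-point evaluation can split mathematically tied scores by
$\sim 10^{-16}$, so comparisons of "identical" rankings should be made on
values, not row order.

## Limitations

CoEWC inherits the quality of both inputs: with shuffled or missing
expression it degrades toward a CC-weighted degree, and partners absent
from the expression data contribute nothing even when topologically
informative. The AUC depends on the chosen rank prefix, so cross-study AUC
comparisons require matching depth and ranking length. No statistical
significance testing of AUC differences is provided.
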