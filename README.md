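# coewc

Essential proteins are those whose deletion is lethal or causes
infertility; finding them computationally from protein–protein interaction
(PPI) networks is a standard shortcut around costly knockout screens. The
classical route is the centrality–lethality rule — hubs tend to be
essential — but experimentally determined interactomes are noisy, and hubs
come in two biologically distinct flavours: **party hubs**, embedded inside
one densely connected module and co-expressed with their partners, and
**date hubs**, which bridge several modules and are *not* co-clustered with
their own neighbourhood. Purely topological scores (degree, clustering
coefficient, sum of edge clustering coefficients) miss one class or the
other, and also over-rank star-like hubs whose partners are unconnected
singletons.

`coewc` implements **CoEWC** (Co-Expression Weighted by Clustering
coefficient), which scores each protein *u* as

```
CoEWC(u) = Σ_{v ∈ N(u)} PCC(u, v) · CC(v)
```

where `N(u)` are *u*'s interaction partners, `PCC(u, v)` is the Pearson
correlation of the two genes' expression profiles across samples, and
`CC(v) = 2 e_v / (k_v (k_v − 1))` is the *partner's* local clustering
coefficient. Both hub classes have partners sitting in dense modules, so
both score highly, while noisy star hubs (partners of degree ≤ 1, `CC = 0`)
score near zero. Proteins absent from the expression data carry the
all-zero profile, so their correlations are 0 by convention.

The package also provides:

* the comparison measures `dc()`, `cc_measure()`, `soecc()`, `sopcc()`,
  `pec()` (ECC(u,v) = |N(u)∩N(v)| / min(k_u−1, k_v−1), with a `plus_one`
  variant);
* readers/writers for DIP-style edge lists (self-interactions and repeated
  interactions filtered on load), expression matrices and ID lists;
* a ranking-evaluation protocol: `top_k()`, `jackknife()` cumulative
  essential-count curves with trapezoidal AUC, seeded `random_baseline()`
  shuffles, and `overlap_analysis()` between measures;
* a seed-deterministic synthetic generator (`synthetic_spec()`,
  `generate_network()`, `perturb_network()`, `toy_modular_network()`) that
  plants degree-matched party, date and noisy hubs with controlled
  hub–neighbour co-expression;
* a command-line front end (`inst/cli/coewc.R`) with `score`, `evaluate`
  and `simulate` subcommands.

## Worked example

The essential yeast protein YOL142W has only 6 interaction partners —
degree centrality ranks it nowhere — yet five partners are themselves
essential, well co-expressed with it, and embedded in dense neighbourhoods.
The package ships the reported per-partner values from the yeast DIP
analysis:

```r
library(coewc)
t3 <- read.delim(system.file("extdata", "yol142w_neighbors.tsv", package = "coewc"))
coewc_from_components(t3$pcc, t3$cc)
#> [1] 1.219556
```

`1.2196` agrees with the reported CoEWC score `1.219508` for YOL142W to
the 3–4 decimals the shipped inputs carry — a score that placed it at rank
179, inside the top 200, despite its degree of 6.

A full synthetic run:

```r
lab <- generate_network(synthetic_spec(seed = 7))
lab
#> labeled_network: 126 proteins, 384 interactions, 36 samples; hubs: 2 party, 2 date, 2 noisy; 4 essential
tab <- coewc(lab$network, lab$expression)
print(tab, n = 4)
#> score_table: CoEWC, 126 proteins
#>  rank  protein    score
#>     1     PH01 9.995997
#>     2     PH02 9.557442
#>     3 PH01_M01 8.998476
#>     4 PH01_M03 8.824707
#> ... 122 more rows
top_k(tab, lab$essential, 10)$true_positive_count
#> [1] 2
```

Both party hubs (`PH*`, scores ≈ 9.6–10) and both date hubs (≈ 6.3–6.4)
outrank the noisy star hubs (= 0), while plain degree ties all six at 12
and cannot separate them.

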