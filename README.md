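# pathmult

Networks are not only "small worlds" — they are often *hesitant* worlds: even
between nearby nodes there can be dozens of equally short routes. `pathmult`
quantifies this **path multiplicity** in simple undirected networks and
relates it to community structure. It is aimed at network scientists and
systems biologists who want to measure route redundancy in empirical graphs
(brain connectomes, interactomes, infrastructure) or to generate synthetic
networks that reproduce it.

## What it computes

For a graph $G$ with $N$ nodes, the *path multiplicity amount* $h_{ij}$ is
the number of distinct shortest paths between nodes $i$ and $j$, and the
*path multiplicity index* is their mean over ordered pairs:

$$\Phi(G) = \frac{\sum_i\sum_{j\ne i} h_{ij}}{N(N-1)}, \qquad
  \tilde\Phi(G) = \frac{\Phi(G)}{\Phi(G_{\mathrm{ER}})}$$

where $\tilde\Phi$ (the relative index) normalizes by the mean $\Phi$ of
Erdős–Rényi graphs with the same $N$ and $M$, removing size and density
effects. $\Phi = 1$ exactly on trees, chains, and complete graphs.

The package provides:

* `count_shortest_paths()` — all-pairs shortest-path **counts and lengths
  simultaneously**, via masked adjacency-matrix powers (exact integers,
  validated against an independent BFS oracle);
* `pmi()`, `rpmi()` — the indices above, with a seeded, reproducible ER
  baseline ensemble;
* `detect_communities()` — deterministic leading-eigenvector modularity
  maximization with Kernighan–Lin refinement and recursive subdivision;
* `qcr()`, `quadrant_counts()`, `pearson_r()`, `spearman_rho()` — association
  statistics, including the quadrant count ratio (median-split concordance);
* `optimize_rewiring()` — greedy target-oriented edge rewiring under fixed
  $N$, $M$ and connectivity, recording associated metrics;
* `tsf_graph()`, `gkk_static()` and reference generators (`er_graph()`,
  `nw_graph()`, `ba_graph()`, `cba_graph()`, `rrl_graph()`,
  `match_reference()`) — the Tribal Scale-Free model with planted community
  ground truth, plus density-matched baselines;
* `read_network()` / `write_network()` — edge list, Matrix Market and
  GraphML I/O (Network Repository dialects);
* experiment drivers `run_pmi_vs_density()`, `run_corpus()`,
  `run_rewiring_experiment()`, `run_model_comparison()` and a CLI
  (`inst/cli/pathmult.R`).

## Worked example

Generate a 10-community Tribal Scale-Free network, detect its communities,
and measure its path multiplicity against a density-matched ER baseline:

```r
library(pathmult)

tg <- tsf_graph(300, 10, seed = 7)
tg
#> TSF graph: N = 300  M = 918  n_c = 10  n_e = 2  alpha = 0.5
#>   intra edges: 900  inter edges: 18

detect_communities(tg$graph)
#> Partition: n_c = 10   Q = 0.880386   gamma = 1

rpmi(tg$graph, ensemble_size = 20, seed = 7)
#> RPMI  Phi = 22.2486   Phi_ER = 2.73676   Phi~ = 8.12953  (ensemble 20 )

count_shortest_paths(tg$graph)
#> Path multiplicity matrices for 300 nodes
#>   diameter (k_max): 19
#>   max PMA: 2088   mean PMA: 22.2486
```

The spectral detector recovers all 10 planted tribes exactly (modularity
Q = 0.88). An average node pair in this modular graph is connected by ~22
equally short routes — 8.1× more than in a random graph of identical size
and density, and one pair has 2088 of them. That gap is the hesitant-world
signature: inter-community interfaces multiply length-equivalent route
combinations.

From a shell, the same analyses are available through the CLI:

```sh
Rscript inst/cli/pathmult.R generate tsf --n 300 --nc 10 --seed 7 --out g.mtx
Rscript inst/cli/pathmult.R rpmi g.mtx --ensemble 20 --seed 7
Rscript inst/cli/pathmult.R communities g.mtx
```

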