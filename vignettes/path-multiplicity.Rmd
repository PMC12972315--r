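---
title: "Path multiplicity, community structure, and the TSF model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path multiplicity, community structure, and the TSF model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmult)
```

## The quantity

In a simple undirected graph $G(V,E)$ with $N$ nodes and $M$ edges, many node
pairs are connected by more than one *equally short* route. The **path
multiplicity amount** $h_{ij}$ is the number of distinct shortest paths
between $v_i$ and $v_j$; the matrix $H = (h_{ij})$ collects them, and the
**path multiplicity index**

$$\Phi(G) \;=\; \frac{\sum_i \sum_{j\neq i} h_{ij}}{N(N-1)}$$

is the mean over ordered pairs. $\Phi = 1$ exactly on trees, chains, and
complete graphs (unique shortest paths everywhere); everything above 1
measures route redundancy. Because $\Phi$ depends strongly on size and edge
density $p = \langle k\rangle/(N-1)$, comparisons across networks use the
**relative index** $\tilde\Phi(G) = \Phi(G)/\Phi(G_{\mathrm{ER}})$, where the
denominator is the mean $\Phi$ of an ensemble of Erdős–Rényi $G(N,M)$ graphs
with identical node and edge counts (each reduced to its giant component).
We use $G(N,M)$ rather than $G(N,p)$ so the density matches exactly, and an
ensemble (default 50 realizations, configurable) rather than a single draw so
the baseline has quantified spread.

All analyses operate on connected graphs; disconnected input is refused with
a pointer to `giant_component()` rather than silently computed.

## Counting all shortest paths at once

`count_shortest_paths()` exploits the fact that $(A^k)_{ij}$ counts walks of
length $k$, and that a walk whose length equals the graph distance is
necessarily a shortest path. Iterating $k = 1, 2, \dots$, the first $k$ at
which a pair acquires a nonzero walk count delivers both the distance
($l_{ij} = k$) and the count ($h_{ij} = (A^k)_{ij}$); a mask of unresolved
pairs confines each deposit to newly resolved pairs. The loop terminates at
$k = $ diameter, and refuses disconnected input when $k$ reaches $N-1$ with
pairs still unresolved.

Two numerical choices matter:

* **Masked propagation.** The literal power $A^k$ accumulates walk counts
  that grow like $\rho(A)^k$ and overflow the exact-integer range of doubles
  ($2^{53}$) on graphs of a few hundred nodes, even though the true path
  counts are tiny by comparison. We therefore propagate only the freshly
  resolved layer: after the deposit at step $k$, entries not at distance
  exactly $k$ are zeroed before the next multiplication. Every predecessor of
  $j$ on a shortest $i$–$j$ path of length $k+1$ sits at distance exactly $k$
  from $i$, and a length-$k$ walk to a closer vertex can never extend into a
  first arrival, so the deposited values are provably identical to the
  literal scheme while magnitudes stay at the scale of real path counts.
  An overflow guard still errors (rather than returning inexact integers) if
  counts themselves approach $2^{53}$.
* **Diagonal masking.** Closed walks would otherwise deposit degree counts on
  the diagonal at $k = 2$; the mask keeps both diagonals zero, and the length
  update applies only to newly resolved pairs so lengths are true distances.

Correctness is established against two independent routes: a per-source BFS
with predecessor-layer count accumulation (`brute_force_count()`), and
igraph's `all_shortest_paths()`, both compared entrywise over hundreds of
random graphs spanning trees, cycles, bipartite, ER and planted-community
topologies.

## Association: the quadrant count ratio

`qcr()` dichotomizes each variable at its sample median and reports the
fraction of observations in the direction-concordant quadrants
($\mathrm{QCR}_+ = (n_I + n_{III})/n$, $\mathrm{QCR}_- = (n_{II}+n_{IV})/n$).
The inclusive quadrant definitions overlap on the median lines, so a point on
a boundary is assigned once, to the concordant quadrant for the hypothesized
direction, and `boundary_count` reports how often that happened. This keeps
the partition identity $n_I+n_{II}+n_{III}+n_{IV} = n$ exact while honoring
the inclusive convention. The statistic is invariant under strictly monotone
transforms of either variable; only the median split is implemented. Pearson
and Spearman coefficients are thin validating wrappers over `stats::cor()`.

## Community detection

`detect_communities()` is a deterministic leading-eigenvector modularity
maximizer. For a vertex subset $U$ the generalized modularity matrix
$B^{(U)}_{ij} = B_{ij} - \delta_{ij}\sum_{\ell\in U} B_{i\ell}$ (with
$B = A - \gamma\,\mathbf{k}\mathbf{k}^\top/2M$) has zero row sums, so the
undivided state is exactly neutral and the bipartition quality is
$s^\top B^{(U)} s / 4M$. The dominant eigenvector's signs give the initial
split, a Kernighan–Lin-style single-vertex refinement polishes it (each
vertex moved at most once per pass, best prefix kept), and a subdivision is
accepted only if the modularity gain exceeds $10^{-10}$; recursion stops when
every group is indivisible (leading eigenvalue $\le 10^{-12}$).

Numerical determinism choices: the eigenvector sign is fixed so its first
nonzero entry is positive; zero entries are assigned to the $+1$ group (with
a message); refinement ties break toward the smallest vertex index. The
dominant eigenpair is obtained from a dense symmetric `eigen()` on
$B^{(U)}$ rather than an iterative method: at the problem sizes this package
targets (up to a few thousand nodes) the dense solve is fast, and it is
robust to the degenerate leading eigenvalues that stall power iteration on
symmetric fixtures. The $O(M+N)$ implicit product (`modularity_matvec()`) is
retained and tested against the dense matrix, so an iterative backend could
be swapped in for much larger graphs. Resolution $\gamma$ multiplies the
null term and defaults to 1. Walktrap/Louvain/label-propagation/Infomap are
available as clearly flagged igraph pass-throughs for robustness comparisons
only.

## Target-oriented rewiring

`optimize_rewiring()` greedily maximizes a scalar objective (path
multiplicity index, community number, clustering, diameter, or
assortativity) under hard constraints: node count, edge count and
connectivity are preserved at every accepted state. An elementary move
deletes one uniformly chosen edge and adds one uniformly chosen
previously-absent pair — degree sequences are *not* preserved, since only
size, density and connectivity are constrained. Each iteration draws
`trials` candidates (default 20), each applying a uniform budget
$b \in [1, b_{\max}]$ of elementary moves (default $b_{\max} = \max(1,
M/10)$, a scale-free ~10% perturbation); the best candidate is selected,
ties (including ties with the current value) resolved uniformly at random,
and a candidate set that is strictly worse than the current state leaves the
state unchanged — hence the recorded target series is non-decreasing. The
first recorded iteration is the best initial candidate, not the seed graph.
Objectives are recomputed from scratch on every candidate; correctness over
speed at desk scale.

### What the desk-scale rewiring experiments do and do not show

The package's test suite probes whether maximizing $\Phi$ drags the
community number upward (and conversely) on 30-node ER seeds with 50
iterations of 10 trials. That experiment verifies the optimizer's contracts
(monotone target, conserved constraints, determinism), but in our runs it
does **not** exhibit the community–multiplicity coupling reported for
large networks, and we believe the coupling has a scale floor rather than
the implementation a defect. Two observations support this. First, on 40-node
graphs the optimizer raises $\Phi$ four-fold while the detected community
number *falls*: the high-$\Phi$ optima at this size are bipartite-lattice-like
cores with near-zero clustering, and deliberately modular planted graphs of
identical size and density only reach $\Phi \approx 2$ — at small $N$,
community interfaces are simply not the dominant channel for route
redundancy. Second, at $N = 150$–$300$ a 10-trial greedy budget moves $\Phi$
by only 15–30% over 50–120 iterations, far too little for the associated
metric to respond above detection noise. Reproducing the coupling appears to
require both hundreds-to-thousands of nodes and orders of magnitude more
accepted rewirings than a desk-scale budget affords.

## Generators

* `gkk_static(n, m, alpha)` — static scale-free model: vertex $v$ carries
  weight $\propto v^{-\alpha}$, $\alpha \in [0,1)$; weighted pairs are drawn
  (independently, rejecting coincident endpoints and existing edges) until
  $m$ edges exist. The degree-distribution tail exponent is
  $\lambda = (1+\alpha)/\alpha$; $\alpha = 0$ is the homogeneous limit.
* `tsf_graph(n, n_c, intra_degree, alpha, n_e)` — the Tribal Scale-Free
  model: nodes are randomly assigned to $n_c$ near-equal communities
  ($\lfloor N/n_c\rfloor$ with the remainder spread over the first
  communities — deterministic sizes keep the structural identities sharp);
  each community is a GKK subnet with a common $\alpha$; communities are
  joined into one component with $n_e$ uniformly placed cross edges per
  joining step, giving exactly $n_e(n_c-1)$ inter-community edges. Defaults:
  `intra_degree = 6` (sparse but comfortably above the connectivity
  threshold for the community sizes used), `alpha = 0.5` (tail exponent 3,
  the canonical heavy-tail regime), `n_e = 2` (sparse interfaces that keep
  the planted partition crisp).
* Connectivity: an unconditioned GKK draw leaves isolated low-weight
  vertices often enough that the union of subnets is rarely connected
  (measured ~3% at $N=400$, $n_c=4$, `intra_degree = 6`). Each subnet is
  therefore drawn conditionally on internal connectivity (bounded retries),
  which guarantees a single component and keeps the edge-count identity
  exact. This conditions the subnet distribution on connectivity — the same
  practice as for any connected-graph benchmark — and is the one deliberate
  departure from a fully unconditioned composition.
* Reference models: ER ($G(N,M)$ or $G(N,p)$), regular ring lattices,
  Newman–Watts (ring lattice plus added shortcuts, no removal),
  Barabási–Albert, and a clustered BA variant with triad-formation
  probability (default 0.5). `match_reference()` draws any of these, or a
  TSF graph, with the node count of a reference graph and an edge count as
  close as the model's granularity permits.

### What the synthetic corpus emulates

`run_corpus()` mirrors a heterogeneous observational corpus: many networks
of different sizes and community counts, each summarized by classical
metrics, $\Phi$, $\tilde\Phi$ and the detected $n_c$, followed by
metric-versus-$\tilde\Phi$ association statistics. The test fixtures hold
the *tribe size* fixed (30 nodes) and vary the *number* of tribes, so that
$N$ grows with $n_c$ as in real corpora. Holding $N$ fixed instead and
sweeping $n_c$ produces a humped $n_c$–$\tilde\Phi$ relation — once
intra-community density approaches 1 the tribes saturate toward cliques,
leave the scale-free regime, and route redundancy falls — which is a model
property, not a corpus analogue. Synthetic fixtures share none of the noise
sources of real data (measurement error, degree heterogeneity across
communities, overlapping communities), so a passing association test shows
the pipeline and the direction of the effect, not field realism.

## Problem sizes and runtime choices

Tests and the acceptance checks use: oracle equivalence on 200 random
graphs with $N \le 40$; structural identities on 100 TSF draws ($N$ up to
180); parameter recovery on 50 TSF draws at $N = 400$ with planted
$n_c \in \{4, 8, 16\}$ and RPMI ensembles of 6 (directional $\tilde\Phi > 1$
assertions need no larger baseline); rewiring ensembles of 10 seeds at
$N = 30$. These sizes were chosen so the full suite completes in minutes on
one core while keeping every assertion at its exact or statistical strength.

## Known limitations

* Path counts are exact only below $2^{53}$; beyond that the counter errors
  out rather than approximating. No arbitrary-precision backend is wired in.
* Unweighted graphs only; no tolerance band for near-shortest paths.
* The rewiring optimizer is purely greedy (no annealing), and objective
  evaluation is not incremental, so large graphs are slow.
* Leading-eigenvector detection inherits modularity's resolution behavior;
  on very small or near-degenerate subsets it can differ from other
  maximizers at equal modularity.
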