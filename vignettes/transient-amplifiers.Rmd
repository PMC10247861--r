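---
title: "Finding transient amplifiers of selection for death-Birth updating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding transient amplifiers of selection for death-Birth updating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transamp)
```

## The model

A population of $N$ individuals lives on a simple connected undirected graph
$\mathcal G$, one individual per vertex. Residents have fitness 1, a mutant
type has fitness $r > 0$. Under **death-Birth (dB) updating** a uniformly
random individual dies and one of its neighbors, chosen with probability
proportional to fitness, places a copy of itself on the vacant vertex. With
**uniform initialization** the mutant arises on a uniformly random vertex, and
$\varrho_{\mathcal G}(r)$ denotes the probability that the mutant line
eventually occupies the whole graph.

Structures for which $\varrho_{\mathcal G}(r) > \varrho_N(r)$ (the
complete-graph baseline) amplify selection. For dB updating no graph amplifies
universally; at best a graph is a **transient amplifier**, beating the
complete graph only on a bounded fitness window $1 < r < r_{\max}$. Transient
amplifiers for dB updating are rare and, at small orders, were long thought
not to exist at all. This package implements a search procedure that finds
them by perturbing regular graphs, plus the analysis tools around it.

## The weak-selection test

The workhorse is a weak-selection criterion built from coalescing random
walks. Two walkers sit on vertices $i$ and $j$; each step, one of the two
(probability $1/2$ each) moves to a uniformly random neighbor. The expected
meeting times $\tau_{ij}$ solve the linear system over unordered pairs

$$\tau_{ij} = 1 + \tfrac12 \sum_k \left(p_{ik}\tau_{jk} + p_{jk}\tau_{ik}\right),
  \qquad \tau_{ii} = 0, \qquad p_{ij} = e_{ij}/k_i ,$$

from which the per-vertex remeeting time
$\tau_i = 1 + \sum_j p_{ij}\tau_{ij}$ and, with relative degrees
$\pi_i = k_i / \sum_j k_j$, the **effective population size**

$$N_{\mathrm{eff}} = \sum_i \pi_i \tau_i$$

are computed. The identity $\sum_i \pi_i^2 \tau_i = 1$ holds on every
connected graph and serves as a built-in correctness check.
$N_{\mathrm{eff}} > N$ certifies an amplifier of weak selection; for every
$k$-regular graph $N_{\mathrm{eff}} = N$ exactly (the isothermal situation),
so only non-regular structures can pass the test.

```{r identity}
pet <- igraph::make_graph("Petersen")
res <- effective_population_size(pet)$result
c(identity_sum = sum(res$pi^2 * res$tau_remeet), n_eff = res$n_eff)
```

The pair system is solved densely (LAPACK) up to 1500 unknowns and sparsely
(LU on the pair-system matrix, roughly $k_i + k_j$ nonzeros per row) beyond
that; the two paths agree to $10^{-9}$ on shared sizes and the threshold is
purely a performance choice.

## The guided edge-removal search

Since regular graphs sit exactly at $N_{\mathrm{eff}} = N$, the search
perturbs them: starting from a connected $k$-regular graph, edges are removed
one at a time, at most $1 + (k-2)N/2$ in total (beyond that a connected graph
cannot lose further edges). A perturbation argument suggests removing edges
where the remeeting time grows fastest, so every candidate graph carries its
history $\tau_i(0), \tau_i(1), \ldots$ along its lineage and selects the
vertex maximizing the **moving difference**
$\Delta^j \tau_i = \tau_i(j) - \tau_i(j-1)$ ($\tau_i$ itself at $j = 0$). The
exact forward difference $\sum_p (-1)^{j-p}\binom{j}{p}\tau_i(p)$ is available
as an alternative (`difference = "forward"`), but the moving difference is the
default as it performs better as a guide.

Each step, every pool member spawns one child per edge at its selected
vertex. Children that disconnect are discarded. The pooled children are
deduplicated by their **cospectral key** — the sorted normalized-Laplacian
spectrum rounded to 9 decimals — a cheap proxy for isomorphism (isomorphic
graphs are always cospectral; non-isomorphic cospectral mates are rare at
these sizes). In greedy mode only the `filter_size` (default 500) children
with the smallest algebraic connectivity $\lambda_2$ of the normalized
Laplacian survive: low $\lambda_2$ means bottlenecks and near-disconnection,
which is exactly where amplifiers live. Every retained child is tested with
the $N_{\mathrm{eff}}$ criterion; hits are recorded and expanded further
(consecutive amplifiers along one lineage do occur).

```{r search, eval = FALSE}
inputs <- regulars_from_cycle_partitions(11) # the six 8-regular graphs
camp <- run_campaign(inputs, search_config())
glance(camp)
```

On the six 8-regular graphs on 11 vertices this campaign takes well under a
minute and finds one non-isomorphic transient amplifier — reached from every
input — with $N_{\mathrm{eff}} = 11.0008$, mean degree $3.82$ and
$\lambda_2 = 0.057$: two near-complete clusters joined by a short bridge.

### Determinism and its limits

Three conventions are open wherever the procedure is under-determined, and
all three are fixed deterministically:

* **Vertex ties** in the argmax are broken by the lowest vertex index.
* **Pool order**: after dedup the pool is always sorted by
  (filter measure, cospectral key); the greedy filter is then a plain
  truncation. Since keys are unique after dedup this order is total.
* **Cospectral collisions**: when two lineages produce the same key in one
  step, the first in pool order survives and keeps its own $\tau$ history.

The *set* of amplifier graphs found is robust under reasonable variations of
these conventions, but the *number of input graphs* that reach an amplifier
is not: because the surviving lineage's $\tau$ history steers later vertex
selections, collision handling can flip individual inputs between success and
failure. Counts of contributing inputs should therefore be read as
convention-dependent; the non-isomorphic amplifier set and its
$N_{\mathrm{eff}}$ values are the stable quantities.

### Spectral dynamics

With `record_dynamics = TRUE` the search stores every retained member's
normalized-Laplacian spectrum. [spectral_dynamics()] then splits, for each
removal count $\ell$, the pool into members whose lineage eventually reaches
an amplifier and members whose lineage does not, forms the two ensemble
densities

$$\varphi(x) = \frac{1}{N}\sum_i \frac{1}{\sqrt{2\pi\sigma^2}}
  \exp\!\left(-\frac{(x - \lambda_i)^2}{2\sigma^2}\right),
  \qquad \sigma = \frac{1}{3N},$$

and integrates $d = \int_0^2 |\varphi - \varphi'|\,dx$ (trapezoidal rule on a
2001-point grid over $[0,2]$; the grid is dense relative to $\sigma$ so the
quadrature error is negligible against the distances of interest). Amplifier-
bound evolutions show a narrower travelling $\lambda_2$ peak and a growing
multiplicity peak near $x \approx 1.1$; the distance is large at the start
and the end of the process. The same density machinery accepts standard-
Laplacian spectra, where the grid spans $[0, 2\Delta(\mathcal G)]$ and the
same $\sigma$ rule is reused (recorded in the object).

A comparison mode filters by $\mu_2$ of the standard Laplacian instead
(`filter_measure = "mu2"`); it drives the pool away from the structures that
amplify and is expected to find nothing — it exists to make that negative
result reproducible.

## Bell-like graph families

The amplifiers found by the search resemble two dense blocks joined by a
bridge, which motivates closed families: barbell $B(a,b)$ (complete blocks),
dumbbell $D(a,b)$ (cycle blocks), Moebius-ladder bells $M(a,b)$ and
antiprism bells $A(a,b)$, each with one bridge of $b$ edges
($N = 2a + b - 1$) or two vertex-disjoint bridges at adjacent bridgeheads
($N = 2a + 2(b-1)$; the two-bridge order formula follows from the same
interior-vertex count and is recorded in the scan metadata). Bridgeheads are
block vertices 1 (and 2), irrelevant up to isomorphism because all four
blocks are vertex-transitive; for the antiprism's two-bridge variant the
offset-1 neighbor is used. $a = 4$ Moebius/antiprism blocks degenerate to
$K_4$, which is allowed deliberately — the smallest members live there.

```{r bells}
scan_family("barbell", 1, a_values = 8, b_values = c(2, 4, 8, 16))[, -(1:2)]
smallest_amplifier("barbell", a_max = 8, b_max = 12)
```

One-bridge barbells amplify for every tested $a$ once $b > 3$; the smallest
amplifying member is $B(4,5)$ with $N = 12$, and the Moebius family matches
it via the $K_4$ degeneracy. Two-bridge variants stay below
$N_{\mathrm{eff}}/N = 1$ everywhere we scan. The smallest amplifying dumbbell
found by the scan is $D(3,11)$ with $N = 16$ and a margin of only
$+7\cdot10^{-4}$ — margins this small sit far above the $10^{-9}$ solver
noise but are invisible on a ratio plot, so scans near the onset of
amplification should always be read from the numbers, not the curves.
`smallest_amplifier()` walks the $(a,b)$ box in ascending $N$ and stops at
the first amplifying order, so only small systems are ever solved.

## Exact fixation probabilities

The weak-selection test is tangential at $r = 1$; whether a certified graph
really beats the complete graph at finite $r$ is settled by the full chain.
`fixation_exact()` solves the absorbing Markov chain over all $2^N$ mutant
configurations (dense LAPACK solve after sparse aggregation — the
configuration hypercube causes catastrophic fill-in under sparse LU, so dense
is faster here), feasible to $N = 13$. `fixation_mc()` is the simulation
fallback beyond that. `classify()` compares $\varrho_{\mathcal G}$ with the
complete-graph closed form (the lumped birth-death chain) on a grid spanning
$r = 1$ and reports amplifier / suppressor / transient amplifier / other,
bisecting detected sign changes above $r = 1$ to bracket $r_{\max}$. The
classification is reported, never enforced: the transient window of the
graphs found here is narrow (for $B(4,5)$, roughly $1 < r < 1.015$, with a
difference of order $10^{-6}$), so grids must be chosen accordingly.

```{r fixation}
b45 <- make_bell("barbell", 4, 5)
c(rho_at_1 = fixation_exact(b45, 1),
  diff_1.01 = fixation_exact(b45, 1.01) - fixation_complete(12, 1.01),
  diff_2 = fixation_exact(b45, 2) - fixation_complete(12, 2))
```

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `filter_size` | 500 | greedy pool bound; smaller is faster, larger is not reliably better |
| `filter_measure` | `"lambda2"` | spectral filter; `"mu2"` is the negative control |
| `max_removals` | $1 + (k-2)N/2$ | connectivity bound on total removals |
| `amplifier_tol` | $10^{-9}$ | margin on $N_{\mathrm{eff}} - N$; real margins are $\ge 7\cdot10^{-4}$ |
| `cospectral_decimals` | 9 | dedup rounding; eigensolver noise is $\sim 10^{-12}$ |
| `sigma` | $1/(3N)$ | spectral-density kernel width |
| `tol` (classify) | $10^{-10}$ | tolerance on $\varrho$ differences |

## Conventions and scope

Vertices are indexed `1..N` in memory, following the R and igraph
convention; the on-disk edge-list format stays 0-based and graph6 is
index-free, so files interoperate with other tools. Graphs are igraph
objects throughout; tabular results (scans, campaign statistics, fixation
curves) are tibbles, and fitted objects carry `tidy()`/`glance()`/
`autoplot()` methods.

The synthetic input generators cover what the method actually consumes:
`regulars_from_cycle_partitions()` constructs all $(N-3)$-regular graphs as
complements of disjoint cycle unions (one per cycle partition, pairwise
non-isomorphic by construction), and `enumerate_regulars()` backtracks over
small $(N,k)$ for exhaustive cross-checks. These are real input spaces, not
stochastic mocks — the only randomness anywhere is in `fixation_mc()` and in
test fixtures. What passing tests do *not* show is behaviour on graph orders
beyond the tested range ($N \lesssim 30$ for searches, $N \le 13$ for exact
fixation) or on weighted/directed structures, which are out of scope.

Campaign problem sizes used in the shipped tests and the acceptance script:
the full six-input 8-regular campaign on 11 vertices (filter 500), cubic
exhaustive/greedy equivalence up to $N = 8$, bell scans up to
$N = 123$, and 200-graph random batteries for the identity and spectral
property suites. These sizes were chosen so the whole suite stays at desk
scale while still exercising every code path at full fidelity.

## Known limitations

* The cospectral proxy can in principle merge non-isomorphic cospectral
  mates, discarding a lineage; exact canonical keys are used for final
  non-isomorphic counts only.
* Counts of inputs-with-amplifier are sensitive to collision-lineage
  conventions (see above); amplifier sets are the robust output.
* `fixation_exact()` is exponential in $N$ by design; `classify()` inherits
  the $N \le 13$ bound.
* Coalescence quantities are defined here for simple unweighted undirected
  graphs only.
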