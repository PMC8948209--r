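---
title: "Observer-based source localisation on networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer-based source localisation on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silocate)
```

## The problem

A spreading process — an infection, a rumour — starts at one unknown node
of a known undirected graph. We cannot watch the whole network; only a
budget of K < N *observers* record the time the spread first reached them.
From the graph topology and those K arrival times alone, we want to rank
every node by how plausible it is as the origin. `silocate` implements the
three layers of this experiment: the spreading model, the observer
placement strategies, and the localisation estimators, together with the
metrics used to compare them.

## Spreading model and its delay moments

The simulator is a synchronous agent-based Susceptible–Infected process.
At each discrete step every infected node independently tries to infect
each susceptible neighbour with probability β (the infection rate). A
susceptible node with m infected neighbours is therefore infected this
step with probability 1 − (1−β)^m — equivalent to independent per-edge
trials and order-free, as a simultaneous update must be. There is no
recovery; on a connected graph the process runs to completion.

Two consequences matter for the estimators:

* at β = 1 arrival times equal hop distances from the source (the process
  is a breadth-first front), which gives exact recovery checks;
* the first-passage delay across a single link is geometric with mean
  μ = 1/β and variance σ² = (1−β)/β².

The Gaussian-based estimators (LPTV, GMLA, EPL) need a per-link delay
mean and variance. The simulation produces geometric, not Gaussian,
delays — deliberately so: the benchmark asks how the estimators cope when
their distributional assumptions are violated, as they are for any real
epidemic. `delay_model(beta)` therefore plugs in the geometric moments by
default; both can be overridden (`delay_model(mu =, sigma2 =)`), which the
test suite uses to drive the estimators under their own Gaussian
assumptions.

## Observer placement

All four strategies return exactly k distinct nodes, and every tie is
broken by ascending vertex index, so placements are deterministic for a
fixed indexing.

* **BC** ranks nodes by betweenness centrality. The set objective is a
  per-node sum, so the optimal set is the top-k ranking.
* **HCR** greedily maximises the coverage rate — the fraction of nodes
  adjacent to at least one observer. Coverage uses *open* neighbourhoods:
  an observer does not cover itself (it is covered only if it neighbours
  another observer). Because coverage saturates at 1 well below the
  densities of interest, the objective escalates: once every node is
  covered, subsequent observers maximise the number of double-covered
  nodes, then triple-covered, and so on.
* **HVO** covers shortest paths instead of neighbourhoods: it maximises
  the number of nodes lying on shortest paths (of length at most L)
  between observer pairs, with the same multiplicity escalation
  (single-path-covered, then double-, ...). Path multiplicity is counted
  exactly through shortest-path counts: node v lies on
  σ(a,v)·σ(v,b) shortest a–b paths whenever d(a,v)+d(v,b) = d(a,b). The
  initial pair is the exhaustive best over all node pairs. The length
  cutoff L is exposed as `max_len` and defaults to unlimited — with no
  cutoff the objective is the least truncated, and the choice of L is a
  free parameter of the method rather than something the problem dictates.
* **RND** is the uniform null model.

## Localisation estimators

Every method produces a `score_table`: a score F(s) per candidate, the
argmax set, and the set of candidates actually evaluated.

**LPTV** assumes propagation along a shortest-path tree rooted at the
candidate s with i.i.d. Gaussian per-link delays. With observer delays
taken relative to the reference observer o₀, the score is the Gaussian
log-likelihood up to constants, F(s) = μₛᵀ Λ⁻¹ (d − ½μₛ). The BFS tree is
made deterministic by always choosing the lowest-index shortest
predecessor as a parent. The covariance entry for observers k and i is σ²
times the number of tree edges shared by the paths o₀→oₖ and o₀→oᵢ —
computed here from tree depths and lowest common ancestors, which on a
tree is algebraically identical to intersecting edge sets. The reference
observer is the one with the smallest arrival time (ties by index): the
source is most likely near the first-informed observer, and this keeps
LPTV consistent with GMLA's anchor. Only arrival times are used (the
limited-information variant); the identity of the transmitting neighbour
is assumed unavailable.

**TRBS** needs no reference observer: it compares absolute arrival times
with μ·(hop distance) from each candidate and scores by the negative
variance of the residuals. Adding a constant to all observed times leaves
the scores unchanged.

**PC** is the Pearson correlation between hop distances and arrival
times. Scale-invariance makes the delay mean irrelevant, so raw hop
counts enter the correlation. A candidate whose distances to all
observers are equal has an undefined correlation and is assigned the
sentinel −2, below any valid score — such a candidate is uninformative
and should never win. If the observed times themselves have zero
variance, no candidate is distinguishable: all scores are set equal and
the table is flagged `degenerate`.

**GMLA** reduces LPTV's cost and noise by keeping only the K₀ observers
with the smallest arrival times and hill-climbing: score the neighbours
of the first-informed observer, move to the best neighbour whose score is
at least the current maximum, and repeat until no unvisited neighbour
qualifies. A visited set prevents revisiting plateau nodes, guaranteeing
termination; the anchor observer itself is also scored so the evaluated
set always contains it. Nodes the climb never reaches are unscored and
receive the maximum rank N in evaluation — the occasional outsized
credible sets this produces are a real property of the method. K₀
defaults to max(5, ⌈√N⌉) (capped at K): the method's published motivation
is that distant observers contribute little, and a √N-scale neighbourhood
keeps the restricted problem well-conditioned at the graph sizes used
here; it is exposed in `gmla_config()`.

**EPL** drops the tree assumption. Each shortest path between candidate
and observer is a Gaussian traversal time with mean Lμ and variance Lσ²;
with n parallel shortest paths the expected arrival is the mean of their
minimum. The closed form for the minimum of two correlated Gaussians
(through θ = √(σ₁² + σ₂² − 2ρσ₁σ₂)) supplies the moments, with the
correlation between two paths defined as their shared-edge fraction; for
n > 2 the ensemble is approximated by two independent paths (ρ = 0). The
observer covariance couples the shortest-path ensembles from each
observer to the reference observer: the Jaccard index of their edge
unions times the geometric mean of their min-distribution variances. This
matrix does not depend on the candidate and is computed once per observer
set. Path listings are capped (default 64 per node pair), which is
lossless for the moments — only the count and, for n = 2 exactly, the
shared-edge fraction enter them, and both the exact count and the exact
edge unions come from the predecessor DAG independent of the cap.

### Numerical choices

* Singular covariances occur legitimately (β = 1 gives σ² = 0; duplicated
  tree paths). All quadratic forms add a ridge ε·I with
  ε = 10⁻⁹·max(diag, 1) and use a linear solve, never an explicit
  inverse. At σ² = 0 the LPTV score degenerates gracefully to the
  least-squares criterion μₛᵀ(d − ½μₛ), which still recovers exact-delay
  sources.
* The min-of-Gaussians variance is clamped at zero against round-off, and
  θ = 0 (perfectly correlated equal-variance paths) returns the
  smaller-mean variable's moments exactly.
* All tie-breaks (parents in BFS trees, placement picks, reference
  observers, argmax reporting) resolve by ascending vertex index;
  given a seed, every pipeline stage is bit-reproducible.

## Evaluation metrics

Per-test precision is 1/|argmax set| when the true source is among the
top-scored nodes and 0 otherwise; it is averaged over realisations. The
credible set size CSS_α is the smallest k such that the true source
ranked within the top k in at least a fraction α of realisations — the
⌈αn⌉-th order statistic of the ranks. Ranks are pessimistic competition
ranks (a node is placed last among its ties, and unevaluated nodes rank
N), which makes CSS conservative; with α = 0.95 a uniformly random scorer
on N nodes yields CSS ≈ 0.95·N, while a perfect localiser yields 1.

`run_cell()` orchestrates one parameter cell. For synthetic networks the
graph is redrawn per realisation block (10 graphs by default, the
realisations split evenly) so results average over topologies as well as
spreads; deterministic placements are computed once per graph and random
placements redrawn per graph. One master seed drives child seeds for
every graph, placement and realisation, so any single realisation can be
reproduced in isolation.

## What the synthetic generators do and do not emulate

The Barabási–Albert generator (preferential attachment from a complete
seed of m+1 nodes, m = ⟨k⟩/2) produces the heavy-tailed degree
distributions of social and contact networks; the Erdős–Rényi G(N,p)
model with p = ⟨k⟩/(N−1) is the homogeneous counterpart. If an ER draw is
disconnected the giant component is kept and reindexed — spreading cannot
leave a component, and distance-based scores need finite distances; the
discarded fraction is recorded on the graph. These models capture degree
heterogeneity but not clustering, community structure, degree
correlations or temporal edges of real networks, so conclusions from
passing benchmarks transfer to real data only qualitatively. Empirical
edge lists load through `read_edge_list()`, with the conventional
preprocessing (symmetrise; iteratively prune nodes of degree < 2, since
removal can drag neighbours below the threshold) available as
`prune_low_degree()`.

## Problem sizes

The default study conditions follow the published experimental design
(infection rates β ∈ {0.2, 0.5, 0.8}, observer densities around
d = 0.1–0.2, BA/ER topologies with ⟨k⟩ = 8) at reduced network size:
benchmark cells run on N = 200 graphs with 400 realisations, recovery
and oracle checks on N ≤ 50 graphs, and the Gaussian-assumption checks on
trees with N ≤ 15 and 1000 replicates. These sizes give stable regime
comparisons (the low-β dominance of PC over TRBS is detected by a
one-sided proportion test at 95% confidence) while keeping the whole
suite desk-scale.

## Known limitations

* Directed, weighted and temporal graphs are out of scope; edge lists are
  symmetrised on load.
* Only single-source spreads are considered, and only the SI compartment
  model (no recovery).
* The EPL two-path approximation treats n > 2 parallel paths as two
  independent ones; for graphs with massive path multiplicity the
  resulting means are biased upward.
* LPTV's full-information variant (which also observes the transmitting
  neighbour) is deliberately not implemented.
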