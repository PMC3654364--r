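---
title: "Finding conserved interaction modules by cross-species network alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding conserved interaction modules by cross-species network alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consnet)
```

## The model

`consnet` aligns two or three protein–protein interaction (PPI) networks
globally, looking for *conserved interaction modules*: groups of
functionally orthologous proteins whose mutual interactions are present in
every (or almost every) aligned species. The central object is the
**alignment graph**. Its nodes are cross-species protein tuples — one
protein per species, drawn from one precompiled homolog group (KO-style
functional orthologs) — and its edges mark interactions conserved across
the compared networks. Conserved modules are simply the connected
components of this graph, which makes the clustering step parameter-free
and linear in the size of the alignment graph.

The approach leans on one biological assumption: proteins placed in the
same functional-ortholog group (same KO term) perform the same role in
each species, so the cross-product of a group's per-species members is a
sound node candidate set. This is deliberate: true ortholog groups are few
relative to the proteome, so starting from them is much cheaper than
all-against-all sequence matching, and it front-loads biological meaning
into the node set. The cost is equally deliberate: anything the homolog
table misses can never be aligned.

### Edge rules

For a pairwise alignment, nodes $u = (a_1, b_1)$ and $v = (a_2, b_2)$ are
joined iff $(a_1, a_2)$ is an edge of the first species' network *and*
$(b_1, b_2)$ is an edge of the second's. Two nodes sharing a protein are
never joined — a protein cannot conserve an interaction with itself across
the same node pair — and self-interactions are kept by the loaders but
ignored by the edge builder, since a self-loop carries no between-node
information.

For a three-way alignment the strict rule would demand a direct
interaction in all three species; with today's patchy interactomes this is
too brittle. The relaxed rule requires a direct interaction in at least
`min_direct = 2` species and an unweighted shortest-path distance of at
most `max_indirect_distance = 2` between the members in every remaining
species. An unreachable pair simply yields no edge. Edge provenance
(`direct` vs `distance-k`, per species) is recorded so downstream analyses
can distinguish fully conserved edges from rescued ones.

### Component finding

The component finder implements a Tarjan lowlink traversal over the
symmetrized arc set — each undirected edge contributes both arcs. On such
a symmetric relation, strongly connected components coincide with
connected components, so the strongly-connected machinery doubles as a
plain component finder while keeping the lowlink structure. Two
engineering choices matter:

* the DFS uses an **explicit stack** (no recursion), so pathological
  components — a 5000-node path, say — cannot exhaust the interpreter's
  recursion limit;
* nodes are visited in ascending `node_id` and cluster ids assigned in
  emission order, so the output is a pure function of the input graph.

An independent breadth-first flood fill (`components_oracle()`) ships with
the package purely as a cross-check; the test suite verifies the two agree
on hundreds of random graphs, and once against `igraph::components()` as a
third, external implementation.

## Scoring

Each cluster $C$ receives $\mathrm{Score}(C) = w_1 S(C) + w_2 I(C) + w_3
F(C)$, a normalized value in $[0, 1]$, with equal default weights
$w_i = 1/3$ — no component is privileged a priori, and the three terms
deliberately measure different evidence axes (genome, interactome,
functome):

* **Sequence/ortholog confidence** $S(C) = \sum_k s(k) / |C|$. Under the
  ortholog rule, $s(k) = 1$ iff all of node $k$'s members share a KO term.
  Under the BLAST rule, a node whose cross-species e-value is at most the
  cluster's arithmetic-mean e-value gets 1, otherwise the ratio of that
  mean to its e-value. Both "BLAST score" and the comparison baseline are
  read as e-values (smaller = better) — the only reading under which the
  ratio branch lands in $[0, 1]$. A node with no similarity record scores
  0 rather than erroring: absence of evidence is treated as no
  confidence. The ortholog rule is applied per node so that $S(C)$ retains
  its per-node decomposition; a strict cluster-level variant (all proteins
  of the whole cluster share one term, giving $S \in \{0, 1\}$) is
  available as `confidence = "ortholog_cluster"`.
* **Interaction conservation** $I(C) = i(C) / (|C|(|C|-1)/2)$ — observed
  conserved interactions over the clique count. Because component sizes
  vary widely, $I$ is then normalized across clusters: values above the
  across-cluster mean are reset to 1, the rest to value/mean (the mean
  itself maps to 1). Normalization is on by default for $I$ (its raw value
  is strongly size-dependent) and off for $S$ and $F$ (their confidence
  rules are already intrinsically scaled); all three switches are exposed.
* **Functional coherence** $F(C)$: within each species, the
  intersection-over-union of the GO biological-process term sets of the
  cluster's annotated member proteins, averaged over species.
  Unannotated proteins are excluded from both numerator and denominator,
  and a species contributes only if at least two of its cluster proteins
  are annotated — otherwise the IU ratio would be degenerately 1 and
  coverage gaps would masquerade as coherence. If every species is
  skipped, $F(C) = 0$.

### Degenerate inputs and tie-breaks

* Singleton clusters have no pairs, so $I$ is undefined; they return `NA`
  ("not scorable") and are excluded from reporting by the `min_size = 2`
  filter before scoring matters.
* If every cluster has $I = 0$ the normalization mean is zero; the
  package warns and returns zeros rather than dividing by zero.
* Reported BLAST e-values of exactly 0 are floored at `1e-180` so
  confidence ratios stay finite.
* In `best_pairs` node mode, the member combination minimizing the product
  of cross-species e-values wins; ties break lexicographically on protein
  ids, and a missing record counts as $E = 1$ (worst), so the choice is
  deterministic.
* Weight triples must sum to 1 within `1e-9`; score identities are exact
  to floating-point roundoff and tested at `1e-12`.
* Cross-product node enumeration is capped (default 64 nodes per group,
  with a warning) to bound the blow-up a promiscuous group could cause.

## Empirical significance

For each cluster, `significance_scores()` draws $N$ uniform random *node
subsets* of size $|C|$ from the alignment graph (default $N = 3000$, a
sample size at which the smallest attainable p-value is
$1/(N+1) \approx 3\times10^{-4}$), recomputes $S$, $I$, $F$ on each, and
reports $P = (R+1)/(N+1)$ per component, where $R$ counts null samples at
or above the observed value. The add-one form guarantees validity
($P(p \le x) \le x$ under the null), which the test suite checks
empirically.

Null samples are unconstrained subsets, not random *connected* subgraphs:
the interesting question for a conserved region is precisely whether its
connectivity could arise among arbitrary nodes, so conditioning the null
on connectivity would erase the signal $p_I$ is meant to measure.

Two combined quantities are reported and kept distinct on purpose: the
quality score $\mathrm{Score}(C) \in [0,1]$ (larger = better) and the
p-value combination $\sum_i w_i (R_i+1)/(N_i+1)$ (smaller = more
significant). They point in opposite directions and are not reconciled
into one number; ranking uses the quality score, with the component
p-values available as filters.

## ICCF refinement

Iterative connected-components finding alternates component detection,
scoring, and removal of entire failing clusters (never individual nodes)
until a pass removes nothing. Two rules are built in:

* `go_coherence_nonzero` — remove clusters with $F = 0$. This rule is
  cluster-local, so removing one cluster cannot change another's verdict;
  convergence therefore takes at most two passes (one removing, one
  confirming), which the acceptance suite asserts on generated
  benchmarks.
* `score_threshold` — remove clusters with combined score below 0.5 (the
  conventional cutoff). Here the across-cluster $I$ normalization couples
  clusters, so scores are recomputed — including the normalization — each
  pass, and convergence may legitimately need more than two passes;
  `max_iter` (default 10) bounds the loop and a non-converged result is
  flagged rather than silently truncated.

## Evaluation metrics

* **KO specificity.** Equivalence classes are the alignment nodes; a node
  is correct iff all its members share a KO term. `Ceq` is the fraction of
  correct classes among reported-cluster nodes, `Cnode` the fraction of
  nodes in correct classes. With node-level classes the two coincide; both
  are reported for continuity with the multi-protein-class variants other
  aligners use. When nodes are built from the very KO table used for
  assessment, every node is correct by construction — `Ceq = Cnode = 1` is
  a structural theorem, and the acceptance suite verifies it on a
  500-protein-per-species benchmark.
* **KO sensitivity.** `Cor` counts correct nodes across reported clusters;
  `Tot` counts homolog groups spanning all aligned species after network
  filtering (groups eligible for alignment) — the natural denominator for
  "how much of the alignable signal was recovered".
* **GO process coherence.** A cluster is coherent in a species iff its
  projected protein set shows at least one BP term with BH-adjusted
  hypergeometric $p <$ 0.05 against that species' full network as
  background. Specificity is the coherent fraction per species;
  sensitivity the number of distinct enriched terms. The enrichment test
  is in-package (`stats::phyper` upper tail + `stats::p.adjust` BH): the
  external tool it replaces is specified only by its test family and FDR
  procedure, and a self-contained test keeps evaluation dependency-free.
  No GO-graph term propagation is performed — annotations are taken as
  given — and the draw size $n$ is the full projected cluster set, the
  convention of list-based enrichment tools. Both are deviations to know
  about when comparing against DAG-aware enrichment software.
* **MIPS coverage.** A cluster is covered iff all member proteins (of the
  assessed species) share a complex/FunCat term; coverage is the covered
  fraction. The bundled report auto-detects which species a catalogue
  annotates, since complex catalogues are typically single-species.

## The synthetic benchmark

`generate_benchmark()` emulates exactly the structure the aligner assumes:
1:1 ortholog groups whose within-species subgraphs (cliques or paths) are
mirrored across species, degraded by per-species conserved-edge dropout,
embedded in Erdős–Rényi background noise, with decoy ortholog groups and
annotation noise. Defaults — two species × 500 proteins, eight clique
modules of four groups, background edge probability 0.005, dropout 0.1, 25
decoy groups, 5% annotation noise — describe a small, sparse, somewhat
degraded interactome pair: large enough for nontrivial clusters and stable
evaluation metrics, small enough that the full suite runs in seconds.
Ortholog e-values are drawn log-uniform on $[10^{-50}, 10^{-20}]$ and
decoys on $[10^{-3}, 1]$: disjoint ranges representing the close-homolog
regime on one side and hits a sensible pipeline would never call orthologs
on the other.

What the generator does **not** emulate: realistic degree distributions
(PPI networks are heavy-tailed; the background here is Erdős–Rényi),
many-to-many ortholog groups, correlated assay noise, duplication and
divergence evolution, or incomplete proteome coverage. Passing tests
therefore demonstrate algorithmic correctness — recovery of planted
structure under controlled degradation — not field performance on real
interactomes.

Everything is seeded: the same configuration and seed reproduce every
output byte-for-byte, including the resampling p-values (per-cluster
seeds are derived deterministically from the master seed).

## Problem sizes in the test suite

Tests run on benchmarks of 80–500 proteins per species, 3–8 planted
modules, and resampling depths of 100–2000 null draws; the component
finder is additionally property-tested on 200 random graphs of up to 40
nodes plus a 5000-node path for recursion safety. These sizes were chosen
so the full suite exercises every code path in a couple of minutes while
keeping each stochastic assertion at comfortable margins.

## Known limitations

* At most three species; deeper multiple alignment needs a different edge
  rule than the "all-but-one within distance two" relaxation.
* No ID mapping: protein identifiers must already agree between the PPI
  networks, homolog table, similarity table, and annotations. Identifiers
  are treated as opaque, species-local strings.
* Clusters never overlap (components partition the graph), so shared
  subunits between complexes land in a single merged cluster.
* The linear-time claim is about graph size in the alignment graph; a
  pathologically promiscuous homolog table can still blow up the node set,
  which the cross-product cap only blunts.
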