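---
title: "Extracting confident explanatory subnetworks from putative regulatory networks"
author: "lombarde package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting confident explanatory subnetworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lombarde)
```

## The problem

Sequence-based prediction of transcription-factor/binding-site (TF/BS)
affinities vastly over-predicts regulation: a genome-scale affinity scan
produces an order of magnitude more arcs than the set of regulations an
organism actually uses, and each arc comes only with an affinity p-value.
Independently, expression compendia yield pairs of co-expressed genes or
operons, which are symmetric and carry no causal direction.  This package
implements a combinatorial strategy for reconciling the two: among all
putative arcs, keep exactly those that participate in a *simple and
confident* causal story for some observed co-expression.

The inputs are an **a-priori graph** -- a simple digraph over genes or
operons whose arcs are the union of the affinity predictions
$\mathcal{A}$ (with p-values) and an optional set $\mathcal{V}$ of
experimentally validated regulations -- and a set $\mathcal{C}$ of
unordered co-expressed pairs.  In prokaryotes, gene-level inputs are
first condensed to operon level (`condenseAffinity()`,
`condenseCoexpression()`): a gene's expression implies its operon's
expression, operon pairs wholly inside one operon are trivial and
dropped, and when several TF genes of one operon hit another operon the
minimum p-value is kept.

## Explanations

A co-expressed pair $(A, B)$ is *explained* by a set of arcs that forms

1. a directed path $A \to B$ (a regulatory cascade from $A$ to $B$),
2. a directed path $B \to A$, or
3. two divergent directed paths from a common regulator $C$ to $A$ and to
   $B$ that share only $C$.

Explanations are identified with their arc sets; paths are simple, and
in the divergent case both branches are non-empty with
$C \notin \{A, B\}$ (the degenerate choices $C = A$ and $C = B$ are
exactly the two path cases).  `enumerateExplanations()` materialises this
definition by exhaustive search and serves as the testing oracle; it
refuses graphs above 12 vertices because its cost is exponential.

## Costs: equal-frequency likelihood levels

Small p-value differences carry no biological meaning, so costs are
deliberately *discrete*.  `assignLevels()` sorts the affinity arcs by
p-value and splits them into `k` equal-frequency bins: level 0 holds the
most likely arcs, level `k-1` the least likely, and the cost of a level-
`i` arc is `r^i`.  Validated arcs always sit at level 0 (cost 1).  The
ratio `r` is the exchange rate between quality and parsimony: a cascade
may grow `r` arcs of level `i-1` before it is worth one arc of level
`i`.  Two deliberate conventions close gaps the level rule leaves open:

* when the arc count is not divisible by `k`, the first `n mod k` bins
  take the extra arc (deterministic, as close to equal frequency as
  possible);
* arcs with *identical* p-values are never split across a bin boundary:
  the whole tie is pulled into the lower (more likely) level, since
  equal evidence must mean equal cost.

Defaults are `k = 9` and `r = 10`, the strict end of the ranges usually
swept: raising either parameter shrinks the output and biases it toward
high-confidence arcs, because expensive detours stop being competitive.
Both are exposed everywhere (`costScheme(k, r)`).

Costs must be compared *exactly*: the output is defined by cost ties, and
a tolerance-based comparison would silently change the result.  Because
`r` may be fractional (e.g. 1.5), `costScheme()` stores `r` as a rational
`p/q` (continued-fraction approximation, denominators up to $10^6$) and
every internal cost is the integer `p^i * q^(k-1-i)` -- the level costs
with denominators cleared.  Path costs are then sums of integers held in
doubles, exact below $2^{53}$; `costScheme()` warns if level costs exceed
$2^{48}$, where long paths could break exactness.

## The optimisation and its algorithm

For each pair the package computes the minimum explanation cost and the
union of *all* optimal explanations.  The key observation that makes this
polynomial is that the three-case definition collapses into one formula:

$$\mathrm{OPT}(A,B) \;=\; \min_{C \in V} \; d(C \to A) + d(C \to B),$$

with the convention $d(X, X) = 0$.  With strictly positive arc costs the
divergent-branch disjointness constraint is satisfied automatically at
any optimal root: if two cheapest branches from an optimal $C$ met again
at $D \neq C$, then $D$ itself would satisfy
$d(D \to A) + d(D \to B) < \mathrm{OPT}$, a contradiction.  The test
suite asserts this equivalence against exhaustive enumeration on hundreds
of random digraphs.

Per pair, two single-target shortest-path computations on the graph give
$d(\cdot \to A)$ and $d(\cdot \to B)$ (Dijkstra via igraph, with the
exact integer weights); the optimal roots are the minimisers.  One
forward computation from each optimal root then yields the union of
optimal explanations through the shortest-path-DAG membership test: arc
$(u, v)$ lies on a cheapest $C \to A$ path iff
$d(C \to u) + w(u,v) + d(v \to A) = d(C \to A)$.  `runLombarde()`
memoises the reverse distances across pairs sharing an endpoint and
batches the forward searches over all optimal roots.

The output subnetwork is the union over all explainable pairs of these
per-pair unions.  It is unique, order-independent, and re-explains every
pair at its original optimum (asserted in the tests).  Pairs with no
explanation -- including pairs mentioning vertices absent from the graph
-- reflect missing or inaccurate input and are removed with a logged
count (`filterExplainable()`).

## Why not a global optimum?

Two natural global alternatives are implemented as exhaustive oracles,
deliberately guarded to small instances because both are NP-hard
(reductions from Steiner Weighted Directed Tree and from Minimum Hitting
Set respectively):

* `minCostExplainingSubgraph()` -- the subgraph of minimum total cost
  containing *some* explanation per pair.  On the built-in toy network it
  leaves the pair (G, H) with an explanation of cost 18 although that
  pair's own optimum is 6: global parsimony can starve individual pairs.
* `minCostOptimalSubgraph()` -- the cheapest union of one *optimal*
  explanation per pair.  Every solution is a subset of the full union
  output, so materialising it adds nothing; and the number of optimal
  unions can explode combinatorially (twenty pairs with two optimal
  explanations each already give $2^{20} > 10^6$ subgraphs,
  `countOptimalSubgraphs()`).

Both searches minimise over unions of one enumerated explanation per
pair.  This is exact: any feasible subgraph contains an explanation per
pair, and the union of those explanations is feasible and no costlier,
so the minimum over unions equals the minimum over all arc subsets.  The
raw subset scan is kept in the test suite as an independent check.

## Evaluation statistics

`degreeStats()` reports arcs/vertices and the total-degree distribution;
a credible regulatory network has average degree near 2, while raw
affinity scans sit far higher.  `radiality()` ranks candidate global
regulators: with unweighted directed distances $d$ and diameter $D$ (the
maximum finite distance), each reachable target contributes
$1 + D - d(u, v)$ and `Rad(u)` is the mean contribution over all other
vertices.  Unreachable targets contribute 0 -- the index is meant to
measure the capability to reach, so unreachability is penalised rather
than ignored; this convention (the natural one, since the index is
otherwise undefined on partially reachable digraphs) keeps scores
comparable across vertices.  Distances here are deliberately unweighted
even though explanations are cost-weighted: centrality asks about cascade
*lengths*, not confidence.  `centralRegulators()` takes the top 30% by
radiality, including all ties at the cutoff.  `hypergeomEnrichment()`
gives the exact upper-tail hypergeometric probability (log-space safe)
used to test whether validated arcs are over-represented among the kept
arcs, and `networkReport()` assembles the headline quantities
(percentages at one decimal place).

## The synthetic generator

`generateTrn()` emulates the structural features the method relies on,
not expression data itself: a small TF set (15% of operons) with
heavy-tailed, Zipf-weighted out-degrees; a p-value mixture with a "true
site" component log-uniform on $[10^{-12}, 10^{-7}]$ and a spurious
component near-uniform on $[10^{-7}, 10^{-3}]$ (chosen so that
equal-frequency binning is never degenerate; both are parameters); a
random half of the true arcs exported as the validated set; and a set of
*orphan* operons carrying no affinity arcs, mirroring the fact that real
co-expression compendia involve more operons than an affinity scan
covers.  `plantCoexpressions()` samples explainable pairs (shared
ancestor, established by plain reachability, independent of the cost
machinery) and unexplainable decoys (no shared ancestor, or an orphan
member).  Defaults -- 120 operons, 480 arcs, 25% true arcs, 10 orphans --
give an average degree of 4, between a raw affinity scan (~10) and a
validated network (~2), at a size where a hundred instances run in
seconds.

What passing synthetic tests shows is that the machinery is correct and
biased toward validated arcs *when validated arcs truly lie on
regulatory structure*; it does not show that real affinity pipelines
satisfy the coverage assumption (that the a-priori graph contains most
real interactions), which is a property of the upstream data, not of
this method.

## The built-in toy example

`toyTRN()` returns a nine-gene, twelve-arc network (`k = 3`, `r = 3`,
costs 1/3/9, four arcs per level) with three co-expressed pairs.  It is
constructed so that every interesting behaviour appears at enumerable
scale: (F, I) has six explanations, exactly two of them optimal at cost
10 (one divergent, one a pure cascade); (A, B) and (G, H) have unique
optima; and the globally cheapest explaining subgraph trades (G, H)'s
cost-6 optimum for a cost-18 explanation.  The p-values attached to its
arcs are chosen so that equal-frequency binning with `k = 3` reproduces
the intended levels exactly.

## Problem sizes and runtime choices

The shipped tests enumerate explanations on random digraphs of up to 9
vertices (500 instances for the oracle-equivalence property), run the
full pipeline on synthetic instances of 45-80 operons and 150-480 arcs
(100 instances for the validated-arc bias property), and exercise the
exhaustive global oracles on graphs of at most ~16 arcs.  These sizes
keep the whole suite under a minute while leaving every property
non-trivial.  The polynomial pipeline itself scales far beyond: its cost
is dominated by one Dijkstra per distinct pair endpoint and per optimal
root.

## Known limitations

* Co-expression input is treated as a set of unordered pairs; weights or
  mutual-information scores on pairs are not used.
* The method explains pairs independently; it never trades confidence
  between pairs, by design.
* Costs below $2^{-53}$-relative exactness are not representable: exotic
  `r` values with large rational denominators combined with large `k`
  trigger the exactness warning and should be avoided.
* The radiality report materialises the full distance matrix
  ($O(|V|^2)$ memory), fine for networks of a few thousand operons.
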