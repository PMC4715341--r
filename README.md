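# lombarde

Extraction of confident explanatory subnetworks from putative
transcriptional regulatory networks (TRNs).

## The problem

Scanning a prokaryotic genome for transcription-factor binding sites
produces a putative TRN with far more arcs than the organism actually
uses; each predicted arc carries only an affinity p-value.  Expression
compendia independently provide pairs of co-expressed genes or operons,
which are symmetric and say nothing about direction or mechanism.  This
package extracts from the putative network the subnetwork most likely to
*cause* the observed co-expressions, for people building regulatory
models from sequence predictions plus expression data (and evaluating
them against independently validated regulations).

## The method

The a-priori graph is the simple digraph 𝒢 = (𝔾, 𝒜 ∪ 𝒱) over operons,
where 𝒜 are the TF/BS affinity arcs and 𝒱 optional validated
regulations.  A co-expressed pair (A, B) is **explained** by a directed
path A→B, a directed path B→A, or two divergent directed paths from a
common regulator C to A and B sharing only C.

Arc costs are discrete likelihood levels: the affinity arcs are split by
p-value into *k* equal-frequency bins and an arc in level *i* (0 = most
likely; validated arcs are pinned there) costs *r*ⁱ.  The cost of an
explanation is the sum of its arc costs, and for each pair the package
computes

    OPT(A,B) = min over C of d(C→A) + d(C→B),    d(X,X) = 0,

which covers all three cases at once; with positive costs the divergent
branches are automatically disjoint at any optimal root.  The output is
the union, over all explainable pairs, of **all** minimum-cost
explanations — unique, order-independent, polynomial to compute, and it
re-explains every pair at its original optimum.  The globally
minimum-cost alternatives are NP-hard and are provided only as
exhaustive-search oracles for small instances.

## Worked example

The package ships a nine-gene toy network with three likelihood levels
(k = 3, r = 3, so arc costs are 1, 3 and 9) and three co-expressed
pairs:

```r
library(lombarde)
toy <- toyTRN()
toy$graph
#> AprioriGraph: 9 vertices, 12 arcs (0 validated), k = 3, r = 3
#>   arcs per level: 4/4/4

optimalExplanationCost(toy$graph, "F", "I")
#> [1] 10
optimalRoots(toy$graph, "F", "I")
#> [1] "C" "I"
```

The pair (F, I) has six explanations, two of which attain the optimal
cost 10: the divergent pair of cascades from the common regulator C, and
the cascade I→D→F.  Running the extraction over all three pairs keeps
the union of all optimal explanations:

```r
res <- runLombarde(toy$graph, toy$pairs)
res
#> LombardeResult: 8 arcs over 8 vertices (from 12 a-priori arcs)
#>   pairs: 3 explained, 0 removed; validated arcs kept: 0

arcs(res)[, c("from", "to", "level", "cost", "pairUse")]
#>   from to level cost pairUse
#> 1    B  C     2    9       1
#> 2    C  A     0    1       1
#> 3    C  F     0    1       1
#> 4    C  I     2    9       1
#> 5    D  F     2    9       1
#> 6    D  G     1    3       1
#> 7    D  H     1    3       1
#> 8    I  D     0    1       1
```

Only 8 of the 12 putative arcs survive; `pairUse` counts how many pairs'
optimal explanations use each arc.  The globally cheapest subgraph that
explains all three pairs illustrates why per-pair optimisation is
preferable:

```r
sol <- minCostExplainingSubgraph(toy$graph, toy$pairs)
sol[[1]]@perPairCost
#> A|B F|I G|H
#>  10  13  18
```

The global optimum (total cost 19) explains (G, H) only at cost 18,
three times that pair's own optimum of 6 — global parsimony starves
individual pairs, besides being NP-hard.

A command-line interface wraps the same pipeline
(`inst/scripts/lombarde run --affinities ... --coexpr ... --out ...`,
plus `stats`, `oracle` and `synth` subcommands).

## Learn more

The methods vignette (`vignettes/lombarde-methods.Rmd`) documents the
model and its assumptions, the exact-arithmetic cost representation, the
tie-breaking conventions, the synthetic-data generator and the package's
limitations.
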