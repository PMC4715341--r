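# Exhaustive oracles for the two global (NP-hard) alternatives to the
# per-pair optimisation: the minimum-cost subgraph explaining all pairs
# (reduction from Steiner Weighted Directed Tree) and the minimum-cost
# subgraph containing an optimal explanation for each pair (reduction
# from Minimum Hitting Set).  Both are intended for small instances
# only; they exist to characterise what the per-pair strategy avoids.
#
# Exactness of the search space: any arc-minimal subgraph explaining all
# pairs is a union of one explanation per pair (each pair contributes a
# contained explanation; the union of those explanations is feasible and
# no costlier), so minimising total cost over unions of enumerated
# explanations is equivalent to scanning all arc subsets.

.pairLabel <- function(a, b) paste(a, b, sep = "|")

.minCostUnions <- function(graph, explLists, pairs) {
  scale <- .costScale(graph@scheme)
  w <- graph@arcs$costInt
  nP <- length(explLists)
  best <- Inf
  bestSets <- list()
  idxLists <- lapply(explLists, function(L)
    lapply(L, function(e) e@arcIdx))
  rec <- function(i, acc) {
    if (i > nP) {
      cs <- sum(w[acc])
      if (cs < best) {
        best <<- cs
        bestSets <<- list(acc)
      } else if (cs == best) {
        bestSets[[length(bestSets) + 1L]] <<- acc
      }
      return(invisible())
    }
    for (e in idxLists[[i]]) {
      acc2 <- union(acc, e)
      if (sum(w[acc2]) <= best)           # branch-and-bound on the partial union
        rec(i + 1L, acc2)
    }
    invisible()
  }
  rec(1L, integer(0))
  keys <- vapply(bestSets, function(s) paste(sort(s), collapse = ","),
                 character(1))
  bestSets <- bestSets[!duplicated(keys)]
  lapply(bestSets, function(s) {
    s <- as.integer(sort(s))
    per <- vapply(seq_len(nP), function(i) {
      costs <- vapply(idxLists[[i]], function(e)
        if (all(e %in% s)) sum(w[e]) else Inf, numeric(1))
      min(costs) / scale
    }, numeric(1))
    names(per) <- .pairLabel(pairs$a, pairs$b)
    new("SubgraphSolution", arcIdx = s,
        totalCost = sum(w[s]) / scale, totalCostInt = sum(w[s]),
        perPairCost = per)
  })
}

.altOptimaSetup <- function(graph, pairs, maxArcs, maxVertices) {
  stopifnot(is(graph, "AprioriGraph"))
  pairs <- coexpressionSet(pairs$a, pairs$b)
  if (nrow(graph@arcs) > maxArcs)
    stop(sprintf(
      "graph has %d arcs; exhaustive search refuses > %d (NP-hard problem)",
      nrow(graph@arcs), maxArcs))
  explLists <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ex <- enumerateExplanations(graph, pairs$a[i], pairs$b[i], maxVertices)
    if (!length(ex))
      stop(sprintf(
        "pair (%s, %s) has no explanation; run filterExplainable() first",
        pairs$a[i], pairs$b[i]))
    explLists[[i]] <- ex
  }
  list(pairs = pairs, explLists = explLists)
}

#' Minimum-cost subgraph explaining every pair (exhaustive oracle)
#'
#' Returns all subgraphs of minimum total arc cost that contain at least
#' one explanation for every pair.  NP-hard in general; this exhaustive
#' oracle refuses instances above the guards.  The cheapest explanation
#' it leaves a pair with can be much costlier than that pair's own
#' optimum, which is the main argument against this global objective.
#'
#' @param graph an [AprioriGraph-class] (small).
#' @param pairs co-expression `data.frame` (columns `a`, `b`), all
#'   explainable in `graph`.
#' @param maxArcs refuse graphs with more arcs than this (default 20).
#' @param maxVertices guard passed to [enumerateExplanations()].
#' @return List of [SubgraphSolution-class] objects (all global minima).
#' @export
minCostExplainingSubgraph <- function(graph, pairs, maxArcs = 20L,
                                      maxVertices = 12L) {
  st <- .altOptimaSetup(graph, pairs, maxArcs, maxVertices)
  .minCostUnions(graph, st$explLists, st$pairs)
}

#' Minimum-cost union of per-pair optimal explanations (exhaustive oracle)
#'
#' Among subgraphs formed as the union of one *optimal* explanation per
#' pair, returns those of minimum total cost.  Every solution is a
#' subset of the full union-of-optimal-explanations output, which is why
#' this mixed objective adds nothing over reporting that union.
#'
#' @inheritParams minCostExplainingSubgraph
#' @return List of [SubgraphSolution-class] objects.
#' @export
minCostOptimalSubgraph <- function(graph, pairs, maxArcs = 20L,
                                   maxVertices = 12L) {
  st <- .altOptimaSetup(graph, pairs, maxArcs, maxVertices)
  optLists <- lapply(st$explLists, function(L) {
    costs <- vapply(L, function(e) e@costInt, numeric(1))
    L[costs == min(costs)]
  })
  .minCostUnions(graph, optLists, st$pairs)
}
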