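# Synthetic regulatory networks with planted co-expression structure,
# and the built-in toy example network.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic putative regulatory network
#'
#' Emulates the structure of a TF/binding-site affinity network: a small
#' set of transcription-factor operons with heavy-tailed (Zipf-weighted)
#' out-degrees regulating targets drawn uniformly.  A fraction of the
#' arcs are "true" regulations whose affinity p-values come from a
#' low-p component (log-uniform on \[1e-12, 1e-7\]); the rest are
#' spurious hits with near-uniform p-values on \[1e-7, 1e-3\].  A random
#' subset of the true arcs is emitted as the independently validated
#' set.
#'
#' @param nVertices number of operons (default 120).
#' @param nArcs number of distinct affinity arcs (default 480).
#' @param tfFraction fraction of operons acting as TFs (default 0.15).
#' @param trueArcFraction fraction of arcs drawn from the true-site
#'   p-value component (default 0.25).
#' @param validatedFraction fraction of true arcs reported as validated
#'   (default 0.5).
#' @param nOrphans number of additional operons that take part in
#'   co-expression but acquired no affinity arcs (default 10).  Real
#'   co-expression sets involve more operons than the affinity network
#'   covers; pairs touching such operons can never be explained.
#' @param seed integer seed; the output is reproducible byte for byte.
#' @return List with `affinity` (data.frame `from`, `to`, `p`, `true`),
#'   `validated` (data.frame `from`, `to`), `operons` (all operon
#'   identifiers, including the orphans) and `params`.
#' @export
generateTrn <- function(nVertices = 120, nArcs = 480, tfFraction = 0.15,
                        trueArcFraction = 0.25, validatedFraction = 0.5,
                        nOrphans = 10, seed = 1L) {
  nVertices <- as.integer(nVertices); nArcs <- as.integer(nArcs)
  nTF <- max(2L, as.integer(round(tfFraction * nVertices)))
  if (nArcs > nTF * (nVertices - 1L))
    stop(sprintf(
      "cannot place %d distinct arcs with %d TFs over %d vertices",
      nArcs, nTF, nVertices))
  ids <- sprintf("op%03d", seq_len(nVertices))
  tfs <- ids[seq_len(nTF)]
  .withSeed(seed, {
    zipf <- (1 / seq_len(nTF))            # heavy-tailed out-degree weights
    from <- character(0); to <- character(0)
    seen <- character(0)
    while (length(from) < nArcs) {
      need <- nArcs - length(from)
      f <- sample(tfs, 2L * need + 8L, replace = TRUE, prob = zipf)
      t <- sample(ids, 2L * need + 8L, replace = TRUE)
      ok <- f != t
      key <- paste(f, t, sep = "\r")
      ok <- ok & !duplicated(key) & !(key %in% seen)
      f <- f[ok][seq_len(min(need, sum(ok)))]
      t <- t[ok][seq_len(min(need, sum(ok)))]
      from <- c(from, f); to <- c(to, t)
      seen <- c(seen, paste(f, t, sep = "\r"))
    }
    nTrue <- round(trueArcFraction * nArcs)
    isTrue <- logical(nArcs)
    isTrue[sample.int(nArcs, nTrue)] <- TRUE
    p <- numeric(nArcs)
    p[isTrue] <- 10^stats::runif(nTrue, -12, -7)
    p[!isTrue] <- stats::runif(nArcs - nTrue, 1e-7, 1e-3)
    vIdx <- which(isTrue)[sample.int(nTrue, round(validatedFraction * nTrue))]
    affinity <- data.frame(from = from, to = to, p = p, true = isTrue,
                           stringsAsFactors = FALSE)
    validated <- affinity[sort(vIdx), c("from", "to")]
    rownames(validated) <- NULL
    operons <- c(ids, if (nOrphans > 0)
      sprintf("orph%03d", seq_len(nOrphans)))
    list(affinity = affinity, validated = validated, operons = operons,
         params = list(nVertices = nVertices, nArcs = nArcs,
                       tfFraction = tfFraction,
                       trueArcFraction = trueArcFraction,
                       validatedFraction = validatedFraction,
                       nOrphans = nOrphans, seed = seed))
  })
}

#' Plant explainable co-expression pairs and unexplainable decoys
#'
#' Planted pairs are sampled among vertex pairs that have at least one
#' explanation in the graph (a directed connection or a common
#' regulator); decoys are sampled among pairs with none: either both
#' vertices are in the graph but share no ancestor, or at least one
#' vertex lies outside the graph (an operon with no affinity arcs, as
#' supplied through `universe`).  Explainability is established here by
#' unweighted reachability (a pair is explainable iff the two vertices
#' share an ancestor, where every vertex is its own ancestor),
#' independently of the cost machinery.
#'
#' @param graph an [AprioriGraph-class].
#' @param nPlanted number of explainable pairs to sample.
#' @param nDecoys number of unexplainable pairs to sample.
#' @param seed integer seed.
#' @param universe vertex identifiers eligible for co-expression;
#'   defaults to the graph vertices.  Identifiers outside the graph
#'   (e.g. the `operons` element of [generateTrn()]) enlarge the decoy
#'   pool, mirroring real co-expression sets that involve operons
#'   absent from the affinity network.
#' @return data.frame `a`, `b`, `label` (`"planted"` or `"decoy"`).
#' @export
plantCoexpressions <- function(graph, nPlanted, nDecoys, seed = 1L,
                               universe = NULL) {
  stopifnot(is(graph, "AprioriGraph"))
  gi <- .graphIndex(graph)
  if (is.null(universe)) universe <- gi$verts
  universe <- sort(unique(as.character(universe)), method = "radix")
  if (!all(gi$verts %in% universe))
    stop("universe must contain every graph vertex")
  d <- igraph::distances(gi$ig, v = gi$verts, to = gi$verts,
                         mode = "out", weights = NA)
  reach <- is.finite(d[gi$verts, gi$verts, drop = FALSE]) * 1
  inGraph <- matrix(FALSE, length(universe), length(universe),
                    dimnames = list(universe, universe))
  inGraph[gi$verts, gi$verts] <- crossprod(reach) > 0
  ut <- upper.tri(inGraph)
  expIdx <- which(inGraph & ut, arr.ind = TRUE)
  decIdx <- which(!inGraph & ut, arr.ind = TRUE)
  if (nrow(expIdx) < nPlanted || nrow(decIdx) < nDecoys)
    stop(sprintf(
      "insufficient connectivity: %d explainable and %d decoy pairs available",
      nrow(expIdx), nrow(decIdx)))
  .withSeed(seed, {
    pi <- expIdx[sample.int(nrow(expIdx), nPlanted), , drop = FALSE]
    di <- decIdx[sample.int(nrow(decIdx), nDecoys), , drop = FALSE]
    v <- universe
    out <- rbind(
      data.frame(a = v[pi[, 1L]], b = v[pi[, 2L]],
                 label = rep("planted", nrow(pi)),
                 stringsAsFactors = FALSE),
      data.frame(a = v[di[, 1L]], b = v[di[, 2L]],
                 label = rep("decoy", nrow(di)),
                 stringsAsFactors = FALSE))
    lo <- ifelse(.strlt(out$a, out$b), out$a, out$b)
    hi <- ifelse(.strlt(out$a, out$b), out$b, out$a)
    out$a <- lo; out$b <- hi
    rownames(out) <- NULL
    out
  })
}

#' Built-in toy regulatory network
#'
#' A nine-gene, twelve-arc putative TRN with three likelihood levels
#' (`k = 3`, `r = 3`, arc costs 1, 3 and 9) and three co-expressed
#' pairs: (F, I), (A, B) and (G, H).  Small enough to enumerate every
#' explanation by hand, yet rich enough to exhibit the interesting
#' behaviours: (F, I) has six explanations of which exactly two are
#' optimal (cost 10), (G, H) has a unique cheap optimum (cost 6), and
#' the globally minimum-cost subgraph explaining all three pairs leaves
#' (G, H) with a far costlier explanation (cost 18) than its own
#' optimum -- the key argument for per-pair optimisation.
#'
#' @return List with `graph` (an [AprioriGraph-class]), `pairs`
#'   (canonical co-expression data.frame) and `affinity` (the raw
#'   affinity arc table with p-values).
#' @examples
#' toy <- toyTRN()
#' optimalExplanationCost(toy$graph, "F", "I")   # 10
#' @export
toyTRN <- function() {
  affinity <- data.frame(
    from = c("C", "C", "A", "I", "C", "D", "D", "B", "C", "D", "D", "B"),
    to   = c("A", "F", "G", "D", "E", "G", "H", "I", "I", "B", "F", "C"),
    p    = c(1e-9, 2e-9, 5e-9, 8e-9,           # level 0, cost 1
             1e-6, 2e-6, 4e-6, 8e-6,           # level 1, cost 3
             1e-4, 3e-4, 5e-4, 9e-4),          # level 2, cost 9
    stringsAsFactors = FALSE)
  graph <- buildAprioriGraph(affinity, scheme = costScheme(k = 3, r = 3))
  pairs <- coexpressionSet(c("F", "A", "G"), c("I", "B", "H"))
  list(graph = graph, pairs = pairs, affinity = affinity)
}
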