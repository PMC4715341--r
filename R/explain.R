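# Optimal explanations of co-expressed pairs and the output subgraph.
#
# An explanation of a pair (A, B) is a directed path A->B, a directed
# path B->A, or two divergent directed paths from a common regulator C
# to A and to B sharing only C.  With strictly positive arc costs the
# minimum over the relaxed objective d(C->A) + d(C->B) (convention
# d(X, X) = 0) equals the minimum explanation cost: at an optimal C any
# pair of cheapest C->A / C->B paths can only share C, otherwise the
# shared vertex would beat C.  The three cases of the definition are the
# C = A, C = B and C not in {A, B} specialisations of the same formula.

# --- internal indexed view of an AprioriGraph ------------------------------

.graphIndex <- function(graph) {
  a <- graph@arcs
  verts <- graph@vertices
  ig <- igraph::graph_from_data_frame(
    d = a[, c("from", "to"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  list(ig = ig, verts = verts, n = length(verts),
       from = match(a$from, verts), to = match(a$to, verts),
       w = a$costInt, nArcs = nrow(a))
}

# scaled-integer distances from every vertex to each of `targets`
.distTo <- function(gi, targets) {
  m <- igraph::distances(gi$ig, v = gi$verts, to = targets,
                         mode = "out", weights = gi$w)
  m[gi$verts, , drop = FALSE]
}

# scaled-integer distances from each of `sources` to every vertex
.distFrom <- function(gi, sources) {
  m <- igraph::distances(gi$ig, v = sources, to = gi$verts,
                         mode = "out", weights = gi$w)
  m[, gi$verts, drop = FALSE]
}

.checkVertex <- function(graph, v) {
  if (!all(v %in% graph@vertices))
    stop("unknown vertex: ", paste(setdiff(v, graph@vertices), collapse = ", "))
}

# --- exported operations ---------------------------------------------------

#' Cheapest directed path costs towards a target
#'
#' Exact nonnegative-weight shortest-path distances from every vertex to
#' `target`, in cost units.  `distancesTo(g, t)[t] == 0`; unreachable
#' vertices map to `Inf`.
#'
#' @param graph an [AprioriGraph-class].
#' @param target a vertex identifier.
#' @return Named numeric vector over all vertices.
#' @export
distancesTo <- function(graph, target) {
  stopifnot(is(graph, "AprioriGraph"), length(target) == 1L)
  .checkVertex(graph, target)
  gi <- .graphIndex(graph)
  d <- .distTo(gi, target)[, 1L]
  stats::setNames(d / .costScale(graph@scheme), gi$verts)
}

#' Minimum explanation cost of a co-expressed pair
#'
#' Minimum cost over all explanations of the pair: directed paths in
#' either direction and divergent cascade pairs from any common
#' regulator.  Computed as `min over C of d(C->A) + d(C->B)` with exact
#' arithmetic.
#'
#' @param graph an [AprioriGraph-class].
#' @param a,b the two vertex identifiers (must differ).
#' @return The optimum cost in cost units, or `Inf` when the pair has no
#'   explanation.
#' @export
optimalExplanationCost <- function(graph, a, b) {
  .pairOpt(graph, a, b)$optCost
}

#' Optimal common-regulator roots of a pair
#'
#' All vertices C attaining the minimum of `d(C->A) + d(C->B)`.  The
#' result includes A itself when a cheapest directed path A->B attains
#' the optimum (and symmetrically B).
#'
#' @inheritParams optimalExplanationCost
#' @return Character vector of roots; empty when the pair is
#'   unexplainable.
#' @export
optimalRoots <- function(graph, a, b) {
  .pairOpt(graph, a, b)$roots
}

#' Arcs lying on at least one optimal explanation
#'
#' For each optimal root C, an arc (u, v) is part of a cheapest C->A
#' path iff `d(C->u) + cost(u, v) + d(v->A) == d(C->A)` (and
#' symmetrically for B).  The union over optimal roots and both sides is
#' exactly the arc set of the union of all optimal explanations of the
#' pair.
#'
#' @inheritParams optimalExplanationCost
#' @return Sorted integer vector of arc indices into `arcs(graph)`;
#'   empty when the pair is unexplainable.
#' @export
optimalExplanationArcs <- function(graph, a, b) {
  .pairOpt(graph, a, b)$arcIdx
}

.pairOpt <- function(graph, a, b) {
  stopifnot(is(graph, "AprioriGraph"),
            length(a) == 1L, length(b) == 1L)
  if (a == b) stop("the two members of a co-expressed pair must differ")
  .checkVertex(graph, c(a, b))
  gi <- .graphIndex(graph)
  d <- .distTo(gi, c(a, b))
  res <- .pairOptCore(gi, d[, 1L], d[, 2L])
  res$optCost <- res$optCostInt / .costScale(graph@scheme)
  res
}

# core per-pair computation given reverse distance vectors (scaled ints)
.pairOptCore <- function(gi, dA, dB, fwRows = NULL) {
  tot <- dA + dB
  optInt <- suppressWarnings(min(tot))
  if (!is.finite(optInt))
    return(list(optCostInt = Inf, roots = character(0), arcIdx = integer(0)))
  rootIdx <- which(tot == optInt)
  roots <- gi$verts[rootIdx]
  fw <- if (is.null(fwRows)) .distFrom(gi, roots) else fwRows[roots, , drop = FALSE]
  keep <- logical(gi$nArcs)
  for (i in seq_along(rootIdx)) {
    fu <- fw[i, gi$from]
    onA <- fu + gi$w + dA[gi$to] == dA[rootIdx[i]]
    onB <- fu + gi$w + dB[gi$to] == dB[rootIdx[i]]
    keep <- keep | (onA & !is.na(onA)) | (onB & !is.na(onB))
  }
  list(optCostInt = optInt, roots = roots,
       arcIdx = as.integer(which(unname(keep))))
}

#' Partition co-expressed pairs by explainability
#'
#' Pairs whose vertices are absent from the graph, and pairs with no
#' explanation (no directed connection and no common regulator), cannot
#' be explained by the a-priori network; they reflect missing or
#' inaccurate input data and are removed before subnetwork extraction.
#'
#' @param graph an [AprioriGraph-class].
#' @param pairs co-expression `data.frame` (columns `a`, `b`).
#' @return List with `explainable` (data.frame `a`, `b`, `optCost`) and
#'   `removed` (data.frame `a`, `b`, `reason`).
#' @export
filterExplainable <- function(graph, pairs) {
  stopifnot(is(graph, "AprioriGraph"))
  pairs <- coexpressionSet(pairs$a, pairs$b)
  known <- pairs$a %in% graph@vertices & pairs$b %in% graph@vertices
  removed <- data.frame(a = character(0), b = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  if (any(!known)) {
    removed <- data.frame(a = pairs$a[!known], b = pairs$b[!known],
                          reason = "unknown_vertex", stringsAsFactors = FALSE)
    message(sprintf("removed %d pair(s) with vertices absent from the graph",
                    sum(!known)))
  }
  kp <- pairs[known, , drop = FALSE]
  if (nrow(kp)) {
    gi <- .graphIndex(graph)
    ends <- unique(c(kp$a, kp$b))
    d <- .distTo(gi, ends)
    opt <- mapply(function(x, y) {
      suppressWarnings(min(d[, x] + d[, y]))
    }, kp$a, kp$b, USE.NAMES = FALSE)
    expl <- is.finite(opt)
    if (any(!expl)) {
      removed <- rbind(removed,
        data.frame(a = kp$a[!expl], b = kp$b[!expl],
                   reason = "unexplainable", stringsAsFactors = FALSE))
      message(sprintf("removed %d unexplainable pair(s)", sum(!expl)))
    }
    explainable <- data.frame(a = kp$a[expl], b = kp$b[expl],
                              optCost = opt[expl] / .costScale(graph@scheme),
                              stringsAsFactors = FALSE)
  } else {
    explainable <- data.frame(a = character(0), b = character(0),
                              optCost = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(explainable) <- rownames(removed) <- NULL
  list(explainable = explainable, removed = removed)
}

#' Extract the explanatory subnetwork for a set of co-expressed pairs
#'
#' For every explainable pair the union of all its minimum-cost
#' explanations is computed; the output subnetwork is the union of these
#' arc sets over all pairs.  The result is unique and independent of the
#' order in which pairs are processed.
#'
#' @param graph an [AprioriGraph-class].
#' @param pairs co-expression `data.frame` (columns `a`, `b`).
#' @return A [LombardeResult-class].
#' @examples
#' toy <- toyTRN()
#' res <- runLombarde(toy$graph, toy$pairs)
#' summary(res)
#' @export
runLombarde <- function(graph, pairs) {
  stopifnot(is(graph, "AprioriGraph"))
  part <- filterExplainable(graph, pairs)
  kp <- part$explainable
  gi <- .graphIndex(graph)
  scale <- .costScale(graph@scheme)
  pairUse <- integer(gi$nArcs)
  keepAll <- logical(gi$nArcs)
  results <- vector("list", nrow(kp))
  if (nrow(kp)) {
    ends <- unique(c(kp$a, kp$b))
    dRev <- .distTo(gi, ends)
    # first pass: optimal roots of every pair, to batch forward searches
    rootSets <- vector("list", nrow(kp))
    for (i in seq_len(nrow(kp))) {
      tot <- dRev[, kp$a[i]] + dRev[, kp$b[i]]
      rootSets[[i]] <- gi$verts[which(tot == min(tot))]
    }
    fwAll <- .distFrom(gi, sort(unique(unlist(rootSets))))
    for (i in seq_len(nrow(kp))) {
      res <- .pairOptCore(gi, dRev[, kp$a[i]], dRev[, kp$b[i]], fwRows = fwAll)
      results[[i]] <- new("PairResult",
        pair = c(kp$a[i], kp$b[i]),
        optCost = res$optCostInt / scale, optCostInt = res$optCostInt,
        roots = res$roots, arcIdx = res$arcIdx, explainable = TRUE)
      keepAll[res$arcIdx] <- TRUE
      pairUse[res$arcIdx] <- pairUse[res$arcIdx] + 1L
    }
  }
  keepIdx <- which(keepAll)
  sub <- graph@arcs[keepIdx, , drop = FALSE]
  sub$pairUse <- pairUse[keepIdx]
  rownames(sub) <- NULL
  touched <- sort(unique(c(sub$from, sub$to)), method = "radix")
  outGraph <- new("AprioriGraph", vertices = touched, arcs = sub,
                  scheme = graph@scheme)
  validObject(outGraph)
  summary <- list(
    nArcsApriori = gi$nArcs,
    nArcsKept = nrow(sub),
    nValidatedKept = sum(sub$validated),
    nValidatedApriori = sum(graph@arcs$validated),
    nPairsInput = nrow(kp) + nrow(part$removed),
    nPairsExplained = nrow(kp),
    nPairsRemoved = nrow(part$removed),
    nVerticesTouched = length(touched))
  new("LombardeResult", graph = outGraph, perPair = results,
      removed = part$removed, summary = summary)
}

#' Extract a subgraph by arc indices
#'
#' @param graph an [AprioriGraph-class].
#' @param arcIdx integer indices into `arcs(graph)`.
#' @return An [AprioriGraph-class] restricted to those arcs and their
#'   endpoints (plus any vertices in `keepVertices`).
#' @param keepVertices additional vertex identifiers to retain.
#' @export
arcSubgraph <- function(graph, arcIdx, keepVertices = character(0)) {
  stopifnot(is(graph, "AprioriGraph"))
  sub <- graph@arcs[arcIdx, , drop = FALSE]
  rownames(sub) <- NULL
  verts <- sort(unique(c(sub$from, sub$to, keepVertices)), method = "radix")
  g <- new("AprioriGraph", vertices = verts, arcs = sub,
           scheme = graph@scheme)
  validObject(g)
  g
}

# --- exhaustive enumeration oracle ----------------------------------------

# all simple paths s -> t as integer vectors of arc indices
.simplePaths <- function(adjArc, adjTo, s, t, n) {
  out <- list()
  onPath <- logical(n)
  arcsAcc <- integer(0)
  rec <- function(u) {
    if (u == t) {
      out[[length(out) + 1L]] <<- arcsAcc
      return(invisible())
    }
    onPath[u] <<- TRUE
    nb <- adjTo[[u]]
    for (j in seq_along(nb)) {
      v <- nb[j]
      if (!onPath[v] && v != s) {
        arcsAcc <<- c(arcsAcc, adjArc[[u]][j])
        if (v == t) out[[length(out) + 1L]] <<- arcsAcc
        else rec(v)
        arcsAcc <<- arcsAcc[-length(arcsAcc)]
      }
    }
    onPath[u] <<- FALSE
    invisible()
  }
  if (s == t) return(out)
  rec(s)
  out
}

#' Enumerate every explanation of a pair (testing oracle)
#'
#' Exhaustively lists all explanations of (A, B): every simple directed
#' path A->B, every simple directed path B->A, and for every other
#' vertex C every pair of non-empty simple paths C->A and C->B sharing
#' only C.  Explanations are identified with their arc sets and
#' deduplicated.  Exponential in graph size: refuses graphs above
#' `maxVertices`.
#'
#' @inheritParams optimalExplanationCost
#' @param maxVertices guard on the vertex count (default 12).
#' @return List of [Explanation-class] objects.
#' @export
enumerateExplanations <- function(graph, a, b, maxVertices = 12L) {
  stopifnot(is(graph, "AprioriGraph"))
  if (length(graph@vertices) > maxVertices)
    stop(sprintf(
      "graph has %d vertices; enumeration is exponential and refuses > %d",
      length(graph@vertices), maxVertices))
  if (a == b) stop("the two members of a co-expressed pair must differ")
  .checkVertex(graph, c(a, b))
  gi <- .graphIndex(graph)
  n <- gi$n
  adjTo <- vector("list", n); adjArc <- vector("list", n)
  for (e in seq_len(gi$nArcs)) {
    u <- gi$from[e]
    adjTo[[u]] <- c(adjTo[[u]], gi$to[e])
    adjArc[[u]] <- c(adjArc[[u]], e)
  }
  ia <- match(a, gi$verts); ib <- match(b, gi$verts)
  scale <- .costScale(graph@scheme)
  seen <- new.env(parent = emptyenv())
  out <- list()
  add <- function(kind, root, arcIdx) {
    key <- paste(sort(arcIdx), collapse = ",")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    ci <- sum(gi$w[arcIdx])
    out[[length(out) + 1L]] <<- new("Explanation", kind = kind, root = root,
      arcIdx = as.integer(sort(arcIdx)), cost = ci / scale, costInt = ci)
    invisible()
  }
  for (p in .simplePaths(adjArc, adjTo, ia, ib, n))
    add("path_forward", a, p)
  for (p in .simplePaths(adjArc, adjTo, ib, ia, n))
    add("path_backward", b, p)
  pathVerts <- function(p, s) unique(c(s, gi$to[p]))
  for (ic in seq_len(n)) {
    if (ic == ia || ic == ib) next
    pA <- .simplePaths(adjArc, adjTo, ic, ia, n)
    if (!length(pA)) next
    pB <- .simplePaths(adjArc, adjTo, ic, ib, n)
    if (!length(pB)) next
    for (x in pA) {
      vx <- pathVerts(x, ic)
      for (y in pB) {
        vy <- pathVerts(y, ic)
        if (length(intersect(vx, vy)) == 1L)   # only C shared
          add("divergent", gi$verts[ic], c(x, y))
      }
    }
  }
  out
}

#' Count the optimal subgraphs explaining a pair set
#'
#' An optimal subgraph is a union of one minimum-cost explanation per
#' pair.  When the unions of optimal explanations of the pairs are
#' pairwise vertex-disjoint, every choice yields a distinct subgraph, so
#' the count is the product over pairs of the number of optimal
#' explanations (counted exactly by exhaustive enumeration within each
#' pair's optimal-arc union).
#'
#' @param graph an [AprioriGraph-class].
#' @param pairs co-expression `data.frame` (columns `a`, `b`), all
#'   explainable.
#' @param maxVertices per-pair enumeration guard (default 12).
#' @return Named list: `perPair` (optimal explanation count per pair) and
#'   `nOptimalSubgraphs` (their product).
#' @export
countOptimalSubgraphs <- function(graph, pairs, maxVertices = 12L) {
  stopifnot(is(graph, "AprioriGraph"))
  counts <- numeric(nrow(pairs))
  vsets <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    po <- .pairOpt(graph, pairs$a[i], pairs$b[i])
    if (!is.finite(po$optCost)) stop("pair without explanation: ",
                                     pairs$a[i], ", ", pairs$b[i])
    sub <- arcSubgraph(graph, po$arcIdx)
    vsets[[i]] <- sub@vertices
    ex <- enumerateExplanations(sub, pairs$a[i], pairs$b[i], maxVertices)
    costs <- vapply(ex, function(e) e@costInt, numeric(1))
    counts[i] <- sum(costs == min(costs))
  }
  for (i in seq_len(nrow(pairs)))
    for (j in seq_len(i - 1L))
      if (length(intersect(vsets[[i]], vsets[[j]])))
        stop("optimal-explanation unions of pairs ", i, " and ", j,
             " share vertices; the product formula does not apply")
  list(perPair = counts, nOptimalSubgraphs = prod(counts))
}
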