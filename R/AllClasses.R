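#' @include AllGenerics.R
NULL

# Central S4 containers.  Arc tables are plain data.frames; all cost
# comparisons are made on exact scaled-integer costs (column `costInt`),
# never on floating-point level costs.

.arcCols <- c("from", "to", "p", "validated", "level", "cost", "costInt")

#' Discrete likelihood-level cost scheme
#'
#' Arcs of the a-priori network are assigned to `k` likelihood levels by
#' equal-frequency binning of their affinity p-values; an arc in level
#' `i` (0 = most likely) costs `r^i`.  To keep cost ties exact even for
#' fractional `r`, the ratio is stored as a rational number `rNum/rDen`
#' and all internal path costs are the integers
#' `rNum^i * rDen^(k-1-i)` (the level costs with denominators cleared).
#'
#' @slot k number of likelihood levels (>= 1).
#' @slot r incremental cost between consecutive levels (> 0).
#' @slot rNum,rDen numerator and denominator of the rational approximation
#'   of `r` used for exact arithmetic.
#' @slot boundaries upper p-value edge of levels `0 .. k-2` as assigned by
#'   [assignLevels()]; `NA` until levels have been assigned.
#'
#' @seealso [costScheme()], [assignLevels()], [arcCost()]
#' @export
setClass("CostScheme",
  representation(k = "integer", r = "numeric",
                 rNum = "numeric", rDen = "numeric",
                 boundaries = "numeric"),
  prototype(k = 9L, r = 10, rNum = 10, rDen = 1, boundaries = numeric(0)))

setValidity("CostScheme", function(object) {
  msg <- NULL
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (length(object@r) != 1L || is.na(object@r) || object@r <= 0)
    msg <- c(msg, "r must be a single positive number")
  if (object@rNum < 1 || object@rDen < 1)
    msg <- c(msg, "rational representation of r must be positive")
  if (length(object@boundaries) &&
      is.unsorted(object@boundaries, na.rm = TRUE))
    msg <- c(msg, "level boundaries must be non-decreasing")
  if (is.null(msg)) TRUE else msg
})

#' A-priori regulatory network
#'
#' Simple directed graph over genes or operons whose arcs are the union of
#' the affinity arc set (TF/binding-site predictions with p-values) and the
#' optional set of experimentally validated regulations.  At most one arc
#' per ordered vertex pair; every arc carries a likelihood level and the
#' corresponding discrete cost.
#'
#' @slot vertices character vector of vertex identifiers.
#' @slot arcs data.frame with columns `from`, `to`, `p`, `validated`,
#'   `level`, `cost`, `costInt` (exact scaled-integer cost).
#' @slot scheme the [CostScheme-class] used to assign levels.
#'
#' @seealso [buildAprioriGraph()], [runLombarde()]
#' @export
setClass("AprioriGraph",
  representation(vertices = "character", arcs = "data.frame",
                 scheme = "CostScheme"))

setValidity("AprioriGraph", function(object) {
  msg <- NULL
  a <- object@arcs
  if (!all(.arcCols %in% names(a)))
    msg <- c(msg, paste("arc table must have columns",
                        paste(.arcCols, collapse = ", ")))
  else {
    if (anyDuplicated(paste(a$from, a$to, sep = "\r")))
      msg <- c(msg, "parallel arcs: at most one arc per ordered pair")
    if (!all(c(a$from, a$to) %in% object@vertices))
      msg <- c(msg, "arc endpoints must be listed in the vertex set")
    if (nrow(a)) {
      k <- object@scheme@k
      if (any(a$level < 0L | a$level > k - 1L))
        msg <- c(msg, "arc levels must lie in 0 .. k-1")
      if (any(a$validated & a$level != 0L))
        msg <- c(msg, "validated arcs must sit at level 0")
      bad <- !is.na(a$p) & (a$p <= 0 | a$p > 1)
      if (any(bad))
        msg <- c(msg, "p-values must lie in (0, 1]")
      if (any(is.na(a$p) & !a$validated))
        msg <- c(msg, "arcs without a p-value must be validated")
    }
  }
  if (anyDuplicated(object@vertices))
    msg <- c(msg, "duplicated vertex identifiers")
  if (is.null(msg)) TRUE else msg
})

#' One explanation of a co-expressed pair
#'
#' An explanation for a pair (A, B) is a set of arcs forming a directed
#' path A -> B (`kind = "path_forward"`), a directed path B -> A
#' (`"path_backward"`), or two divergent directed paths from a common
#' regulator C to A and to B that share only C (`"divergent"`).
#'
#' @slot kind one of `"path_forward"`, `"path_backward"`, `"divergent"`.
#' @slot root the common regulator C (equals the start vertex for paths).
#' @slot arcIdx integer indices of the member arcs into `arcs(graph)`.
#' @slot cost explanation cost, the sum of member arc costs.
#' @slot costInt the same cost in exact scaled-integer units.
#'
#' @seealso [enumerateExplanations()]
#' @export
setClass("Explanation",
  representation(kind = "character", root = "character",
                 arcIdx = "integer", cost = "numeric", costInt = "numeric"))

setValidity("Explanation", function(object) {
  if (!object@kind %in% c("path_forward", "path_backward", "divergent"))
    return("unknown explanation kind")
  TRUE
})

#' Optimal-explanation summary for one co-expressed pair
#'
#' @slot pair the two vertex identifiers (canonical order).
#' @slot optCost minimum explanation cost (`Inf` if unexplainable).
#' @slot optCostInt the same in exact scaled-integer units.
#' @slot roots vertices C attaining the optimum of d(C->A) + d(C->B)
#'   (may include the pair members themselves for path explanations).
#' @slot arcIdx indices (into the a-priori arc table) of all arcs lying on
#'   at least one optimal explanation.
#' @slot explainable whether any explanation exists.
#'
#' @seealso [runLombarde()], [optimalExplanationArcs()]
#' @export
setClass("PairResult",
  representation(pair = "character", optCost = "numeric",
                 optCostInt = "numeric", roots = "character",
                 arcIdx = "integer", explainable = "logical"))

#' Output subnetwork of a network extraction
#'
#' The extracted subnetwork is the union, over all explainable
#' co-expressed pairs, of all arcs belonging to at least one minimum-cost
#' explanation of the pair.  The arc table gains a `pairUse` column: the
#' number of input pairs whose optimal explanations use the arc.
#'
#' @slot graph the output subnetwork as an [AprioriGraph-class].
#' @slot perPair list of [PairResult-class], one per input pair.
#' @slot removed data.frame of discarded pairs (unexplainable or with
#'   unknown vertices) with a `reason` column.
#' @slot summary named list of summary counts.
#'
#' @seealso [runLombarde()]
#' @export
setClass("LombardeResult",
  representation(graph = "AprioriGraph", perPair = "list",
                 removed = "data.frame", summary = "list"))

#' Radiality centrality report
#'
#' Radiality of a vertex u averages R(u, v) = 1 + D - d(u, v) over all
#' other vertices v, where d is the unweighted directed distance and D the
#' diameter (maximum finite distance); unreachable v contribute 0.
#'
#' @slot distances unweighted directed distance matrix.
#' @slot diameter maximum finite directed distance (0 for arcless graphs).
#' @slot radiality named vector Rad(u).
#'
#' @seealso [radiality()], [centralRegulators()]
#' @export
setClass("RadialityReport",
  representation(distances = "matrix", diameter = "numeric",
                 radiality = "numeric"))

#' Subgraph solution of a global optimisation oracle
#'
#' @slot arcIdx indices of the member arcs into the a-priori arc table.
#' @slot totalCost sum of member arc costs.
#' @slot totalCostInt the same in exact scaled-integer units.
#' @slot perPairCost cheapest explanation cost of each input pair within
#'   the subgraph, named by canonical pair labels.
#'
#' @seealso [minCostExplainingSubgraph()], [minCostOptimalSubgraph()]
#' @export
setClass("SubgraphSolution",
  representation(arcIdx = "integer", totalCost = "numeric",
                 totalCostInt = "numeric", perPairCost = "numeric"))

setMethod("show", "CostScheme", function(object) {
  cat(sprintf("CostScheme: k = %d levels, r = %s (exact %s/%s)\n",
              object@k, format(object@r),
              format(object@rNum), format(object@rDen)))
  cat("  level costs:",
      paste(format(levelCosts(object)), collapse = ", "), "\n")
  if (length(object@boundaries))
    cat("  p-value level boundaries:",
        paste(signif(object@boundaries, 3), collapse = ", "), "\n")
})

setMethod("show", "AprioriGraph", function(object) {
  a <- object@arcs
  cat(sprintf(
    "AprioriGraph: %d vertices, %d arcs (%d validated), k = %d, r = %s\n",
    length(object@vertices), nrow(a), sum(a$validated),
    object@scheme@k, format(object@scheme@r)))
  if (nrow(a)) {
    lv <- table(factor(a$level, levels = 0:(object@scheme@k - 1L)))
    cat("  arcs per level:", paste(as.integer(lv), collapse = "/"), "\n")
  }
})

setMethod("show", "PairResult", function(object) {
  cat(sprintf("PairResult (%s, %s): ", object@pair[1L], object@pair[2L]))
  if (object@explainable)
    cat(sprintf("OPT = %s, %d optimal root(s), %d arc(s) in union\n",
                format(object@optCost), length(object@roots),
                length(object@arcIdx)))
  else cat("unexplainable\n")
})

setMethod("show", "LombardeResult", function(object) {
  s <- object@summary
  cat(sprintf(
    "LombardeResult: %d arcs over %d vertices (from %d a-priori arcs)\n",
    s$nArcsKept, s$nVerticesTouched, s$nArcsApriori))
  cat(sprintf("  pairs: %d explained, %d removed; validated arcs kept: %d\n",
              s$nPairsExplained, s$nPairsRemoved, s$nValidatedKept))
})

setMethod("show", "RadialityReport", function(object) {
  cat(sprintf("RadialityReport: %d vertices, diameter %d\n",
              length(object@radiality), as.integer(object@diameter)))
  top <- head(sort(object@radiality, decreasing = TRUE), 5L)
  cat("  top radiality:",
      paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n")
})

setMethod("show", "SubgraphSolution", function(object) {
  cat(sprintf("SubgraphSolution: %d arcs, total cost %s\n",
              length(object@arcIdx), format(object@totalCost)))
})

#' @rdname arcs
#' @export
setMethod("arcs", "AprioriGraph", function(x) x@arcs)

#' @rdname arcs
#' @export
setMethod("arcs", "LombardeResult", function(x) x@graph@arcs)

#' @rdname vertices
#' @export
setMethod("vertices", "AprioriGraph", function(x) x@vertices)

#' @rdname vertices
#' @export
setMethod("vertices", "LombardeResult", function(x) x@graph@vertices)

#' @rdname scheme
#' @export
setMethod("scheme", "AprioriGraph", function(x) x@scheme)

#' @rdname scheme
#' @export
setMethod("scheme", "LombardeResult", function(x) x@graph@scheme)

#' @rdname perPair
#' @export
setMethod("perPair", "LombardeResult", function(x) x@perPair)

#' Summary counts of a network extraction
#'
#' @param object a [LombardeResult-class].
#' @param ... ignored.
#' @return Named list of counts: a-priori arcs, arcs kept, validated arcs
#'   kept, pairs explained/removed, vertices touched.
#' @export
setMethod("summary", "LombardeResult", function(object, ...) object@summary)
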