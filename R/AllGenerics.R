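#' Arc table of a network object
#'
#' Returns the arc (directed edge) table of an [AprioriGraph-class] or of a
#' [LombardeResult-class].  One row per directed arc, with columns `from`,
#' `to`, `p` (affinity p-value, `NA` for validated-only arcs), `validated`,
#' `level` (likelihood level, 0 = most likely) and `cost` (the level cost
#' r^level).
#'
#' @param x an `AprioriGraph` or `LombardeResult` object.
#' @return A `data.frame` with one row per arc.
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))

#' Vertex identifiers of a network object
#'
#' @param x an `AprioriGraph` or `LombardeResult` object.
#' @return Character vector of vertex (gene/operon) identifiers.
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' Cost scheme attached to a network object
#'
#' @param x an `AprioriGraph` or `LombardeResult` object.
#' @return The [CostScheme-class] used to assign arc levels and costs.
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' Per-pair results of a network extraction
#'
#' @param x a `LombardeResult` object.
#' @return A list of [PairResult-class] objects, one per input
#'   co-expressed pair (in canonical pair order).
#' @export
setGeneric("perPair", function(x) standardGeneric("perPair"))
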