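# Evaluation statistics: degree distribution, radiality centrality and
# central-regulator ranking, hypergeometric enrichment of validated
# arcs, summary reports.

#' Average degree and degree distribution
#'
#' Average degree is arcs/vertices (each directed arc contributes one
#' interaction).  The histogram reports the proportion of vertices at
#' each total degree (in-degree + out-degree).
#'
#' @param x an [AprioriGraph-class] or [LombardeResult-class].
#' @return List with `averageDegree` and `distribution` (named numeric
#'   vector of proportions by total degree).
#' @export
degreeStats <- function(x) {
  a <- arcs(x); v <- vertices(x)
  if (!length(v)) stop("degree statistics of an empty graph are undefined")
  deg <- table(factor(c(a$from, a$to), levels = v))
  tab <- table(as.integer(deg))
  list(averageDegree = nrow(a) / length(v),
       distribution = stats::setNames(as.numeric(tab) / length(v),
                                      names(tab)))
}

#' Radiality centrality of every vertex
#'
#' With d(u, v) the unweighted directed distance and D the diameter
#' (maximum finite distance), each ordered pair contributes
#' R(u, v) = 1 + D - d(u, v); Rad(u) is the mean contribution over all
#' v != u, with unreachable v contributing 0.  High radiality marks
#' vertices able to reach many others in few regulatory steps, the
#' signature of global regulators.
#'
#' @param x an [AprioriGraph-class] or [LombardeResult-class].
#' @return A [RadialityReport-class].
#' @export
radiality <- function(x) {
  g <- if (is(x, "LombardeResult")) x@graph else x
  stopifnot(is(g, "AprioriGraph"))
  v <- g@vertices
  if (!length(v)) stop("radiality of an empty graph is undefined")
  gi <- .graphIndex(g)
  d <- igraph::distances(gi$ig, v = v, to = v, mode = "out", weights = NA)
  d <- d[v, v, drop = FALSE]
  finite <- is.finite(d) & d > 0
  D <- if (any(finite)) max(d[finite]) else 0
  contrib <- ifelse(finite, 1 + D - d, 0)
  diag(contrib) <- 0
  rad <- if (length(v) > 1L) rowSums(contrib) / (length(v) - 1L)
         else stats::setNames(0, v)
  new("RadialityReport", distances = d, diameter = as.numeric(D),
      radiality = stats::setNames(as.numeric(rad), v))
}

#' Central regulators by radiality rank
#'
#' Vertices whose radiality rank (descending) falls within the top
#' `fraction` of vertices; all ties at the cutoff value are included.
#'
#' @param report a [RadialityReport-class].
#' @param fraction top fraction to keep (default 0.30).
#' @return Character vector of central vertex identifiers.
#' @export
centralRegulators <- function(report, fraction = 0.30) {
  stopifnot(is(report, "RadialityReport"), fraction > 0, fraction <= 1)
  rad <- report@radiality
  nTop <- ceiling(fraction * length(rad))
  cutoff <- sort(rad, decreasing = TRUE)[nTop]
  names(rad)[rad >= cutoff]
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing `x` or more successes when drawing `n`
#' elements without replacement from a population of `N` containing `K`
#' successes.  Used to test whether the extracted subnetwork is enriched
#' in experimentally validated arcs.  Computed in log space, so extreme
#' enrichment keeps a meaningful (if denormal) value; `log = TRUE`
#' returns the natural-log probability.
#'
#' @param N population size (arcs eligible for selection).
#' @param K number of successes in the population (validated arcs).
#' @param n sample size (arcs kept).
#' @param x observed successes in the sample (validated arcs kept).
#' @param log return the natural logarithm of the probability.
#' @return `P(X >= x)` (or its log).
#' @examples
#' hypergeomEnrichment(10, 5, 4, 4)   # 5/210
#' @export
hypergeomEnrichment <- function(N, K, n, x, log = FALSE) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L,
            length(x) == 1L)
  if (any(c(N, K, n, x) < 0) || K > N || n > N || x > n ||
      any(c(N, K, n, x) != floor(c(N, K, n, x))))
    stop("inconsistent hypergeometric counts: need 0 <= x <= n <= N, 0 <= K <= N")
  lp <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  if (log) lp else exp(lp)
}

#' Summary report comparing an output subnetwork with its input
#'
#' Assembles the headline evaluation quantities: arcs and vertices kept,
#' the fraction of co-expressed pairs explained, retention of validated
#' versus non-validated arcs with a hypergeometric enrichment p-value,
#' average degrees, and banded p-value histograms of the affinity arcs
#' before and after extraction.  Percentages are reported at one decimal
#' place.
#'
#' @param apriori the input [AprioriGraph-class].
#' @param output the [LombardeResult-class] obtained from it.
#' @param validatedArcs optional data.frame (`from`, `to`) of
#'   independently validated regulations used for the bias evaluation;
#'   defaults to the validated flags present in `apriori` (extended
#'   scenario).  Supplying an external set reproduces the ab-initio
#'   protocol, where validation data are withheld from the input and
#'   used only to evaluate the bias.
#' @return JSON-serializable named list.
#' @export
networkReport <- function(apriori, output, validatedArcs = NULL) {
  stopifnot(is(apriori, "AprioriGraph"), is(output, "LombardeResult"))
  aIn <- apriori@arcs
  aOut <- arcs(output)
  s <- output@summary
  keyIn <- paste(aIn$from, aIn$to, sep = "\r")
  keyOut <- paste(aOut$from, aOut$to, sep = "\r")
  isVal <- if (is.null(validatedArcs)) aIn$validated
           else keyIn %in% paste(validatedArcs$from, validatedArcs$to, sep = "\r")
  kept <- keyIn %in% keyOut
  nVal <- sum(isVal); nValKept <- sum(isVal & kept)
  nOther <- sum(!isVal); nOtherKept <- sum(!isVal & kept)
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_
  enrich <- if (nVal > 0 && sum(kept) > 0)
    hypergeomEnrichment(nrow(aIn), nVal, sum(kept), nValKept, log = TRUE)
  else NA_real_
  pvalHist <- function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) return(stats::setNames(numeric(0), character(0)))
    br <- cut(log10(p), breaks = seq(-12, 0, by = 1), include.lowest = TRUE)
    tab <- table(br)
    stats::setNames(as.numeric(tab), names(tab))
  }
  list(
    nArcsApriori = nrow(aIn),
    nArcsKept = nrow(aOut),
    pctArcsKept = pct(nrow(aOut), nrow(aIn)),
    nVerticesApriori = length(apriori@vertices),
    nVerticesKept = s$nVerticesTouched,
    nPairsInput = s$nPairsInput,
    nPairsExplained = s$nPairsExplained,
    pctPairsExplained = pct(s$nPairsExplained, s$nPairsInput),
    nValidated = nVal,
    nValidatedKept = nValKept,
    pctValidatedKept = pct(nValKept, nVal),
    nNonValidated = nOther,
    nNonValidatedKept = nOtherKept,
    pctNonValidatedKept = pct(nOtherKept, nOther),
    logEnrichmentP = enrich,
    averageDegreeApriori = nrow(aIn) / max(length(apriori@vertices), 1L),
    averageDegreeOutput = if (s$nVerticesTouched > 0)
      nrow(aOut) / s$nVerticesTouched else NA_real_,
    pvalueHistogramApriori = pvalHist(aIn$p),
    pvalueHistogramOutput = pvalHist(aOut$p))
}
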