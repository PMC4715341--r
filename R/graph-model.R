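# Reading edge-list inputs, building the a-priori graph, operon-level
# condensation, and deterministic network output.

.readTsv <- function(source) {
  lines <- if (is.character(source) && length(source) == 1L &&
               !grepl("[\t\n]", source)) {
    if (!file.exists(source))
      stop("cannot open input file: ", source)
    readLines(source)
  } else if (inherits(source, "connection")) {
    readLines(source)
  } else {
    as.character(source)
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a tab-separated arc table
#'
#' Reads regulator/target arc lists: two columns (`regulator`, `target`)
#' for experimentally validated arcs, three columns (with an affinity
#' p-value) for predicted TF/binding-site arcs.  Lines starting with `#`
#' are comments/headers and are skipped.
#'
#' @param source path to a file, a connection, or a character vector of
#'   lines.
#' @param hasPvalue logical; if `TRUE` the third column is parsed as the
#'   affinity p-value and the records are affinity arcs; if `FALSE` the
#'   records are validated arcs (no p-value).
#' @return A `data.frame` with columns `from`, `to`, `p` (NA when
#'   `hasPvalue = FALSE`) and `validated` (`!hasPvalue`).
#' @examples
#' readArcTable(c("tfA\topX\t1e-6"), hasPvalue = TRUE)
#' @export
readArcTable <- function(source, hasPvalue = TRUE) {
  tsv <- .readTsv(source)
  ncols <- if (hasPvalue) 3L else 2L
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != ncols
  if (any(bad))
    stop(sprintf("line %d: expected %d tab-separated fields",
                 tsv$lineno[which(bad)[1L]], ncols))
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  if (any(!nzchar(from)) || any(!nzchar(to)))
    stop(sprintf("line %d: empty vertex identifier",
                 tsv$lineno[which(!nzchar(from) | !nzchar(to))[1L]]))
  if (hasPvalue) {
    p <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
    bad <- is.na(p) | p <= 0 | p > 1
    if (any(bad))
      stop(sprintf("line %d: p-value must be a number in (0, 1]",
                   tsv$lineno[which(bad)[1L]]))
  } else {
    p <- rep(NA_real_, length(from))
  }
  data.frame(from = from, to = to, p = p, validated = !hasPvalue,
             stringsAsFactors = FALSE)
}

#' Read a co-expressed pair list
#'
#' Two tab-separated columns of vertex identifiers per line; lines
#' starting with `#` are skipped.  The result is canonicalized with
#' [coexpressionSet()].
#'
#' @inheritParams readArcTable
#' @return A canonical co-expression `data.frame` (columns `a`, `b`).
#' @export
readCoexpression <- function(source) {
  tsv <- .readTsv(source)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad))
    stop(sprintf("line %d: expected 2 tab-separated fields",
                 tsv$lineno[which(bad)[1L]]))
  coexpressionSet(vapply(parts, `[[`, character(1), 1L),
                  vapply(parts, `[[`, character(1), 2L))
}

#' Read a gene-to-operon map
#'
#' Two tab-separated columns per line: gene identifier, operon identifier.
#'
#' @inheritParams readArcTable
#' @return Named character vector mapping gene -> operon.
#' @export
readOperonMap <- function(source) {
  tsv <- .readTsv(source)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad))
    stop(sprintf("line %d: expected 2 tab-separated fields",
                 tsv$lineno[which(bad)[1L]]))
  gene <- vapply(parts, `[[`, character(1), 1L)
  operon <- vapply(parts, `[[`, character(1), 2L)
  if (anyDuplicated(gene)) {
    dup <- gene[duplicated(gene)][1L]
    stop("gene mapped to more than one operon: ", dup)
  }
  stats::setNames(operon, gene)
}

#' Canonical set of co-expressed pairs
#'
#' Co-expression is symmetric: pairs are stored unordered, with the two
#' identifiers in lexicographic order, self-pairs rejected and duplicates
#' removed.
#'
#' @param a,b character vectors of vertex identifiers (recycled to common
#'   length).
#' @return `data.frame` with columns `a`, `b` (`a < b` lexicographically,
#'   byte order), one row per distinct pair.
#' @export
coexpressionSet <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == length(b))
  if (any(a == b))
    stop("self-pairs are not allowed in a co-expression set")
  lo <- ifelse(.strlt(a, b), a, b)
  hi <- ifelse(.strlt(a, b), b, a)
  d <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  d <- d[order(d$a, d$b, method = "radix"), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# byte-order string comparison, locale-independent
.strlt <- function(a, b) {
  mapply(function(x, y) {
    xr <- charToRaw(x); yr <- charToRaw(y)
    m <- min(length(xr), length(yr))
    cmp <- which(xr[seq_len(m)] != yr[seq_len(m)])
    if (length(cmp)) xr[cmp[1L]] < yr[cmp[1L]]
    else length(xr) < length(yr)
  }, a, b, USE.NAMES = FALSE)
}

#' Build the a-priori regulatory graph
#'
#' Forms the simple directed graph whose arc set is the union of the
#' affinity arcs and the validated arcs.  Parallel affinity arcs on the
#' same ordered pair keep the minimum p-value.  An ordered pair present
#' in both inputs keeps its p-value and is flagged validated.  Likelihood
#' levels are assigned by equal-frequency binning of the affinity
#' p-values ([assignLevels()]); validated arcs are forced to level 0 (the
#' highest likelihood) regardless of any p-value.
#'
#' @param affinity data.frame of affinity arcs (`from`, `to`, `p`), e.g.
#'   from [readArcTable()] with `hasPvalue = TRUE`.
#' @param validated optional data.frame of validated arcs (`from`, `to`).
#' @param scheme a [CostScheme-class]; its boundaries slot is filled from
#'   the binning.
#' @return An [AprioriGraph-class].
#' @examples
#' aff <- data.frame(from = "x", to = "y", p = 1e-6)
#' buildAprioriGraph(aff, scheme = costScheme(k = 3, r = 3))
#' @export
buildAprioriGraph <- function(affinity, validated = NULL,
                              scheme = costScheme()) {
  stopifnot(is(scheme, "CostScheme"))
  aff <- if (is.null(affinity) || !nrow(affinity)) {
    data.frame(from = character(0), to = character(0), p = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    af <- affinity
    if (any(is.na(af$p) | af$p <= 0 | af$p > 1))
      stop("affinity arcs must carry p-values in (0, 1]")
    # parallel arcs: keep the minimum p-value per ordered pair
    key <- paste(af$from, af$to, sep = "\r")
    pmin <- tapply(af$p, key, min)
    idx <- !duplicated(key)
    af <- af[idx, c("from", "to", "p")]
    af$p <- as.numeric(pmin[paste(af$from, af$to, sep = "\r")])
    af
  }
  lv <- assignLevels(aff$p, scheme@k)
  aff$level <- lv$level
  scheme@boundaries <- lv$boundaries
  aff$validated <- logical(nrow(aff))
  if (!is.null(validated) && nrow(validated)) {
    vkey <- unique(paste(validated$from, validated$to, sep = "\r"))
    akey <- paste(aff$from, aff$to, sep = "\r")
    both <- akey %in% vkey
    aff$validated[both] <- TRUE
    aff$level[both] <- 0L
    vonly <- setdiff(vkey, akey)
    if (length(vonly)) {
      ft <- strsplit(vonly, "\r", fixed = TRUE)
      aff <- rbind(aff, data.frame(
        from = vapply(ft, `[[`, character(1), 1L),
        to = vapply(ft, `[[`, character(1), 2L),
        p = NA_real_, level = 0L, validated = TRUE,
        stringsAsFactors = FALSE))
    }
  }
  aff$cost <- .levelCostInt(scheme, aff$level) / .costScale(scheme)
  aff$costInt <- .levelCostInt(scheme, aff$level)
  verts <- sort(unique(c(aff$from, aff$to)), method = "radix")
  aff <- aff[order(aff$from, aff$to, method = "radix"),
             c("from", "to", "p", "validated", "level", "cost", "costInt")]
  rownames(aff) <- NULL
  g <- new("AprioriGraph", vertices = verts, arcs = aff, scheme = scheme)
  validObject(g)
  g
}

.mapIds <- function(ids, map, strict, what) {
  hit <- ids %in% names(map)
  if (!all(hit)) {
    miss <- unique(ids[!hit])
    if (strict)
      stop(sprintf("%d %s identifier(s) missing from the operon map (e.g. %s)",
                   length(miss), what, miss[1L]))
    message(sprintf("dropping %d %s record(s) with unmapped genes",
                    sum(!hit), what))
  }
  hit
}

#' Condense gene-level co-expression to operon level
#'
#' Each gene pair is lifted to the pair of operons containing the genes
#' (expression of a gene implies expression of its operon).  Pairs whose
#' two genes fall in the same operon are trivial and dropped; duplicate
#' operon pairs are redundant and deduplicated.
#'
#' @param pairs co-expression `data.frame` (columns `a`, `b`) over genes.
#' @param map named character vector gene -> operon ([readOperonMap()]).
#' @param strict if `TRUE` (default) an unmapped gene is an error;
#'   otherwise the offending pairs are dropped with a message.
#' @return Canonical co-expression `data.frame` over operons.
#' @export
condenseCoexpression <- function(pairs, map, strict = TRUE) {
  if (!nrow(pairs)) return(coexpressionSet(character(0), character(0)))
  ok <- .mapIds(pairs$a, map, strict, "co-expression") &
        .mapIds(pairs$b, map, strict, "co-expression")
  pairs <- pairs[ok, , drop = FALSE]
  oa <- unname(map[pairs$a]); ob <- unname(map[pairs$b])
  keep <- oa != ob                       # same-operon pairs are trivial
  coexpressionSet(oa[keep], ob[keep])
}

#' Condense gene-level affinity arcs to operon level
#'
#' Gene-level arcs are lifted to ordered operon pairs; when several TF
#' genes of one operon hit (the promoter region of) genes of another
#' operon, the arc is reported once with the minimum p-value among the
#' contributing gene-level arcs.  Self-arcs arising from genes of the
#' same operon are retained (they can never participate in an
#' explanation).
#'
#' @param arcTable data.frame of gene-level affinity arcs
#'   (`from`, `to`, `p`).
#' @param map named character vector gene -> operon.
#' @param strict see [condenseCoexpression()].
#' @return data.frame of operon-level arcs (`from`, `to`, `p`,
#'   `validated`), one row per ordered operon pair.
#' @export
condenseAffinity <- function(arcTable, map, strict = TRUE) {
  if (!nrow(arcTable))
    return(data.frame(from = character(0), to = character(0), p = numeric(0),
                      validated = logical(0), stringsAsFactors = FALSE))
  ok <- .mapIds(arcTable$from, map, strict, "affinity") &
        .mapIds(arcTable$to, map, strict, "affinity")
  arcTable <- arcTable[ok, , drop = FALSE]
  of <- unname(map[arcTable$from]); ot <- unname(map[arcTable$to])
  key <- paste(of, ot, sep = "\r")
  pmin <- tapply(arcTable$p, key, min)
  idx <- !duplicated(key)
  out <- data.frame(from = of[idx], to = ot[idx],
                    p = as.numeric(pmin[key[idx]]),
                    validated = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a network as a deterministic TSV
#'
#' One row per arc with columns `regulator`, `target`, `level`, `cost`,
#' `validated` and `pairUse` (number of co-expressed pairs whose optimal
#' explanations use the arc; 0 for an a-priori graph).  Rows are sorted
#' lexicographically by (regulator, target) so that output is
#' byte-reproducible.
#'
#' @param x an [AprioriGraph-class] or [LombardeResult-class].
#' @param file output path or connection.
#' @return Invisibly, the data.frame written.
#' @export
writeNetwork <- function(x, file) {
  a <- arcs(x)
  pu <- if ("pairUse" %in% names(a)) a$pairUse else rep(0L, nrow(a))
  d <- data.frame(regulator = a$from, target = a$to, level = a$level,
                  cost = a$cost, validated = as.integer(a$validated),
                  pairUse = pu, stringsAsFactors = FALSE)
  d <- d[order(d$regulator, d$target, method = "radix"), , drop = FALSE]
  lines <- c("#regulator\ttarget\tlevel\tcost\tvalidated\tpairUse",
             sprintf("%s\t%s\t%d\t%s\t%d\t%d", d$regulator, d$target,
                     d$level, format(d$cost, trim = TRUE, scientific = FALSE,
                                     drop0trailing = TRUE),
                     d$validated, d$pairUse))
  writeLines(lines, file)
  invisible(d)
}

#' Read a network TSV written by [writeNetwork()]
#'
#' @param file input path or connection.
#' @return data.frame with columns `regulator`, `target`, `level`,
#'   `cost`, `validated`, `pairUse`.
#' @export
readNetwork <- function(file) {
  tsv <- .readTsv(file)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 6L
  if (any(bad))
    stop(sprintf("line %d: expected 6 tab-separated fields",
                 tsv$lineno[which(bad)[1L]]))
  data.frame(
    regulator = vapply(parts, `[[`, character(1), 1L),
    target = vapply(parts, `[[`, character(1), 2L),
    level = as.integer(vapply(parts, `[[`, character(1), 3L)),
    cost = as.numeric(vapply(parts, `[[`, character(1), 4L)),
    validated = as.integer(vapply(parts, `[[`, character(1), 5L)),
    pairUse = as.integer(vapply(parts, `[[`, character(1), 6L)),
    stringsAsFactors = FALSE)
}

#' Export a network in SIF format
#'
#' Simple interaction format: `regulator regulates target`, one arc per
#' line, sorted as in [writeNetwork()].
#'
#' @inheritParams writeNetwork
#' @export
writeSif <- function(x, file) {
  a <- arcs(x)
  d <- a[order(a$from, a$to, method = "radix"), , drop = FALSE]
  writeLines(sprintf("%s\tregulates\t%s", d$from, d$to), file)
  invisible(NULL)
}
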