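# Independent brute-force oracles and random-instance generators used
# across the test files.  These deliberately avoid the package's own
# shortest-path machinery wherever they check it.

# random a-priori graph on <= maxV vertices with random scheme
randomApriori <- function(seed, maxV = 9L, k = NULL, r = NULL,
                          pValidated = 0) {
  set.seed(seed)
  nV <- sample(4:maxV, 1L)
  verts <- LETTERS[seq_len(nV)]
  maxArcs <- nV * (nV - 1L)
  nA <- sample(seq(nV, min(maxArcs, 2L * nV)), 1L)
  pool <- expand.grid(from = verts, to = verts, stringsAsFactors = FALSE)
  pool <- pool[pool$from != pool$to, ]
  sel <- pool[sample.int(nrow(pool), nA), ]
  aff <- data.frame(from = sel$from, to = sel$to,
                    p = 10^runif(nA, -9, -1), stringsAsFactors = FALSE)
  validated <- NULL
  if (pValidated > 0) {
    nVal <- rbinom(1L, nA, pValidated)
    if (nVal > 0)
      validated <- aff[sample.int(nA, nVal), c("from", "to")]
  }
  if (is.null(k)) k <- sample(2:4, 1L)
  if (is.null(r)) r <- sample(c(1, 1.5, 2, 3, 10), 1L)
  buildAprioriGraph(aff, validated, costScheme(k = k, r = r))
}

# pick a random pair of distinct vertices
randomPair <- function(graph, seed) {
  set.seed(seed + 10000L)
  sample(vertices(graph), 2L)
}

arcKey <- function(idx) paste(sort(idx), collapse = ",")

explCosts <- function(exps) vapply(exps, function(e) e@costInt, numeric(1))

# union of arc indices over the minimum-cost enumerated explanations
enumOptUnion <- function(exps) {
  ci <- explCosts(exps)
  sort(unique(unlist(lapply(exps[ci == min(ci)], function(e) e@arcIdx))))
}

# --- independent explanation checker (structural, no path search) ---------

# does `idx` form a simple directed path s -> t using every arc?
.isPathSet <- function(a, idx, s, t) {
  sub <- a[idx, , drop = FALSE]
  if (anyDuplicated(sub$from) || anyDuplicated(sub$to)) return(FALSE)
  nxt <- setNames(sub$to, sub$from)
  cur <- s
  used <- 0L
  seen <- character(0)
  while (cur %in% names(nxt)) {
    if (cur %in% seen) return(FALSE)
    seen <- c(seen, cur)
    cur <- unname(nxt[cur])
    used <- used + 1L
  }
  cur == t && used == length(idx)
}

# is `idx` an explanation of (A, B)?  Checks the three shapes directly:
# a simple path either way, or any split into two vertex-disjoint
# (except the root) paths from a common vertex C to A and to B.
isExplanationSet <- function(graph, idx, A, B) {
  a <- arcs(graph)
  if (!length(idx)) return(FALSE)
  if (.isPathSet(a, idx, A, B) || .isPathSet(a, idx, B, A)) return(TRUE)
  sub <- a[idx, , drop = FALSE]
  roots <- names(which(table(sub$from) == 2L))
  n <- length(idx)
  for (C in setdiff(roots, c(A, B))) {
    for (m in 1:(2^n - 2L)) {
      take <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1L)))
      ia <- idx[take]; ib <- idx[!take]
      if (.isPathSet(a, ia, C, A) && .isPathSet(a, ib, C, B)) {
        va <- unique(c(a$from[ia], a$to[ia]))
        vb <- unique(c(a$from[ib], a$to[ib]))
        if (setequal(intersect(va, vb), C)) return(TRUE)
      }
    }
  }
  FALSE
}

# brute-force enumeration of explanations by scanning all arc subsets;
# only for very small graphs (<= maxArcs arcs)
bruteExplanations <- function(graph, A, B, maxArcs = 12L) {
  a <- arcs(graph)
  n <- nrow(a)
  stopifnot(n <= maxArcs)
  found <- list()
  for (m in 1:(2^n - 1L)) {
    idx <- which(as.logical(bitwAnd(m, 2^(seq_len(n) - 1L))))
    if (isExplanationSet(graph, idx, A, B))
      found[[length(found) + 1L]] <- idx
  }
  found
}

# pair explainable within an arc subset, via unweighted reachability only
reachExplainable <- function(graph, idx, A, B) {
  a <- arcs(graph)[idx, , drop = FALSE]
  verts <- unique(c(a$from, a$to, A, B))
  reach <- diag(length(verts)) > 0
  dimnames(reach) <- list(verts, verts)
  repeat {
    new <- reach
    for (i in seq_len(nrow(a)))
      new[, a$to[i]] <- new[, a$to[i]] | new[, a$from[i]]
    if (identical(new, reach)) break
    reach <- new
  }
  any(reach[, A] & reach[, B])
}

# brute-force minimum-cost explaining subgraphs by scanning arc subsets
bruteMinExplainingSubgraphs <- function(graph, pairs, maxArcs = 12L) {
  a <- arcs(graph)
  n <- nrow(a)
  stopifnot(n <= maxArcs)
  best <- Inf
  sets <- list()
  for (m in 1:(2^n - 1L)) {
    idx <- which(as.logical(bitwAnd(m, 2^(seq_len(n) - 1L))))
    cs <- sum(a$costInt[idx])
    if (cs > best) next
    ok <- all(vapply(seq_len(nrow(pairs)), function(i)
      reachExplainable(graph, idx, pairs$a[i], pairs$b[i]), logical(1)))
    if (!ok) next
    if (cs < best) {
      best <- cs
      sets <- list(idx)
    } else sets[[length(sets) + 1L]] <- idx
  }
  list(costInt = best, sets = sets)
}

# deterministic simple digraph with a prescribed number of vertices and
# distinct arcs: vertex u -> vertex u + j (mod n); p-values spread over
# many distinct values so any k bins cleanly
denseGraph <- function(nVertices, nArcs, k = 9, r = 10) {
  verts <- sprintf("v%04d", seq_len(nVertices))
  i <- seq_len(nArcs) - 1L
  u <- i %% nVertices
  j <- i %/% nVertices + 1L
  stopifnot(max(j) < nVertices)
  aff <- data.frame(from = verts[u + 1L],
                    to = verts[(u + j) %% nVertices + 1L],
                    p = 10^(-9 + 8 * (i %% 97) / 96),
                    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(paste(aff$from, aff$to)))
  g <- buildAprioriGraph(aff, scheme = costScheme(k, r))
  stopifnot(length(vertices(g)) == nVertices)
  g
}

# exact combinatorial upper-tail hypergeometric probability
hyperUpperBrute <- function(N, K, n, x) {
  js <- x:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
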