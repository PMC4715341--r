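toy <- toyTRN()

test_that("cheapest-path distances are exact and handle unreachability", {
  sc <- costScheme(k = 2, r = 3)
  g <- buildAprioriGraph(
    data.frame(from = c("x", "y"), to = c("y", "z"), p = c(1e-6, 1e-3)),
    scheme = sc)
  d <- distancesTo(g, "y")
  expect_equal(unname(d[c("x", "y", "z")]), c(1, 0, Inf))
  d2 <- distancesTo(g, "z")
  expect_equal(unname(d2["x"]), 4)   # 1 + 3 through y
  expect_error(distancesTo(g, "nope"), "unknown vertex")
  # toy network: hand-traced distances towards I
  dI <- distancesTo(toy$graph, "I")
  expect_equal(unname(dI[c("I", "B", "C", "D", "A")]), c(0, 3, 9, 12, Inf))
})

test_that("toy network reproduces the worked example", {
  g <- toy$graph
  expect_equal(optimalExplanationCost(g, "F", "I"), 10)
  expect_equal(optimalExplanationCost(g, "G", "H"), 6)
  expect_equal(optimalExplanationCost(g, "A", "B"), 10)
  ex <- enumerateExplanations(g, "F", "I")
  expect_equal(length(ex), 6L)
  expect_equal(sum(explCosts(ex) == min(explCosts(ex))), 2L)
  # the two optimal explanations: divergent from C, and the path I->D->F
  expect_setequal(optimalRoots(g, "F", "I"), c("C", "I"))
  a <- arcs(g)
  key <- paste(a$from, a$to)
  union <- optimalExplanationArcs(g, "F", "I")
  expect_setequal(key[union], c("C F", "C I", "I D", "D F"))
  expect_equal(key[optimalExplanationArcs(g, "G", "H")],
               c("D G", "D H"))
})

test_that("direct-arc pairs resolve to the trivial explanation", {
  g <- suppressWarnings(
    buildAprioriGraph(data.frame(from = "A", to = "B", p = 1e-6),
                      scheme = costScheme(2, 2)))
  expect_equal(optimalExplanationCost(g, "A", "B"), 1)
  expect_equal(optimalRoots(g, "A", "B"), "A")
  expect_equal(optimalExplanationArcs(g, "A", "B"), 1L)
  expect_equal(length(enumerateExplanations(g, "A", "B")), 1L)
  expect_error(optimalExplanationCost(g, "A", "A"), "must differ")
  expect_error(optimalExplanationCost(g, "A", "zz"), "unknown vertex")
})

test_that("isolated pairs are unexplainable and filtered out", {
  g <- buildAprioriGraph(
    data.frame(from = c("a", "c"), to = c("b", "d"), p = c(1e-6, 1e-5)),
    scheme = costScheme(2, 2))
  expect_equal(optimalExplanationCost(g, "a", "d"), Inf)
  expect_equal(optimalRoots(g, "a", "d"), character(0))
  expect_equal(optimalExplanationArcs(g, "a", "d"), integer(0))
  pairs <- coexpressionSet(c("a", "a", "a"), c("b", "d", "zz"))
  part <- suppressMessages(filterExplainable(g, pairs))
  expect_equal(nrow(part$explainable), 1L)
  expect_setequal(part$removed$reason, c("unknown_vertex", "unexplainable"))
  # toy pairs are all explainable
  partToy <- filterExplainable(toy$graph, toy$pairs)
  expect_equal(nrow(partToy$explainable), 3L)
  expect_equal(nrow(partToy$removed), 0L)
})

test_that("the output subnetwork is the union of all optimal explanations", {
  res <- runLombarde(toy$graph, toy$pairs)
  a <- arcs(res)
  key <- paste(a$from, a$to)
  expect_setequal(key, c("B C", "C A", "C F", "C I", "D F", "D G", "D H",
                         "I D"))
  expect_true(all(a$pairUse == 1L))
  s <- summary(res)
  expect_equal(s$nArcsKept, 8L)
  expect_equal(s$nPairsExplained, 3L)
  expect_equal(s$nVerticesTouched, 8L)
  # empty co-expression set: empty output
  res0 <- runLombarde(toy$graph, coexpressionSet(character(0), character(0)))
  expect_equal(nrow(arcs(res0)), 0L)
  # per-pair result objects carry the optimum
  pp <- perPair(res)
  costs <- sapply(pp, function(x) x@optCost)
  prs <- sapply(pp, function(x) paste(x@pair, collapse = ""))
  expect_equal(costs[match(c("FI", "AB", "GH"), prs)], c(10, 10, 6))
})

test_that("every arc reported for a pair lies on an optimal explanation", {
  for (s in 1:40) {
    g <- randomApriori(s)
    pr <- randomPair(g, s)
    exps <- enumerateExplanations(g, pr[1], pr[2])
    union <- optimalExplanationArcs(g, pr[1], pr[2])
    if (!length(exps)) {
      expect_equal(length(union), 0L)
      expect_equal(optimalExplanationCost(g, pr[1], pr[2]), Inf)
      next
    }
    ci <- explCosts(exps)
    expect_equal(optimalExplanationCost(g, pr[1], pr[2]) *
                   lombarde:::.costScale(scheme(g)),
                 min(ci))
    expect_equal(union, enumOptUnion(exps))
  }
})

test_that("the enumeration oracle agrees with an independent subset scan", {
  for (s in c(3, 11, 21, 34)) {
    set.seed(s)
    verts <- letters[1:5]
    pool <- expand.grid(from = verts, to = verts, stringsAsFactors = FALSE)
    pool <- pool[pool$from != pool$to, ]
    sel <- pool[sample.int(nrow(pool), 7L), ]
    g <- buildAprioriGraph(
      data.frame(sel, p = 10^runif(7, -8, -2)), scheme = costScheme(2, 2))
    pr <- sample(vertices(g), 2L)
    exps <- enumerateExplanations(g, pr[1], pr[2])
    brute <- bruteExplanations(g, pr[1], pr[2], maxArcs = 8L)
    expect_setequal(vapply(exps, function(e) arcKey(e@arcIdx), character(1)),
                    vapply(brute, arcKey, character(1)))
  }
})

test_that("enumeration refuses oversized graphs", {
  g <- randomApriori(1, maxV = 9L)
  expect_error(enumerateExplanations(g, vertices(g)[1], vertices(g)[2],
                                     maxVertices = 3L),
               "refuses > 3")
})

test_that("optimum is symmetric and monotone under arc insertion", {
  for (s in 1:15) {
    g <- randomApriori(s + 100)
    pr <- randomPair(g, s)
    o1 <- optimalExplanationCost(g, pr[1], pr[2])
    expect_identical(o1, optimalExplanationCost(g, pr[2], pr[1]))
    # removing an arc never decreases the optimum
    if (nrow(arcs(g)) > 1) {
      set.seed(s)
      drop <- sample.int(nrow(arcs(g)), 1L)
      g2 <- arcSubgraph(g, setdiff(seq_len(nrow(arcs(g))), drop),
                        keepVertices = pr)
      expect_gte(optimalExplanationCost(g2, pr[1], pr[2]), o1)
    }
  }
})

test_that("optimal roots match the exhaustive per-vertex check", {
  for (s in 1:20) {
    g <- randomApriori(s + 300)
    pr <- randomPair(g, s)
    opt <- optimalExplanationCost(g, pr[1], pr[2])
    roots <- optimalRoots(g, pr[1], pr[2])
    dA <- distancesTo(g, pr[1]); dB <- distancesTo(g, pr[2])
    brute <- names(which(dA + dB == opt))
    if (!is.finite(opt)) brute <- character(0)
    expect_setequal(roots, brute)
  }
})

test_that("explainable pairs keep their optimum inside the output subgraph", {
  for (s in c(2, 9, 17)) {
    g <- randomApriori(s + 500, maxV = 8L)
    verts <- vertices(g)
    set.seed(s)
    n <- min(4L, length(verts) %/% 2L)
    pairs <- coexpressionSet(verts[seq_len(n) * 2 - 1], verts[seq_len(n) * 2])
    res <- suppressMessages(runLombarde(g, pairs))
    gl <- res@graph
    for (x in perPair(res)) {
      expect_identical(
        optimalExplanationCost(gl, x@pair[1], x@pair[2]), x@optCost)
    }
  }
})

test_that("with r = 1 the output matches the single-level output", {
  toyAff <- toyTRN()$affinity
  g1 <- buildAprioriGraph(toyAff, scheme = costScheme(k = 3, r = 1))
  gk <- buildAprioriGraph(toyAff, scheme = costScheme(k = 1, r = 10))
  pairs <- toyTRN()$pairs
  r1 <- runLombarde(g1, pairs)
  rk <- runLombarde(gk, pairs)
  key <- function(res) paste(arcs(res)$from, arcs(res)$to)
  expect_setequal(key(r1), key(rk))
})
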