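test_that("arc tables parse with validation and line numbers", {
  r <- readArcTable(c("tfA\topX\t1e-6"), hasPvalue = TRUE)
  expect_equal(r$from, "tfA")
  expect_equal(r$to, "opX")
  expect_equal(r$p, 1e-6)
  expect_false(r$validated)
  r2 <- readArcTable(c("# header", "tfA\topX"), hasPvalue = FALSE)
  expect_true(is.na(r2$p))
  expect_true(r2$validated)
  expect_error(readArcTable(c("tfA\topX\t2.0"), TRUE), "line 1.*\\(0, 1\\]")
  expect_error(readArcTable(c("tfA\topX\t1e-3", "tfB\topY"), TRUE),
               "line 2")
  expect_error(readArcTable(c("tfA\topX\tnope"), TRUE), "p-value")
  expect_error(readArcTable("/no/such/file.tsv", TRUE), "cannot open")
})

test_that("the a-priori graph is the union of affinity and validated arcs", {
  sc <- costScheme(k = 2, r = 2)
  aff <- data.frame(from = "x", to = "y", p = 1e-6)
  g <- suppressWarnings(buildAprioriGraph(aff, scheme = sc))
  expect_equal(length(vertices(g)), 2L)
  expect_equal(nrow(arcs(g)), 1L)
  expect_false(arcs(g)$validated)
  # ordered pair in both inputs: one arc, validated, keeps p, level 0
  val <- data.frame(from = c("x", "u"), to = c("y", "y"))
  g2 <- buildAprioriGraph(
    data.frame(from = c("x", "x"), to = c("y", "z"), p = c(1e-4, 1e-8)),
    val, sc)
  a <- arcs(g2)
  xy <- a[a$from == "x" & a$to == "y", ]
  expect_true(xy$validated)
  expect_equal(xy$p, 1e-4)
  expect_equal(xy$level, 0L)
  uy <- a[a$from == "u" & a$to == "y", ]
  expect_true(is.na(uy$p))
  expect_equal(uy$cost, 1)
  expect_equal(nrow(a), 3L)   # union of 2 affinity + 2 validated, 1 shared
})

test_that("union cardinality matches |A| + |V| - |A ∩ V| at scale", {
  # construct disjoint id spaces mimicking the published input sizes
  nA <- 25604L; nV <- 1652L; nBoth <- 444L
  src <- sprintf("t%05d", seq_len(300))
  tgt <- sprintf("o%05d", seq_len(200))
  pool <- expand.grid(from = src, to = tgt, stringsAsFactors = FALSE)
  aff <- pool[seq_len(nA), ]
  aff$p <- rep(10^seq(-9, -2, length.out = 18), length.out = nA)
  val <- rbind(aff[seq_len(nBoth), c("from", "to")],
               pool[nA + seq_len(nV - nBoth), ])
  g <- buildAprioriGraph(aff, val, costScheme(k = 9, r = 10))
  expect_equal(nrow(arcs(g)), 26812L)
  expect_equal(sum(arcs(g)$validated), nV)
})

test_that("parallel affinity arcs keep the minimum p-value", {
  aff <- data.frame(from = c("a", "a", "a"), to = c("b", "b", "c"),
                    p = c(1e-4, 1e-7, 1e-5))
  g <- buildAprioriGraph(aff, scheme = costScheme(k = 2, r = 2))
  ab <- arcs(g)[arcs(g)$from == "a" & arcs(g)$to == "b", ]
  expect_equal(nrow(arcs(g)), 2L)
  expect_equal(ab$p, 1e-7)
})

test_that("co-expression condensation lifts, drops trivial, dedups redundant", {
  map <- c(g1 = "op1", g2 = "op1", g3 = "op1", g4 = "op2", g5 = "op2")
  # both genes in one operon: trivial, dropped
  expect_equal(nrow(condenseCoexpression(
    coexpressionSet("g1", "g2"), map)), 0L)
  # two gene pairs collapsing onto one operon pair: deduplicated
  cx <- coexpressionSet(c("g1", "g3"), c("g4", "g5"))
  out <- condenseCoexpression(cx, map)
  expect_equal(nrow(out), 1L)
  expect_equal(unlist(out, use.names = FALSE), c("op1", "op2"))
  # 3 gene pairs mapping to 2 distinct non-trivial operon pairs
  map2 <- c(map, g6 = "op3")
  cx3 <- coexpressionSet(c("g1", "g2", "g1"), c("g4", "g5", "g6"))
  expect_equal(nrow(condenseCoexpression(cx3, map2)), 2L)
  # strict vs lenient unmapped handling
  cxm <- coexpressionSet("g1", "gX")
  expect_error(condenseCoexpression(cxm, map), "missing from the operon map")
  expect_message(out <- condenseCoexpression(cxm, map, strict = FALSE),
                 "unmapped")
  expect_equal(nrow(out), 0L)
})

test_that("affinity condensation groups by operon pair with min-p", {
  map <- c(tf1 = "op1", tf2 = "op1", gA = "op2", gB = "op2", tf3 = "op3")
  arcsG <- data.frame(from = c("tf1", "tf2", "tf1", "tf3"),
                      to = c("gA", "gB", "gB", "gA"),
                      p = c(1e-6, 1e-8, 1e-3, 1e-5))
  out <- condenseAffinity(arcsG, map)
  expect_equal(nrow(out), 2L)   # verified by exhaustive grouping
  expect_equal(out$p[out$from == "op1" & out$to == "op2"], 1e-8)
  expect_equal(out$p[out$from == "op3" & out$to == "op2"], 1e-5)
  # identity: single arc passes through unchanged
  one <- condenseAffinity(data.frame(from = "tf1", to = "gA", p = 1e-4), map)
  expect_equal(one$from, "op1")
  expect_equal(one$p, 1e-4)
})

test_that("condensation under the identity map is the identity", {
  toy <- toyTRN()
  idmap <- setNames(vertices(toy$graph), vertices(toy$graph))
  aff2 <- condenseAffinity(toy$affinity, idmap)
  key <- function(d) paste(d$from, d$to, d$p)
  expect_setequal(key(aff2), key(toy$affinity))
  cx2 <- condenseCoexpression(toy$pairs, idmap)
  expect_equal(cx2, toy$pairs)
})

test_that("network TSV round-trips byte-identically", {
  toy <- toyTRN()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(toy$graph, f1)
  expect_equal(length(readLines(f1)) - 1L, 12L)  # header + one row per arc
  d <- readNetwork(f1)
  # write(read(file)) reproduces the canonical file byte for byte
  d2 <- data.frame(from = d$regulator, to = d$target, p = NA_real_,
                   validated = d$validated == 1L, level = d$level,
                   cost = d$cost, costInt = d$cost, pairUse = d$pairUse)
  fake <- new("AprioriGraph",
              vertices = sort(unique(c(d2$from, d2$to)), method = "radix"),
              arcs = transform(d2, p = ifelse(validated, NA, 1e-6)),
              scheme = scheme(toy$graph))
  writeNetwork(fake, f2)
  expect_identical(readLines(f1), readLines(f2))
  # empty graph: header only
  g0 <- buildAprioriGraph(data.frame(from = character(0), to = character(0),
                                     p = numeric(0)))
  f3 <- withr::local_tempfile()
  writeNetwork(g0, f3)
  expect_equal(readLines(f3), "#regulator\ttarget\tlevel\tcost\tvalidated\tpairUse")
})

test_that("graph validity rejects malformed objects", {
  toy <- toyTRN()
  g <- toy$graph
  bad <- g
  bad@arcs <- rbind(g@arcs, g@arcs[1, ])
  expect_error(validObject(bad), "parallel arcs")
  bad2 <- g
  bad2@arcs$level[1] <- 5L
  expect_error(validObject(bad2), "0 .. k-1")
  # self-loops are retained but never explain anything
  aff <- data.frame(from = c("a", "a"), to = c("a", "b"), p = c(1e-6, 1e-5))
  gl <- buildAprioriGraph(aff, scheme = costScheme(2, 2))
  expect_equal(nrow(arcs(gl)), 2L)
  # the loop takes the likelier level; a->b lands at level 1, cost 2
  expect_equal(optimalExplanationCost(gl, "a", "b"), 2)
  ex <- enumerateExplanations(gl, "a", "b")
  expect_equal(length(ex), 1L)
  expect_equal(ex[[1]]@arcIdx, which(arcs(gl)$to == "b"))
})
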