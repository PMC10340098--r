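test_that("Adamic-Adar closed forms on path and triangle", {
  # path A-C-B, both weights 1: C is the only common neighbor (strength 2)
  net <- networkFromEdges(edgeDf(c("A", "C"), c("C", "B"), c(1, 1)))
  aa <- adamicAdarScores(wholeModule(net))
  expect_equal(aa[["A"]], 1 / log(2), tolerance = 1e-12)
  expect_equal(aa[["B"]], 1 / log(2), tolerance = 1e-12)
  expect_equal(aa[["C"]], 0)

  # triangle, all weights 1: every node pairs twice via a degree-2 neighbor
  tri <- networkFromEdges(edgeDf(c("A", "B", "C"), c("B", "C", "A"),
                                 c(1, 1, 1)))
  aaT <- adamicAdarScores(wholeModule(tri))
  expect_equal(unname(aaT), rep(2 / log(2), 3), tolerance = 1e-12)

  # single edge: no length-2 paths, all scores zero
  e1 <- networkFromEdges(edgeDf("A", "B", 0.7))
  expect_equal(unname(adamicAdarScores(wholeModule(e1))), c(0, 0))
})

test_that("Adamic-Adar matches the brute-force triple-loop oracle", {
  set.seed(101)
  for (i in 1:10) {
    net <- randomNetwork(sample(5:20, 1), minW = 0.05)
    mod <- wholeModule(net)
    fast <- adamicAdarScores(mod)
    slow <- bruteAdamicAdar(mod)
    expect_equal(fast[sort(names(fast))], slow, tolerance = 1e-10)
  }
})

test_that("weak module strengths never produce negative or unbounded scores", {
  # strengths below 1: the floored denominator keeps contributions
  # positive and capped at 1/log(2)
  net <- networkFromEdges(edgeDf(c("A", "C"), c("C", "B"), c(0.15, 0.2)))
  aa <- adamicAdarScores(wholeModule(net))
  expect_true(all(aa >= 0))
  expect_equal(aa[["A"]], 1 / log(2), tolerance = 1e-12)
  expect_equal(adamicAdarScores(wholeModule(net), strengthFloor = 3)[["A"]],
               1 / log(3), tolerance = 1e-12)
})

test_that("PageRank symmetry, normalization, and oracle equivalence", {
  tri <- networkFromEdges(edgeDf(c("A", "B", "C"), c("B", "C", "A"),
                                 c(0.4, 0.4, 0.4)))
  pr <- pagerankScores(wholeModule(tri))
  expect_equal(unname(pr), rep(1 / 3, 3), tolerance = 1e-9)

  star <- networkFromEdges(edgeDf(rep("hub", 3), c("l1", "l2", "l3"),
                                  rep(0.5, 3)))
  prs <- pagerankScores(wholeModule(star))
  expect_gt(prs[["hub"]], prs[["l1"]])
  expect_equal(prs[["l1"]], prs[["l2"]], tolerance = 1e-10)
  expect_equal(sum(prs), 1, tolerance = 1e-9)

  set.seed(202)
  for (i in 1:10) {
    net <- randomNetwork(sample(4:15, 1))
    mod <- wholeModule(net)
    fast <- pagerankScores(mod)
    expect_equal(sum(fast), 1, tolerance = 1e-9)
    expect_equal(fast[sort(names(fast))], densePagerank(mod),
                 tolerance = 1e-8)
    # independent library cross-check
    ig <- igraph::page_rank(subnetwork(mod)@graph, damping = 0.75,
                            weights = igraph::E(subnetwork(mod)@graph)$weight)
    expect_equal(unname(fast[names(ig$vector)]), unname(ig$vector),
                 tolerance = 1e-6)
  }
})

test_that("z-adjustments reproduce the closed-form factor cases", {
  net <- pathNetwork(c("A", "B", "C"))
  modSelf <- buildModule(net, "B", "DAPN")   # members A, B, C
  modOther <- buildModule(net, "A", "DGN")   # members A, B
  base <- c(A = 1.4427, B = 2.0, C = 2.0)

  # canceling z on a shared gene: factor 0.5^0 = 1
  m <- adjustMultiplicative(base, modSelf, modOther,
                            c(A = 1.2), c(A = -1.2))
  expect_equal(m[["A"]], 1.4427)
  # gene in the scored module only: 2 * 0.5^2 = 0.5
  m2 <- adjustMultiplicative(base, modSelf, modOther, c(C = 2), numeric())
  expect_equal(m2[["C"]], 0.5)
  # unmeasured gene: neutral
  expect_equal(m2[["B"]], 2.0)

  # exponential variant: 2/e^2; canceling z; zero base absorbs
  e <- adjustExponential(base, modSelf, modOther, c(C = 2), numeric())
  expect_equal(e[["C"]], 2 / exp(2), tolerance = 1e-12)
  e2 <- adjustExponential(c(A = 5, B = 0, C = 1), modSelf, modOther,
                          c(A = 1, B = 9), c(A = -1))
  expect_equal(e2[["A"]], 5.0)
  expect_equal(e2[["B"]], 0)
})

test_that("both adjustments strictly decrease as the absolute z-sum grows", {
  net <- pathNetwork(c("A", "B", "C"))
  modSelf <- buildModule(net, "B", "DAPN")
  modOther <- buildModule(net, "A", "DGN")
  zs <- seq(0, 5, length.out = 100)
  mult <- vapply(zs, function(z)
    adjustMultiplicative(c(A = 1, B = 1, C = 1), modSelf, modOther,
                         c(C = z), numeric())[["C"]], 0)
  expo <- vapply(zs, function(z)
    adjustExponential(c(A = 1, B = 1, C = 1), modSelf, modOther,
                      c(C = z), numeric())[["C"]], 0)
  expect_true(all(diff(mult) < 0))
  expect_true(all(diff(expo) < 0))
})

test_that("adjustments preserve rank order when base scores are equal", {
  set.seed(303)
  net <- randomNetwork(12)
  mod <- wholeModule(net, "DAPN")
  other <- buildModule(net, nodes(net)[1], "DGN")
  z <- stats::setNames(rnorm(numNodes(net)), nodes(net))
  base <- stats::setNames(rep(3, numNodes(net)), nodes(net))
  m <- adjustMultiplicative(base, mod, other, z, numeric())
  e <- adjustExponential(base, mod, other, z, numeric())
  expect_equal(order(m), order(e))
})

test_that("neighborhood scoring closed forms and linearity", {
  # gene i with z 2; neighbors z -1 (w 0.5) and 3 (w 0.9), alpha 0.7
  net <- networkFromEdges(edgeDf(c("i", "i"), c("a", "b"), c(0.5, 0.9)))
  mod <- wholeModule(net)
  x <- neighborhoodScores(mod, c(i = 2, a = -1, b = 3))
  expect_equal(x[["i"]], 0.7 * 2 + 0.3 * ((-1 + 3) / 2), tolerance = 1e-12)

  # no supra-threshold neighbor: X = alpha * x
  net2 <- networkFromEdges(edgeDf(c("i", "a"), c("a", "b"), c(0.1, 0.8)),
                           floor = 0.05)
  mod2 <- wholeModule(net2)
  x2 <- neighborhoodScores(mod2, c(i = 4, a = 1, b = 1), epsilon = 0.1)
  expect_equal(x2[["i"]], 0.7 * 4, tolerance = 1e-12)  # only edge has w = 0.1

  # all-zero z gives all-zero scores; NS is linear in z
  expect_equal(unname(neighborhoodScores(mod, c(i = 0, a = 0, b = 0))),
               c(0, 0, 0))
  z <- c(i = 1.3, a = -0.4, b = 2.2)
  expect_equal(neighborhoodScores(mod, 3.7 * z),
               3.7 * neighborhoodScores(mod, z), tolerance = 1e-12)
})

test_that("scoreTable enforces the metric ranking direction convention", {
  expect_equal(rankDirection(scoreTable("AA2", c(a = 1))), "descending")
  expect_equal(rankDirection(scoreTable("NS", c(a = 1))), "ascending")
  expect_error(scoreTable("AA1", c(a = 1), rankDirection = "sideways"),
               "rankDirection")
})
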