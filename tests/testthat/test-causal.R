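test_that("top-variance gene selection matches a brute-force sort", {
  set.seed(1)
  expr <- matrix(rnorm(8 * 30, sd = rep(c(3, 1), each = 4 * 30)), 8, 30,
                 dimnames = list(paste0("g", 1:8), NULL))
  top <- selectTopVarianceGenes(expr, 0.25)
  expect_length(top, 2)          # ceiling(0.25 * 8)
  v <- apply(expr, 1, var)
  expect_setequal(top, names(sort(v, decreasing = TRUE))[1:2])

  expr2 <- rbind(expr, const = rep(5, 30))
  expect_false("const" %in% selectTopVarianceGenes(expr2, 0.5))
})

test_that("k-means discretization yields ordered, contiguous states", {
  expect_identical(discretizeKmeans(rep(4, 20)), rep(0L, 20))

  # well-separated trimodal data: three states matching the generating labels
  set.seed(2)
  lab <- sample(0:2, 90, replace = TRUE)
  x <- c(-10, 0, 10)[lab + 1] + rnorm(90, 0, 0.3)
  st <- discretizeKmeans(x, k = 3, seed = 3)
  expect_identical(st, lab)

  # bimodal data: two states, classified low and high
  lab2 <- sample(0:1, 60, replace = TRUE)
  x2 <- c(-5, 5)[lab2 + 1] + rnorm(60, 0, 0.3)
  st2 <- discretizeKmeans(x2, k = 3, seed = 4)
  expect_identical(sort(unique(st2)), 0:1)
  expect_identical(st2, lab2)

  # states are relabeled in increasing center order
  x3 <- c(rnorm(20, -3), rnorm(20, 3), rnorm(20, 9))
  st3 <- discretizeKmeans(x3, seed = 5)
  expect_true(mean(x3[st3 == 0]) < mean(x3[st3 == max(st3)]))
})

test_that("BDeu family scores match direct counting and decompose", {
  set.seed(6)
  child <- sample(0:2, 80, replace = TRUE)
  pa <- matrix(sample(0:1, 160, replace = TRUE), 2, 80)
  expect_equal(bdeuFamilyScore(child, pa), bruteBdeu(child, pa),
               tolerance = 1e-10)
  expect_equal(bdeuFamilyScore(child), bruteBdeu(child), tolerance = 1e-10)

  # decomposability: the network score of a learned DAG equals the sum of
  # family scores computed independently
  lay <- simulateCausalLayer(simulationConfig(dagNNodes = 4, dagNSamples = 150,
                                              seed = 7))
  disc <- discretizeExpression(lay$expr, seed = 8)
  net <- learnStructure(disc, structurePrior(), nRestarts = 3, seed = 9)
  edges <- networkEdges(net)
  total <- sum(vapply(rownames(disc), function(v) {
    pa <- edges[edges[, 2] == v, 1]
    bdeuFamilyScore(disc[v, ],
                    if (length(pa)) disc[pa, , drop = FALSE] else NULL)
  }, numeric(1)))
  expect_equal(attr(net, "score"), total, tolerance = 1e-8)
})

test_that("hill climbing attains the exhaustive optimum on 3 nodes", {
  lay <- simulateCausalLayer(simulationConfig(dagNSamples = 200,
                                              dagEffect = 1, seed = 10),
                             edges = rbind(c("A", "B"), c("B", "C")),
                             eqtlGenes = character())
  disc <- discretizeExpression(lay$expr, seed = 11)
  nodes <- rownames(disc)
  scoreDag <- function(edges) {
    sum(vapply(nodes, function(v) {
      pa <- if (NROW(edges)) edges[edges[, 2] == v, 1] else character()
      bdeuFamilyScore(disc[v, ],
                      if (length(pa)) disc[pa, , drop = FALSE] else NULL)
    }, numeric(1)))
  }
  dags <- allThreeNodeDags(nodes)
  expect_length(dags, 25)
  bestScore <- max(vapply(dags, scoreDag, numeric(1)))
  net <- learnStructure(disc, structurePrior(), nRestarts = 10, seed = 12)
  expect_equal(attr(net, "score"), bestScore, tolerance = 1e-8)
})

test_that("the learner recovers a chain with eQTL-anchored orientation", {
  cfg <- simulationConfig(dagNSamples = 500, dagEffect = 0.9, seed = 13)
  lay <- simulateCausalLayer(cfg, edges = rbind(c("A", "B"), c("B", "C")),
                             eqtlGenes = "A")
  disc <- discretizeExpression(lay$expr, seed = 14)
  net <- learnStructure(disc, structurePrior(eqtlGenes = "A"),
                        nRestarts = 10, seed = 15)
  skel <- edgeKeys(networkEdges(net), directed = FALSE)
  expect_setequal(skel, c("A-B", "B-C"))
  expect_true("A>B" %in% edgeKeys(networkEdges(net)))
})

test_that("independent genes yield an empty graph and output stays acyclic", {
  empties <- vapply(1:5, function(s) {
    lay <- simulateCausalLayer(simulationConfig(dagNNodes = 6,
                                                dagEdgeProb = 0,
                                                dagNSamples = 300, seed = s))
    disc <- discretizeExpression(lay$expr, seed = s)
    net <- learnStructure(disc, structurePrior(), nRestarts = 3, seed = s)
    nrow(networkEdges(net)) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.8)

  set.seed(16)
  for (s in 1:5) {
    disc <- matrix(sample(0:2, 6 * 60, replace = TRUE), 6, 60,
                   dimnames = list(paste0("n", 1:6), NULL))
    net <- learnStructure(disc, structurePrior(), nRestarts = 2, seed = s)
    g <- igraph::graph_from_edgelist(networkEdges(net))
    if (nrow(networkEdges(net))) expect_true(igraph::is_dag(g))
  }
})

test_that("raising the orientation odds never loses eQTL out-edges", {
  cfg <- simulationConfig(dagNNodes = 6, dagEdgeProb = 0.4,
                          dagNSamples = 300, seed = 17)
  lay <- simulateCausalLayer(cfg)
  disc <- discretizeExpression(lay$expr, seed = 18)
  eq <- rownames(disc)[1:2]
  outEdges <- vapply(c(1, 10, 100), function(odds) {
    net <- learnStructure(disc, structurePrior(eq, orientationOdds = odds),
                          nRestarts = 3, seed = 19)
    e <- networkEdges(net)
    sum(e[, 1] %in% eq)
  }, numeric(1))
  expect_true(all(diff(outEdges) >= 0))
})

test_that("structure learning is seed-deterministic", {
  lay <- simulateCausalLayer(simulationConfig(dagNNodes = 7,
                                              dagNSamples = 250, seed = 20))
  disc <- discretizeExpression(lay$expr, seed = 21)
  n1 <- learnStructure(disc, structurePrior(), nRestarts = 5, seed = 22)
  n2 <- learnStructure(disc, structurePrior(), nRestarts = 5, seed = 22)
  expect_identical(networkEdges(n1), networkEdges(n2))
})
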