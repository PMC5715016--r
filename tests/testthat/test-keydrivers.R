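# Hub fixture: HUB drives 20 target leaves; a decoy drives 20 non-targets;
# one bridge edge keeps everything weakly connected so the KDA background
# contains non-targets.
hubNetwork <- function() {
  targets <- sprintf("T%02d", 1:20)
  decoys <- sprintf("N%02d", 1:20)
  edges <- rbind(cbind("HUB", targets), cbind("DEC", decoys),
                 c("T01", "N01"))
  list(net = geneNetwork(edges), targets = targets)
}

test_that("target projection follows the path-length-one rule", {
  chain <- geneNetwork(cbind(c("A", "B", "C"), c("B", "C", "D")))
  sub <- projectTargets(chain, "A")
  expect_setequal(networkNodes(sub), c("A", "B"))

  # two disjoint components with targets: the larger one is returned
  twoComp <- geneNetwork(rbind(
    cbind(c("a1", "a2", "a3", "a4"), c("a2", "a3", "a4", "a5")),
    cbind(c("b1", "b2"), c("b2", "b3"))))
  sub2 <- projectTargets(twoComp, c("a1", "a2", "a3", "b1"))
  expect_setequal(networkNodes(sub2), paste0("a", 1:4))

  # all nodes targets: the largest weakly connected component
  sub3 <- projectTargets(twoComp, networkNodes(twoComp))
  expect_setequal(networkNodes(sub3), paste0("a", 1:5))

  expect_error(projectTargets(chain, "ZZZ"), "no target genes")
})

test_that("KDA finds a planted hub and never rewards childless nodes", {
  hb <- hubNetwork()
  kda <- keyDriverAnalysis(hb$net, hb$targets, K = 7)
  expect_identical(kda$gene[1], "HUB")
  expect_true(kda$isKeyDriver[1])
  expect_identical(kda$bestK[1], 1L)
  # drivers all lie inside the background subnetwork
  expect_true(all(kda$gene %in% networkNodes(hb$net)))
  # a node with no descendants has overlap 0 and p = 1
  leaf <- kda[kda$gene == "T05", ]
  expect_identical(leaf$fisherP, 1)
  expect_false(leaf$isKeyDriver)
  expect_error(keyDriverAnalysis(hb$net, hb$targets, K = 0), "K must be")
})

test_that("KDA p-values equal brute-force descendant enumeration", {
  set.seed(1)
  nodes <- sprintf("V%02d", 1:12)
  edges <- do.call(rbind, lapply(1:11, function(i) {
    to <- nodes[(i + 1):12][runif(12 - i) < 0.25]
    if (length(to)) cbind(nodes[i], to)
  }))
  net <- geneNetwork(edges, nodes = nodes)
  targets <- sample(nodes, 5)
  K <- 3
  kda <- keyDriverAnalysis(net, targets, K = K)
  g <- challengeomics:::asIgraph(net)
  bg <- unique(unlist(lapply(
    igraph::ego(g, order = K, nodes = intersect(targets, nodes),
                mode = "all"), names)))
  for (h in kda$gene) {
    uniH <- setdiff(bg, h)
    targH <- intersect(targets, uniH)
    pk <- vapply(1:K, function(k) {
      down <- intersect(bruteDescendants(networkEdges(net), h, k), uniH)
      if (!length(down)) return(1)
      bruteFisherGreater(length(intersect(down, targH)), length(down),
                         length(targH), length(uniH))
    }, numeric(1))
    expect_equal(kda$fisherP[kda$gene == h], min(pk), tolerance = 1e-9)
  }
})

test_that("KDA is equivariant under node relabeling", {
  hb <- hubNetwork()
  map <- setNames(sprintf("X%02d", seq_along(networkNodes(hb$net))),
                  sort(networkNodes(hb$net)))
  e <- networkEdges(hb$net)
  relab <- geneNetwork(cbind(map[e[, 1]], map[e[, 2]]))
  kda1 <- keyDriverAnalysis(hb$net, hb$targets)
  kda2 <- keyDriverAnalysis(relab, unname(map[hb$targets]))
  expect_identical(unname(map[kda1$gene]), kda2$gene)
  expect_equal(kda1$fisherP, kda2$fisherP)
})

test_that("path levels are longest directed paths to a sink", {
  chain <- geneNetwork(cbind(c("A", "B"), c("B", "C")))
  expect_identical(assignLevels(chain), c(A = 2L, B = 1L, C = 0L))

  diamond <- geneNetwork(cbind(c("A", "A", "B", "C"), c("B", "C", "D", "D")))
  expect_identical(assignLevels(diamond)[c("A", "B", "C", "D")],
                   c(A = 2L, B = 1L, C = 1L, D = 0L))

  # adding an edge from a former sink raises its level, lowers nobody's
  lev1 <- assignLevels(chain)
  chain2 <- geneNetwork(cbind(c("A", "B", "C"), c("B", "C", "E")))
  lev2 <- assignLevels(chain2)
  expect_gte(lev2["C"], 1L)
  expect_true(all(lev2[names(lev1)] >= lev1))

  cyc <- geneNetwork(cbind(c("A", "B", "C"), c("B", "C", "A")))
  expect_warning(levC <- assignLevels(cyc), "cycles")
  expect_length(levC, 3)
})

test_that("level enrichment peaks at the top level when drivers sit there", {
  # drivers exactly the top level of a two-tier cascade
  e <- rbind(cbind(c("R1", "R2"), c("M1", "M2")),
             cbind(c("M1", "M1", "M2", "M2"), c("S1", "S2", "S3", "S4")))
  net <- geneNetwork(e)
  lev <- assignLevels(net)
  le <- levelEnrichment(lev, c("R1", "R2"))
  expect_equal(le$level[1], max(lev))
  expect_equal(le$or[1], max(le$or))
  # OR formula ad/bc when all cells positive
  res <- overlapOddsRatio(3, 10, 4, 20)
  expect_equal(res$or, (3 / 7) / (4 / 16))
})

test_that("uniformly scattered drivers show no level enrichment", {
  set.seed(2)
  nodes <- sprintf("V%02d", 1:40)
  edges <- do.call(rbind, lapply(1:39, function(i) {
    to <- nodes[(i + 1):40][runif(40 - i) < 0.08]
    if (length(to)) cbind(nodes[i], to)
  }))
  net <- geneNetwork(edges, nodes = nodes)
  lev <- assignLevels(net)
  ors <- replicate(20, {
    drv <- sample(nodes, 8)
    le <- levelEnrichment(lev, drv)
    stats::median(le$or)
  })
  expect_gt(median(ors), 0.3)
  expect_lt(median(ors), 3)
})

test_that("driver-set comparison degenerates gracefully", {
  uni <- sprintf("G%02d", 1:20)
  idFit <- compareDriverSets(uni[1:5], uni[1:5], uni)
  expect_true(is.finite(idFit$or))
  expect_gt(idFit$or, 50)          # Haldane-corrected but extreme

  dis <- compareDriverSets(uni[1:4], uni[5:8], uni)
  expect_lt(dis$or, 1)

  set.seed(3)
  for (i in 1:10) {
    a <- sample(uni, 6)
    b <- sample(uni, 7)
    res <- compareDriverSets(a, b, uni)
    k <- length(intersect(a, b))
    expect_equal(res$p, bruteFisherTwoSided(k, length(b), length(a), 20),
                 tolerance = 1e-9)
  }
  expect_error(compareDriverSets("a", "b", character()), "non-empty")
})
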