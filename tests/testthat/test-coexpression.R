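test_that("power adjacency matches its elementwise definition", {
  set.seed(1)
  x <- matrix(rnorm(6 * 40), 6, 40, dimnames = list(paste0("g", 1:6), NULL))
  A <- adjacencyMatrix(x, beta = 6)
  cc <- cor(t(x))
  for (i in 1:6) for (j in 1:6)
    expect_equal(A[i, j], if (i == j) 1 else abs(cc[i, j])^6, tolerance = 1e-12)

  # beta = 1 is the identity power; anticorrelation saturates unsigned
  A1 <- adjacencyMatrix(x, beta = 1)
  expect_equal(A1[1, 2], abs(cc[1, 2]))
  y <- rbind(a = rnorm(30))
  y <- rbind(y, b = -y["a", ])
  expect_equal(adjacencyMatrix(y, 6)["a", "b"], 1)

  # arithmetic: correlation 0.5 at beta 6
  expect_equal(abs(0.5)^6, 0.015625)
})

test_that("zero-variance genes get zero adjacency with a message", {
  x <- rbind(g1 = rnorm(20), g2 = rep(3, 20), g3 = rnorm(20))
  expect_message(A <- adjacencyMatrix(x, 2), "zero-variance")
  expect_equal(A["g2", "g1"], 0)
  expect_equal(A["g2", "g2"], 1)
})

test_that("topological overlap matches the brute-force definition", {
  # two isolated genes with a = 0.5: TOM = 0.5 / (0.5 + 1 - 0.5) = 0.5
  A2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(topologicalOverlap(A2)[1, 2], 0.5)

  # complete graph with all a = 1: all TOM = 1
  A1 <- matrix(1, 4, 4)
  expect_true(all(topologicalOverlap(A1) == 1))

  set.seed(2)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    A <- matrix(runif(n * n, 0, 0.9), n, n)
    A <- (A + t(A)) / 2
    diag(A) <- 1
    tom <- topologicalOverlap(A)
    expect_lt(max(abs(tom - bruteTom(A))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }
})

test_that("the soft-threshold scan reaches scale-free fit on modular data", {
  set.seed(3)
  n <- 150
  # hub topology: power-law factor loadings give a broad, heavy-tailed
  # connectivity distribution
  f <- rnorm(n)
  loadings <- 0.95 * (1:100)^(-0.25)
  expr <- t(sapply(loadings, function(l)
    l * f + sqrt(max(0, 1 - l^2)) * rnorm(n)))
  rownames(expr) <- sprintf("g%03d", seq_len(nrow(expr)))
  scan <- softThresholdScan(expr, betas = 1:12)
  expect_gte(max(scan$table$rsq, na.rm = TRUE), 0.8)
  expect_true(scan$chosenBeta %in% 1:12)
  # connectivity strictly decreases with beta when all |cor| < 1
  expect_true(all(diff(scan$table$meanConnectivity) < 0))
})

test_that("module detection recovers planted blocks and spares noise", {
  set.seed(4)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  expr <- rbind(
    t(sapply(1:50, function(i) sqrt(0.8) * f1 + sqrt(0.2) * rnorm(n))),
    t(sapply(1:50, function(i) sqrt(0.8) * f2 + sqrt(0.2) * rnorm(n))))
  rownames(expr) <- sprintf("g%03d", 1:100)
  tom <- topologicalOverlap(adjacencyMatrix(expr, 6))
  part <- detectModules(tom, minSize = 30)
  truth <- rep(1:2, each = 50)
  # modules must match the planted blocks up to label swap
  agree <- max(mean(part == truth[match(names(part), rownames(expr))]),
               mean(part == (3 - truth)[match(names(part), rownames(expr))]))
  expect_gte(agree, 0.95)
  expect_equal(length(unique(part[part > 0])), 2)

  # i.i.d. noise: everything unassigned at defaults
  noise <- matrix(rnorm(80 * n), 80, n,
                  dimnames = list(sprintf("n%02d", 1:80), NULL))
  part0 <- detectModules(topologicalOverlap(adjacencyMatrix(noise, 6)))
  expect_true(all(part0 == 0))
})

test_that("module labels are invariant to gene input order", {
  set.seed(5)
  n <- 50
  f1 <- rnorm(n)
  expr <- rbind(
    t(sapply(1:40, function(i) sqrt(0.7) * f1 + sqrt(0.3) * rnorm(n))),
    matrix(rnorm(20 * n), 20, n))
  rownames(expr) <- sprintf("g%03d", 1:60)
  tom <- topologicalOverlap(adjacencyMatrix(expr, 6))
  part <- detectModules(tom, minSize = 20)
  perm <- sample(60)
  part2 <- detectModules(tom[perm, perm], minSize = 20)
  expect_identical(part, part2[names(part)])
})

test_that("module enrichment reproduces fold and Fisher arithmetic", {
  # exact proportional case: fold 1
  even <- moduleEnrichmentCounts(5, 50, 20, 200)
  expect_equal(even$fold, 1)

  # enrichment fold is scale-free in the universe
  a <- moduleEnrichmentCounts(30, 60, 100, 1000)
  b <- moduleEnrichmentCounts(30, 60, 200, 2000)
  expect_equal(a$fold, b$fold)

  # one-sided Fisher equals the exhaustive hypergeometric tail
  set.seed(6)
  for (i in 1:20) {
    N <- sample(8:20, 1)
    n <- sample(2:(N - 2), 1)
    K <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(moduleEnrichmentCounts(k, n, K, N)$fisherP,
                 bruteFisherGreater(k, n, K, N), tolerance = 1e-9)
  }

  expect_error(moduleEnrichment(character(), "G1", c("G1", "G2")), "non-empty")
})

test_that("the enrichment table ranks the response module first", {
  part <- setNames(rep(c(1, 2, 0), times = c(40, 40, 20)),
                   sprintf("g%03d", 1:100))
  target <- names(part)[c(1:30, 81:85)]   # concentrated in module 1
  tab <- moduleEnrichmentTable(part, target)
  expect_equal(tab$module[1], 1)
  expect_gt(tab$fold[1], 1)
  expect_equal(tab$N[1], 100)
  expect_equal(tab$fold, (tab$k / tab$n) / (tab$K / tab$N))
})
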