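# Shared fixtures and independent oracles for the test suite.
# Expensive fixtures are built once per run and cached in this environment.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, builder) {
  got <- .fixtureCache[[key]]
  if (is.null(got)) {
    got <- builder()
    .fixtureCache[[key]] <- got
  }
  got
}

# Marker-block leukocyte-like signature: each cell type over-expresses its
# own stripe of genes.
makeSignature <- function(nGenes = 120, nTypes = 5, seed = 9) {
  set.seed(seed)
  sig <- matrix(rexp(nGenes * nTypes, 1 / 20), nGenes, nTypes,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                paste0("ct", seq_len(nTypes))))
  stripe <- split(seq_len(nGenes), rep(seq_len(nTypes), length.out = nGenes))
  for (t in seq_len(nTypes)) sig[stripe[[t]], t] <- sig[stripe[[t]], t] + 150
  sig
}

# Small normalized crossover study with planted interaction genes.
smallStudy <- function() {
  cachedFixture("smallStudy", function() {
    sim <- simulateChallengeDataset(simulationConfig(
      nSubjects = 6, nGenes = 60, deltaT4 = 2, fracInteractionGenes = 0.2,
      nModules = 0, seed = 17))
    ce <- suppressMessages(normalizeChallenge(
      ChallengeExperiment(sim$counts, sim$design)))
    list(ce = ce, truth = sim$truth, sim = sim)
  })
}

# ---- independent oracles --------------------------------------------------

# Triple-loop topological overlap, straight from the definition.
bruteTom <- function(A) {
  n <- nrow(A)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, -i])
    kj <- sum(A[j, -j])
    tom[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  dimnames(tom) <- dimnames(A)
  tom
}

# Exhaustive hypergeometric tail for a 2x2 table (one-sided, enrichment).
bruteFisherGreater <- function(k, n, K, N) {
  kk <- max(0, n + K - N):min(n, K)
  probs <- exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n))
  sum(probs[kk >= k])
}

# Exhaustive two-sided Fisher p: sum of table probabilities <= observed.
bruteFisherTwoSided <- function(k, n, K, N) {
  kk <- max(0, n + K - N):min(n, K)
  probs <- exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n))
  pObs <- probs[kk == k]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the literal step-up definition.
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Directed descendants of node h within k steps, by explicit breadth-first
# expansion over the edge list.
bruteDescendants <- function(edges, h, k) {
  frontier <- h
  seen <- character()
  for (step in seq_len(k)) {
    nxt <- unique(edges[edges[, 1] %in% frontier, 2])
    nxt <- setdiff(nxt, c(seen, h))
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# BDeu family score by direct counting over explicit parent configurations.
bruteBdeu <- function(child, parents = NULL, ess = 1) {
  r <- max(child) + 1
  if (is.null(parents) || NROW(parents) == 0) {
    cfgs <- rep(1, length(child))
    q <- 1
  } else {
    parents <- matrix(parents, ncol = length(child))
    states <- apply(parents, 1, max) + 1
    q <- prod(states)
    cfgs <- apply(parents, 2, paste, collapse = "|")
  }
  total <- 0
  for (cf in unique(cfgs)) {
    idx <- cfgs == cf
    nj <- sum(idx)
    total <- total + lgamma(ess / q) - lgamma(ess / q + nj)
    for (s in 0:(r - 1)) {
      njk <- sum(child[idx] == s)
      total <- total + lgamma(ess / (q * r) + njk) - lgamma(ess / (q * r))
    }
  }
  total
}

# All DAGs on 3 labelled nodes (25 of them), as edge matrices.
allThreeNodeDags <- function(nodes) {
  pairs <- t(combn(nodes, 2))
  pairs <- rbind(pairs, pairs[, 2:1])     # 6 possible directed edges
  dags <- list()
  for (mask in 0:(2^6 - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:5)) > 0)
    edges <- pairs[sel, , drop = FALSE]
    if (anyDuplicated(t(apply(edges, 1, sort))) > 0) next  # 2-cycles
    g <- igraph::graph_from_data_frame(
      as.data.frame(edges, stringsAsFactors = FALSE), directed = TRUE,
      vertices = nodes)
    if (igraph::is_dag(g)) dags[[length(dags) + 1]] <- edges
  }
  dags
}

# Independent TMM implementation following the published trimming rule
# (reference by 75th-percentile cpm, 30%/5% trims, precision weighting).
bruteTmm <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    obs <- counts[, i]; rf <- counts[, ref]
    nO <- lib[i]; nR <- lib[ref]
    logR <- log2((obs / nO) / (rf / nR))
    absE <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
    fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Random DAG with in-degree capped at the learner's parent bound, so the
# planted graph lies inside the searchable model class.
cappedDag <- function(seed, n = 10, p = 0.2, cap = 3) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  topo <- sample(nodes)
  e <- matrix(character(), 0, 2)
  for (j in 2:n) {
    pa <- topo[1:(j - 1)][runif(j - 1) < p]
    if (length(pa) > cap) pa <- sample(pa, cap)
    if (length(pa)) e <- rbind(e, cbind(pa, topo[j]))
  }
  e
}

# Edge sets as canonical strings, for skeleton/edge comparisons.
edgeKeys <- function(edges, directed = TRUE) {
  if (!NROW(edges)) return(character())
  if (directed) paste(edges[, 1], edges[, 2], sep = ">")
  else unique(apply(edges, 1, function(e) paste(sort(e), collapse = "-")))
}
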