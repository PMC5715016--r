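#' Select the most variable genes
#'
#' Ranks genes by variance of (normalized) expression and returns the top
#' `ceiling(frac * nGenes)`; ties are broken by lexicographic gene symbol so
#' the selection is deterministic.
#'
#' @param expr Expression matrix, genes x samples, rownames = symbols.
#' @param frac Fraction to keep (default 0.25, the causal-network input
#'   convention).
#' @return Character vector of selected gene symbols.
#' @export
selectTopVarianceGenes <- function(expr, frac = 0.25) {
  assertScalar(frac, "frac", 1e-12, 1)
  expr <- as.matrix(expr)
  v <- apply(expr, 1, stats::var)
  ord <- order(-v, rownames(expr))
  rownames(expr)[ord][seq_len(minCount(frac, nrow(expr)))]
}

#' Discretize one gene's expression into ordered states by k-means
#'
#' Values are standardized, clustered with `k` centers (seeded multi-start,
#' 10 restarts), then groups without enough support are collapsed: clusters
#' with fewer than `minCluster` members are dropped and their points
#' reassigned to the nearest surviving center, and clusters whose centers
#' lie closer than `mergeGap` (on the standardized scale) are merged, since
#' they describe the same expression regime — this is what collapses a
#' bimodal gene to two states (high and low) while genuinely trimodal or
#' continuous unimodal genes keep three. Surviving clusters are relabeled
#' `0..m-1` in increasing center order so states are comparable across
#' genes.
#'
#' @param values Numeric vector (one gene across samples).
#' @param k Number of clusters (default 3).
#' @param seed Integer seed for the k-means restarts.
#' @param minCluster Minimum cluster occupancy (default 2).
#' @param mergeGap Minimum separation of standardized cluster centers
#'   (default 0.5).
#' @return Integer vector of states, contiguous from 0.
#' @export
discretizeKmeans <- function(values, k = 3, seed = 1, minCluster = 2,
                             mergeGap = 0.5) {
  x <- as.numeric(values)
  ux <- unique(x)
  if (length(ux) < 2) return(rep(0L, length(x)))
  x <- (x - mean(x)) / stats::sd(x)
  kk <- min(k, length(unique(x)))
  set.seed(deriveSeed(seed, "kmeans"))
  km <- suppressWarnings(stats::kmeans(x, centers = kk, nstart = 10))
  centers <- as.numeric(km$centers)
  assign <- km$cluster
  keep <- which(tabulate(assign, nbins = kk) >= minCluster)
  if (!length(keep)) keep <- which.max(tabulate(assign, nbins = kk))
  if (length(keep) < kk) {
    reassign <- !(assign %in% keep)
    assign[reassign] <- keep[apply(abs(outer(x[reassign], centers[keep], "-")),
                                   1, which.min)]
  }
  # merge centers closer than mergeGap: same expression regime
  repeat {
    keep <- keep[order(centers[keep])]
    if (length(keep) < 2) break
    gaps <- diff(centers[keep])
    if (min(gaps) >= mergeGap) break
    i <- which.min(gaps)
    a <- keep[i]; b <- keep[i + 1]
    na <- sum(assign == a); nb <- sum(assign == b)
    centers[a] <- (centers[a] * na + centers[b] * nb) / (na + nb)
    assign[assign == b] <- a
    keep <- setdiff(keep, b)
  }
  ordKeep <- keep[order(centers[keep])]
  match(assign, ordKeep) - 1L
}

#' Discretize an expression matrix gene-wise
#'
#' @param expr Expression matrix, genes x samples.
#' @param k,minCluster Passed to [discretizeKmeans()].
#' @param seed Master seed; each gene gets a derived stream.
#' @return Integer state matrix of the same shape (states per gene contiguous
#'   from 0).
#' @export
discretizeExpression <- function(expr, k = 3, seed = 1, minCluster = 2) {
  expr <- as.matrix(expr)
  out <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (g in seq_len(nrow(expr)))
    out[g, ] <- discretizeKmeans(expr[g, ], k = k,
                                 seed = deriveSeed(seed, rownames(expr)[g]),
                                 minCluster = minCluster)
  out
}

#' Structure prior with eQTL orientation odds
#'
#' Soft prior for network orientation: each edge `u -> v` multiplies the
#' structure prior by `orientationOdds` when `u` is an eQTL-anchored gene
#' (genotype cannot be the effect of expression, so such genes prefer the
#' parent role) and by `1 / orientationOdds` when `v` is one.
#'
#' @param eqtlGenes Character vector of eQTL-anchored gene symbols.
#' @param orientationOdds Prior odds (>= 1, default 10).
#' @param maxParents Parent-set cap for the search (default 3).
#' @return A list of class `"StructurePrior"`.
#' @export
structurePrior <- function(eqtlGenes = character(), orientationOdds = 10,
                           maxParents = 3) {
  assertScalar(orientationOdds, "orientationOdds", 1)
  assertScalar(maxParents, "maxParents", 1)
  structure(list(eqtlGenes = unique(as.character(eqtlGenes)),
                 orientationOdds = orientationOdds,
                 maxParents = as.integer(maxParents)),
            class = "StructurePrior")
}

#' BDeu family score
#'
#' Bayesian-Dirichlet equivalent uniform log marginal likelihood of one
#' node's conditional distribution given its parent set, with equivalent
#' sample size `ess`. The total network score is the sum of family scores
#' (decomposability).
#'
#' @param child Integer state vector of the child node (states `0..r-1`).
#' @param parents Integer state matrix (parents x samples) or `NULL`.
#' @param nStates Named or positional integer vector of state counts; child's
#'   first, parents' after. If `NULL`, counts are inferred as `max + 1`.
#' @param ess Equivalent sample size (default 1).
#' @return Log score (a single number).
#' @export
bdeuFamilyScore <- function(child, parents = NULL, nStates = NULL, ess = 1) {
  child <- as.integer(child)
  r <- if (is.null(nStates)) max(child) + 1L else nStates[1]
  r <- max(r, 1L)
  if (is.null(parents) || NROW(parents) == 0) {
    q <- 1L
    cfg <- rep(1L, length(child))
  } else {
    parents <- matrix(as.integer(parents), ncol = length(child))
    rp <- if (is.null(nStates)) apply(parents, 1, max) + 1L
          else nStates[-1]
    rp <- pmax(rp, 1L)
    q <- prod(rp)
    mult <- cumprod(c(1, rp[-length(rp)]))
    cfg <- as.integer(colSums(parents * mult)) + 1L
  }
  aj <- ess / q
  ajk <- ess / (q * r)
  counts <- table(cfg, factor(child, levels = 0:(r - 1)))
  nj <- rowSums(counts)
  sum(lgamma(aj) - lgamma(aj + nj)) +
    sum(lgamma(ajk + counts) - lgamma(ajk))
}

# Internal: log structure-prior contribution of one directed edge.
edgeLogPrior <- function(u, v, prior) {
  lp <- 0
  lo <- log(prior$orientationOdds)
  if (u %in% prior$eqtlGenes) lp <- lp + lo
  if (v %in% prior$eqtlGenes) lp <- lp - lo
  lp
}

#' Learn a causal DAG by scored hill climbing
#'
#' Greedy hill climbing over add / delete / reverse moves maximizing the
#' BDeu network score (equivalent sample size 1) plus the log structure
#' prior from [structurePrior()]. Parent sets are capped at
#' `prior$maxParents`; acyclicity is enforced at every move; the best of
#' `nRestarts` seeded restarts (restart 1 starts empty, later restarts from
#' random sparse DAGs) is returned. Seed-deterministic.
#'
#' @param disc Integer state matrix from [discretizeExpression()], genes x
#'   samples.
#' @param prior A [structurePrior()].
#' @param nRestarts Number of restarts (default 20).
#' @param seed Integer seed.
#' @param ess BDeu equivalent sample size (default 1).
#' @return A [GeneNetwork-class] DAG; its `metadata`-like attribute `score`
#'   holds the achieved log score.
#' @export
learnStructure <- function(disc, prior = structurePrior(), nRestarts = 20,
                           seed = 1, ess = 1) {
  disc <- as.matrix(disc)
  nodes <- rownames(disc)
  if (is.null(nodes)) nodes <- paste0("g", seq_len(nrow(disc)))
  n <- length(nodes)
  nStates <- pmax(apply(disc, 1, max) + 1L, 1L)
  meanOcc <- ncol(disc) / mean(nStates)
  if (meanOcc < 3)
    warning("fewer than 3 samples per state on average; scores are unstable")

  cache <- new.env(parent = emptyenv(), hash = TRUE)
  famScore <- function(v, pa) {
    key <- paste(v, paste(sort(pa), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- bdeuFamilyScore(disc[v, ],
                           if (length(pa)) disc[pa, , drop = FALSE] else NULL,
                           nStates = c(nStates[v], nStates[pa]), ess = ess)
    cache[[key]] <- val
    val
  }

  hasPath <- function(adj, from, to) {   # DFS: does a directed path exist?
    seen <- stats::setNames(logical(n), nodes)
    stack <- from
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (v == to) return(TRUE)
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, nodes[adj[v, ]])
    }
    FALSE
  }

  runClimb <- function(adj) {
    parents <- lapply(stats::setNames(nodes, nodes),
                      function(v) nodes[adj[, v]])
    fam <- vapply(nodes, function(v) famScore(v, parents[[v]]), numeric(1))
    lprior <- 0
    for (u in nodes) for (v in nodes[adj[u, ]])
      lprior <- lprior + edgeLogPrior(u, v, prior)
    repeat {
      bestDelta <- 1e-9
      bestMove <- NULL
      for (u in nodes) for (v in nodes) {
        if (u == v) next
        if (!adj[u, v]) {
          if (adj[v, u]) next
          if (length(parents[[v]]) >= prior$maxParents) next
          if (hasPath(adj, v, u)) next
          delta <- famScore(v, c(parents[[v]], u)) - fam[v] +
            edgeLogPrior(u, v, prior)
          if (delta > bestDelta) {
            bestDelta <- delta
            bestMove <- list(type = "add", u = u, v = v)
          }
        } else {
          # delete u -> v
          delta <- famScore(v, setdiff(parents[[v]], u)) - fam[v] -
            edgeLogPrior(u, v, prior)
          if (delta > bestDelta) {
            bestDelta <- delta
            bestMove <- list(type = "del", u = u, v = v)
          }
          # reverse u -> v
          if (length(parents[[u]]) < prior$maxParents) {
            adj[u, v] <- FALSE
            ok <- !hasPath(adj, u, v)
            adj[u, v] <- TRUE
            if (ok) {
              delta <- (famScore(v, setdiff(parents[[v]], u)) - fam[v]) +
                (famScore(u, c(parents[[u]], v)) - fam[u]) -
                edgeLogPrior(u, v, prior) + edgeLogPrior(v, u, prior)
              if (delta > bestDelta) {
                bestDelta <- delta
                bestMove <- list(type = "rev", u = u, v = v)
              }
            }
          }
        }
      }
      if (is.null(bestMove)) break
      u <- bestMove$u; v <- bestMove$v
      if (bestMove$type == "add") {
        adj[u, v] <- TRUE
        parents[[v]] <- c(parents[[v]], u)
        fam[v] <- famScore(v, parents[[v]])
        lprior <- lprior + edgeLogPrior(u, v, prior)
      } else if (bestMove$type == "del") {
        adj[u, v] <- FALSE
        parents[[v]] <- setdiff(parents[[v]], u)
        fam[v] <- famScore(v, parents[[v]])
        lprior <- lprior - edgeLogPrior(u, v, prior)
      } else {
        adj[u, v] <- FALSE
        adj[v, u] <- TRUE
        parents[[v]] <- setdiff(parents[[v]], u)
        parents[[u]] <- c(parents[[u]], v)
        fam[v] <- famScore(v, parents[[v]])
        fam[u] <- famScore(u, parents[[u]])
        lprior <- lprior - edgeLogPrior(u, v, prior) + edgeLogPrior(v, u, prior)
      }
    }
    list(adj = adj, score = sum(fam) + lprior)
  }

  empty <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  best <- runClimb(empty)
  if (nRestarts > 1) {
    set.seed(deriveSeed(seed, "hc-restarts"))
    for (r in seq_len(nRestarts - 1)) {
      adj <- empty
      perm <- sample(nodes)
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        if (stats::runif(1) < 0.15 &&
            sum(adj[, perm[j]]) < prior$maxParents)
          adj[perm[i], perm[j]] <- TRUE
      }
      cand <- runClimb(adj)
      if (cand$score > best$score) best <- cand
    }
  }
  idx <- which(best$adj, arr.ind = TRUE)
  edges <- cbind(nodes[idx[, 1]], nodes[idx[, 2]])
  if (nrow(edges))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  net <- geneNetwork(edges, nodes = nodes)
  attr(net, "score") <- best$score
  net
}
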