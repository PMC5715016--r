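#' Remove collection-date effects by per-gene linear adjustment
#'
#' Residualizes each gene's expression on a collection-date factor so that
#' coexpression is not driven by batch-like date effects. Subject effects are
#' deliberately left in: the shared response signal across time points is
#' part of the coexpression structure of interest.
#'
#' @param log2cpm Expression matrix, genes x samples.
#' @param dates Per-sample collection-date labels.
#' @return Residual matrix of the same shape.
#' @export
residualizeDates <- function(log2cpm, dates) {
  log2cpm <- as.matrix(log2cpm)
  f <- factor(dates)
  if (nlevels(f) < 2) return(log2cpm - rowMeans(log2cpm))
  mm <- stats::model.matrix(~f)
  qrX <- qr(mm)
  t(qr.resid(qrX, t(log2cpm)))
}

#' Unsigned power adjacency from expression
#'
#' `a_ij = |cor(i, j)|^beta` (Pearson), `a_ii = 1`. Genes with zero variance
#' get zero off-diagonal adjacency, with a message. A signed variant
#' (`(0.5 + 0.5 * cor)^beta`) is available behind `signed = TRUE`.
#'
#' @param exprResiduals Expression matrix, genes x samples (residualized,
#'   see [residualizeDates()]).
#' @param beta Soft-threshold power (>= 1).
#' @param signed Use the signed adjacency transform?
#' @return Symmetric adjacency matrix in `[0, 1]`, unit diagonal.
#' @export
adjacencyMatrix <- function(exprResiduals, beta = 6, signed = FALSE) {
  stopifnot(beta >= 1)
  x <- as.matrix(exprResiduals)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    message(sum(sds == 0), " zero-variance gene(s); correlations set to 0")
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[!is.finite(cc)] <- 0
  A <- if (signed) (0.5 + 0.5 * cc)^beta else abs(cc)^beta
  diag(A) <- 1
  A
}

#' Scan soft-threshold powers for scale-free topology fit
#'
#' For each candidate power, builds the adjacency, computes the connectivity
#' distribution, and regresses `log10 p(k)` on `log10 k` over connectivity
#' bins; reports the fit R-squared, slope, and mean connectivity. The chosen
#' power is the smallest reaching `rsqCut` (default 0.8), else the argmax
#' R-squared; it can always be overridden (the pipeline default is 6).
#'
#' @param exprResiduals Expression matrix, genes x samples.
#' @param betas Candidate powers (default 1:20).
#' @param rsqCut Scale-free fit target (default 0.8).
#' @param nBins Connectivity histogram bins (default 10).
#' @param signed Signed adjacency?
#' @return List with `table` (`data.frame`: beta, rsq, slope,
#'   meanConnectivity) and `chosenBeta`.
#' @export
softThresholdScan <- function(exprResiduals, betas = 1:20, rsqCut = 0.8,
                              nBins = 10, signed = FALSE) {
  x <- as.matrix(exprResiduals)
  if (nrow(x) < 50)
    warning("fewer than 50 genes; scale-free fit statistics are unstable")
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[!is.finite(cc)] <- 0
  base <- if (signed) 0.5 + 0.5 * cc else abs(cc)
  diag(base) <- 0
  rows <- lapply(betas, function(b) {
    k <- rowSums(base^b)
    pos <- k > 0
    if (length(unique(k[pos])) < 3)
      return(data.frame(beta = b, rsq = NA_real_, slope = NA_real_,
                        meanConnectivity = mean(k)))
    # equal-width connectivity bins; frequency per bin approximates p(k)
    bin <- cut(k[pos], breaks = nBins, include.lowest = TRUE)
    dk <- tapply(k[pos], bin, mean)
    pk <- as.numeric(table(bin)) / sum(pos)
    ok <- is.finite(dk) & pk > 0
    fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    data.frame(beta = b, rsq = summary(fit)$r.squared,
               slope = stats::coef(fit)[2], meanConnectivity = mean(k))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  hit <- which(!is.na(tab$rsq) & tab$rsq >= rsqCut)
  chosen <- if (length(hit)) tab$beta[hit[1]]
            else tab$beta[which.max(tab$rsq)]
  list(table = tab, chosenBeta = chosen)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u != i, j`, connectivity `k_i = sum_{u != i} a_iu`, and
#' `TOM_ii = 1`. Output is symmetric with entries in `[0, 1]` for an
#' unsigned adjacency.
#'
#' @param A Symmetric adjacency matrix in `[0, 1]`.
#' @return TOM matrix of the same shape.
#' @export
topologicalOverlap <- function(A) {
  A <- as.matrix(A)
  A0 <- A
  diag(A0) <- 0
  L <- A0 %*% A0              # zero diagonal excludes u = i and u = j terms
  k <- rowSums(A0)
  kmin <- outer(k, k, pmin)
  tom <- (L + A0) / (kmin + 1 - A0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect coexpression modules by tree cutting of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on dissimilarity `1 - TOM`,
#' followed by a dynamic hybrid-style cut: a static cut at `cutHeight`
#' defines branches; branches of at least `minSize` genes become modules;
#' genes in smaller branches are merged into the module with the highest
#' mean topological overlap, provided that mean dissimilarity does not
#' exceed the cut height, and are otherwise left unassigned (label 0).
#' Surviving modules are relabeled by decreasing size (ties broken by the
#' lexicographically smallest member gene). Deterministic and invariant to
#' gene input order.
#'
#' @param tom TOM matrix with gene dimnames.
#' @param minSize Minimum module size (default 30).
#' @param cutHeight Static cut height on `1 - TOM` (default 0.99).
#' @param deepSplit Reserved sensitivity knob, retained for interface
#'   stability; currently only validated (default 2).
#' @return Named integer vector: gene -> module label (0 = unassigned).
#' @export
detectModules <- function(tom, minSize = 30, cutHeight = 0.99, deepSplit = 2) {
  stopifnot(deepSplit >= 0, cutHeight > 0, cutHeight <= 1)
  tom <- as.matrix(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  ord <- order(genes)                    # canonical order => order invariance
  tom <- tom[ord, ord]
  genes <- genes[ord]
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cutHeight)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= minSize])
  lab <- integer(length(genes))
  if (length(big)) {
    # mean TOM from every gene to each surviving branch
    memb <- lapply(big, function(b) which(cl == b))
    for (gi in seq_along(genes)) {
      if (cl[gi] %in% big) {
        lab[gi] <- match(cl[gi], big)
      } else {
        meanTom <- vapply(memb, function(ix) mean(tom[gi, ix]), numeric(1))
        bestB <- which.max(meanTom)
        if (1 - meanTom[bestB] <= cutHeight) lab[gi] <- bestB
      }
    }
    # relabel survivors by decreasing size; ties by smallest member symbol
    finalSizes <- tabulate(lab, nbins = length(big))
    firstGene <- vapply(seq_along(big), function(b) {
      ix <- which(lab == b)
      if (length(ix)) min(genes[ix]) else "\uFFFF"
    }, character(1))
    newOrder <- order(-finalSizes, firstGene)
    relab <- match(seq_along(big), newOrder)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  stats::setNames(lab, genes)
}

#' Gene-set enrichment of one module
#'
#' Fold enrichment `(k/n) / (K/N)` of a target gene set in a module, with a
#' one-sided (enrichment-direction) Fisher exact p-value. The target set is
#' intersected with the universe first.
#'
#' @param moduleGenes Character vector of module member genes (subset of
#'   `universe`).
#' @param target Character vector: the target gene set.
#' @param universe Character vector: all genes eligible for module detection.
#' @param alternative Fisher alternative (default `"greater"`).
#' @return List with `k` (overlap), `n` (module size), `K` (targets in
#'   universe), `N` (universe size), `fold`, `fisherP`.
#' @examples
#' # worked-example contingency: 1223 of 2381 module genes among 2168
#' # response genes in a 17328-gene universe -> 4.1-fold enrichment
#' moduleEnrichmentCounts(1223, 2381, 2168, 17328)$fold
#' @export
moduleEnrichment <- function(moduleGenes, target, universe,
                             alternative = "greater") {
  universe <- unique(universe)
  moduleGenes <- unique(moduleGenes)
  if (!length(moduleGenes) || !length(universe))
    stop("module and universe must be non-empty")
  if (!all(moduleGenes %in% universe))
    stop("module genes must be a subset of the universe")
  target <- intersect(unique(target), universe)
  moduleEnrichmentCounts(length(intersect(moduleGenes, target)),
                         length(moduleGenes), length(target), length(universe),
                         alternative)
}

#' @rdname moduleEnrichment
#' @param k,n,K,N Contingency counts: overlap, module size, target-in-universe
#'   size, universe size.
#' @export
moduleEnrichmentCounts <- function(k, n, K, N, alternative = "greater") {
  stopifnot(k >= 0, k <= n, n <= N, K <= N, k <= K)
  if (n == 0 || N == 0) stop("module and universe must be non-empty")
  fold <- if (K == 0) NA_real_ else (k / n) / (K / N)
  tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), nrow = 2)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(k = k, n = n, K = K, N = N, fold = fold, fisherP = p)
}

#' Enrichment of a target set across all modules of a partition
#'
#' @param partition Named integer vector from [detectModules()].
#' @param target Character vector: target gene set.
#' @param universe Universe; defaults to all genes in the partition.
#' @return `data.frame` (one row per non-zero module label): `module`, `k`,
#'   `n`, `K`, `N`, `fold`, `fisherP`, `fdr` (BH across modules), sorted by
#'   decreasing fold.
#' @export
moduleEnrichmentTable <- function(partition, target,
                                  universe = names(partition)) {
  labs <- sort(unique(partition[partition > 0]))
  if (!length(labs))
    return(data.frame(module = integer(), k = integer(), n = integer(),
                      K = integer(), N = integer(), fold = numeric(),
                      fisherP = numeric(), fdr = numeric()))
  rows <- lapply(labs, function(m) {
    e <- moduleEnrichment(names(partition)[partition == m], target, universe)
    data.frame(module = m, k = e$k, n = e$n, K = e$K, N = e$N, fold = e$fold,
               fisherP = e$fisherP)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$fisherP, method = "BH")
  out[order(-out$fold), , drop = FALSE]
}
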