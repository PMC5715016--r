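#' Low-expression filter rule
#'
#' A gene is kept iff its counts-per-million exceed `cpmThreshold` (strictly)
#' in at least `ceiling(minSampleFrac * nSamples)` samples. The defaults
#' (cpm > 0.1 in at least 10% of samples) reproduce the standard whole-blood
#' RNA-seq preprocessing contract for this design.
#'
#' @param cpmThreshold Strictly-exceeded cpm threshold (default 0.1).
#' @param minSampleFrac Required fraction of samples (default 0.10).
#' @return A list of class `"FilterRule"`.
#' @export
filterRule <- function(cpmThreshold = 0.1, minSampleFrac = 0.10) {
  assertScalar(cpmThreshold, "cpmThreshold", 1e-12)
  assertScalar(minSampleFrac, "minSampleFrac", 1e-12, 1)
  structure(list(cpmThreshold = cpmThreshold, minSampleFrac = minSampleFrac),
            class = "FilterRule")
}

#' Convert counts to counts-per-million
#'
#' `cpm[g, s] = counts[g, s] / libSizes[s] * 1e6`. When `libSizes` are the
#' column totals (the default), each column of the result sums to 1e6.
#'
#' @param counts Count matrix, genes x samples.
#' @param libSizes Per-sample library sizes; default `colSums(counts)`.
#' @return Numeric cpm matrix of the same shape.
#' @export
computeCpm <- function(counts, libSizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(libSizes) != ncol(counts))
    stop("one library size per sample is required")
  zero <- libSizes <= 0
  if (any(zero)) {
    nm <- colnames(counts)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("zero library size for sample(s): ", paste(nm, collapse = ", "))
  }
  sweep(counts, 2, libSizes, "/") * 1e6
}

#' Mask genes with systematically low expression
#'
#' @param cpm Numeric cpm matrix, genes x samples.
#' @param rule A [filterRule()].
#' @return Logical vector (in gene order): `TRUE` = keep. Applying the filter
#'   to an already-filtered matrix changes nothing (idempotence).
#' @export
filterLowExpression <- function(cpm, rule = filterRule()) {
  stopifnot(inherits(rule, "FilterRule"))
  need <- minCount(rule$minSampleFrac, ncol(cpm))
  keep <- rowSums(cpm > rule$cpmThreshold) >= need
  stats::setNames(keep, rownames(cpm))
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Composition normalization factors computed by edgeR's TMM method: the
#' reference sample is the one whose 75th-percentile cpm is closest to the
#' mean of those quantiles; per sample, a precision-weighted mean of log2
#' expression ratios is taken after trimming 30% of M-values and 5% of
#' A-values; factors are rescaled to geometric mean 1.
#'
#' @param counts Count matrix, genes x samples (>= 1 sample).
#' @return Named numeric vector of normalization factors.
#' @export
tmmFactors <- function(counts) {
  counts <- as.matrix(counts)
  zero <- colSums(counts) == 0
  if (any(zero)) {
    nm <- colnames(counts)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("all-zero sample(s): ", paste(nm, collapse = ", "))
  }
  if (ncol(counts) == 1L)
    return(stats::setNames(1, colnames(counts)))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Precision-weighted log2-cpm transform
#'
#' Computes `log2cpm[g, s] = log2((count + 0.5) / (libSize * factor + 1) * 1e6)`
#' and per-observation precision weights from the fitted mean-variance trend:
#' a per-gene linear fit on `designMatrix`, a lowess smooth (span 0.5) of the
#' square-root residual standard deviation against mean log2-count, and
#' weights equal to the inverse fourth power of the trend evaluated at the
#' fitted log2-counts. Weights are clipped to `[1e-6, 1e6]`.
#'
#' @param counts Filtered count matrix, genes x samples.
#' @param normFactors Per-sample normalization factors, e.g. [tmmFactors()].
#' @param designMatrix Full-rank numeric design matrix (samples x
#'   coefficients) used for the mean-variance trend fit.
#' @return List with matrices `log2cpm` and `weights` (same shape as `counts`).
#' @export
voomTransform <- function(counts, normFactors, designMatrix) {
  counts <- as.matrix(counts)
  designMatrix <- as.matrix(designMatrix)
  if (nrow(designMatrix) != ncol(counts))
    stop("design matrix rows must match samples")
  if (qr(designMatrix)$rank < ncol(designMatrix))
    stop("design matrix is rank-deficient")
  lib <- colSums(counts) * normFactors
  meanLogCount <- rowMeans(log2(t(t(counts + 0.5) / (lib + 1)) * 1e6)) +
    mean(log2(lib + 1)) - log2(1e6)
  if (length(unique(round(meanLogCount, 10))) < 2) {
    # degenerate flat trend (e.g. all genes identical): equal weights
    l2 <- log2(t(t(counts + 0.5) / (lib + 1)) * 1e6)
    w <- matrix(1, nrow(counts), ncol(counts), dimnames = dimnames(counts))
    return(list(log2cpm = l2, weights = w))
  }
  v <- limma::voom(counts, design = designMatrix, lib.size = lib, span = 0.5)
  w <- pmin(pmax(v$weights, 1e-6), 1e6)
  dimnames(w) <- dimnames(counts)
  list(log2cpm = as.matrix(v$E), weights = w)
}

# Internal: trend-fit design over whichever design factors are estimable.
autoDesignFormula <- function(design) {
  terms <- character()
  if (length(unique(design$time)) > 1) terms <- c(terms, "time")
  if (length(unique(design$arm)) > 1) terms <- c(terms, "arm")
  if (length(terms) == 2) terms <- "time * arm"
  if (length(unique(design$order)) > 1) terms <- c(terms, "order")
  if (!length(terms)) terms <- "1"
  stats::as.formula(paste("~", paste(terms, collapse = " + ")))
}

#' Flag outlier samples by multidimensional scaling
#'
#' Classical MDS of pairwise Euclidean distances over the (up to) 500 most
#' variable genes; a sample is flagged iff its distance from the
#' coordinate-wise median of the MDS coordinates exceeds `madMult` times the
#' median absolute deviation of those distances.
#'
#' @param log2cpm Expression matrix, genes x samples (>= 4 samples).
#' @param nDims Number of MDS dimensions (default 2).
#' @param madMult MAD multiplier for the flag rule (default 4).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
mdsOutliers <- function(log2cpm, nDims = 2, madMult = 4) {
  log2cpm <- as.matrix(log2cpm)
  if (ncol(log2cpm) < 4) stop("need >= 4 samples for outlier detection")
  v <- apply(log2cpm, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(500L, nrow(log2cpm)))]
  d <- stats::dist(t(log2cpm[top, , drop = FALSE]))
  coord <- stats::cmdscale(d, k = min(nDims, ncol(log2cpm) - 1))
  ctr <- apply(coord, 2, stats::median)
  dd <- sqrt(colSums((t(coord) - ctr)^2))
  madd <- stats::mad(dd)
  if (madd == 0) return(character())
  colnames(log2cpm)[dd > madMult * madd]
}

#' Normalize a ChallengeExperiment end to end
#'
#' Runs the full preprocessing contract: cpm conversion, low-expression
#' filtering, TMM factors, the precision-weight transform, and MDS outlier
#' flagging. Outliers are flagged but not removed unless `dropOutliers` is
#' `TRUE`.
#'
#' @param ce A raw [ChallengeExperiment-class] with a `counts` assay.
#' @param rule A [filterRule()].
#' @param designFormula Formula over design columns for the mean-variance
#'   trend fit; the default (`NULL`) uses `~ time * arm + order`, dropping
#'   terms whose factors have fewer than two levels (e.g. single-arm
#'   replication studies).
#' @param dropOutliers Remove flagged samples before the transform?
#' @param madMult Passed to [mdsOutliers()].
#' @return A normalized [ChallengeExperiment-class] with assays `counts`,
#'   `log2cpm`, `weights`, a `normFactor` design column, and metadata fields
#'   `filteredGenes` and `outlierSamples`.
#' @examples
#' sim <- simulateChallengeDataset(simulationConfig(nSubjects = 4, nGenes = 80, seed = 5))
#' ce <- normalizeChallenge(ChallengeExperiment(sim$counts, sim$design))
#' ce
#' @export
normalizeChallenge <- function(ce, rule = filterRule(),
                               designFormula = NULL,
                               dropOutliers = FALSE, madMult = 4) {
  stopifnot(is(ce, "ChallengeExperiment"))
  counts <- assay(ce, "counts")
  keep <- filterLowExpression(computeCpm(counts), rule)
  ce <- ce[keep, ]
  counts <- assay(ce, "counts")
  nf <- tmmFactors(counts)
  design <- sampleDesign(ce)
  if (is.null(designFormula)) designFormula <- autoDesignFormula(design)
  mm <- stats::model.matrix(designFormula, data = design)
  vt <- voomTransform(counts, nf, mm)
  out <- if (ncol(ce) >= 4) mdsOutliers(vt$log2cpm, madMult = madMult)
         else character()
  if (dropOutliers && length(out)) {
    sel <- !colnames(ce) %in% out
    ce <- ce[, sel]
    nf <- tmmFactors(assay(ce, "counts"))
    mm <- stats::model.matrix(autoDesignFormula(sampleDesign(ce)),
                              data = sampleDesign(ce))
    vt <- voomTransform(assay(ce, "counts"), nf, mm)
  }
  SummarizedExperiment::assay(ce, "log2cpm") <- vt$log2cpm
  SummarizedExperiment::assay(ce, "weights") <- vt$weights
  ce$normFactor <- unname(nf)
  metadata(ce)$filteredGenes <- sum(keep)
  metadata(ce)$outlierSamples <- out
  validObject(ce)
  ce
}
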