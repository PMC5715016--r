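#' Estimate leukocyte fractions for one sample by nu-SVR
#'
#' Signature-based deconvolution: the mixture profile and the signature
#' matrix are z-scored over their shared gene set, a linear nu-support-vector
#' regression of the mixture on the signature columns is fitted for each
#' candidate `nu`, and the `nu` minimizing the root-mean-square error between
#' the reconstruction and the mixture is selected. Negative coefficients are
#' clipped to zero and the remainder normalized to sum to one.
#'
#' @param mixture Named numeric vector of (linear-scale) expression for one
#'   sample; names are gene symbols.
#' @param signature Numeric matrix, signature genes x cell types.
#' @param nus Candidate nu values (default `c(0.25, 0.5, 0.75)`).
#' @return List with `fractions` (named, non-negative, sum 1), `rmse`,
#'   `correlation`, `nu` (selected), and `degenerate` (TRUE when all raw
#'   coefficients were non-positive and uniform fractions were returned).
#' @examples
#' sig <- matrix(rexp(60, 1 / 40), 30, 2,
#'               dimnames = list(paste0("g", 1:30), c("A", "B")))
#' deconvolveSample(sig[, 1], sig)$fractions
#' @export
deconvolveSample <- function(mixture, signature, nus = c(0.25, 0.5, 0.75)) {
  signature <- as.matrix(signature)
  if (is.null(names(mixture))) {
    if (length(mixture) != nrow(signature))
      stop("unnamed mixture must align with signature rows")
    names(mixture) <- rownames(signature)
  }
  shared <- intersect(names(mixture), rownames(signature))
  if (length(shared) < 2) stop("fewer than 2 genes shared with the signature")
  y <- as.numeric(mixture[shared])
  X <- signature[shared, , drop = FALSE]
  y <- (y - mean(y)) / stats::sd(y)
  X <- (X - mean(X)) / stats::sd(as.vector(X))

  best <- NULL
  for (nu in nus) {
    fit <- e1071::svm(X, y, type = "nu-regression", kernel = "linear",
                      nu = nu, scale = FALSE)
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    w[w < 0] <- 0
    if (sum(w) == 0) {
      cand <- list(frac = rep(1 / ncol(X), ncol(X)), rmse = Inf,
                   cor = 0, nu = nu, degenerate = TRUE)
    } else {
      w <- w / sum(w)
      recon <- as.vector(X %*% w)
      cand <- list(frac = w, rmse = sqrt(mean((recon - y)^2)),
                   cor = stats::cor(recon, y), nu = nu, degenerate = FALSE)
    }
    if (is.null(best) || cand$rmse < best$rmse) best <- cand
  }
  if (best$degenerate) {
    warning("all coefficients non-positive; returning uniform fractions")
    best$rmse <- NA_real_
  }
  list(fractions = stats::setNames(best$frac, colnames(X)),
       rmse = best$rmse, correlation = best$cor, nu = best$nu,
       degenerate = best$degenerate)
}

#' Permutation p-value for a deconvolution fit
#'
#' Permutes the gene labels of the mixture `nPerm` times, refits the
#' regression at the observed best `nu`, and compares the Pearson correlation
#' between reconstruction and (permuted) mixture with the observed one:
#' `p = (1 + #{perm >= observed}) / (nPerm + 1)`. Seed-deterministic.
#'
#' @inheritParams deconvolveSample
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A single p-value.
#' @export
deconvolvePermutationP <- function(mixture, signature, nPerm = 1000, seed = 1,
                                   nus = c(0.25, 0.5, 0.75)) {
  signature <- as.matrix(signature)
  if (is.null(names(mixture))) names(mixture) <- rownames(signature)
  obs <- deconvolveSample(mixture, signature, nus)
  shared <- intersect(names(mixture), rownames(signature))
  y <- as.numeric(mixture[shared])
  X <- signature[shared, , drop = FALSE]
  y <- (y - mean(y)) / stats::sd(y)
  X <- (X - mean(X)) / stats::sd(as.vector(X))
  set.seed(deriveSeed(seed, "deconv-perm"))
  hits <- 0L
  for (b in seq_len(nPerm)) {
    ys <- sample(y)
    fit <- e1071::svm(X, ys, type = "nu-regression", kernel = "linear",
                      nu = obs$nu, scale = FALSE)
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    w[w < 0] <- 0
    cc <- if (sum(w) == 0) 0 else stats::cor(as.vector(X %*% (w / sum(w))), ys)
    if (cc >= obs$correlation) hits <- hits + 1L
  }
  (1 + hits) / (nPerm + 1)
}

#' Deconvolve every sample of a study
#'
#' Applies [deconvolveSample()] (and optionally [deconvolvePermutationP()])
#' to each column of a count matrix or [ChallengeExperiment-class]. By
#' default counts are normalized by median-of-ratios size factors before
#' deconvolution (linear scale, the cited tool's expected input);
#' `input = "log2cpm"` instead uses the normalized log2-cpm assay. No
#' significance filter is applied to the estimated fractions.
#'
#' @param x Count matrix (genes x samples) or a [ChallengeExperiment-class].
#' @param signature Numeric matrix, signature genes x cell types.
#' @param nPerm Permutations per sample; 0 skips permutation p-values.
#' @param seed Integer seed.
#' @param input `"median_ratios"` (default) or `"log2cpm"`.
#' @param nus Candidate nu values.
#' @return `data.frame` (one row per sample x cell type): `sample`,
#'   `cellType`, `fraction`, `fitRmse`, `fitCorrelation`, `permutationP`.
#' @export
deconvolveStudy <- function(x, signature, nPerm = 1000, seed = 1,
                            input = c("median_ratios", "log2cpm"),
                            nus = c(0.25, 0.5, 0.75)) {
  input <- match.arg(input)
  if (is(x, "ChallengeExperiment")) {
    expr <- if (input == "log2cpm") 2^log2cpm(x)
            else assay(x, "counts")
  } else expr <- as.matrix(x)
  if (input == "median_ratios") {
    sf <- DESeq2::estimateSizeFactorsForMatrix(expr)
    expr <- sweep(expr, 2, sf, "/")
  }
  out <- vector("list", ncol(expr))
  for (s in seq_len(ncol(expr))) {
    mix <- expr[, s]
    names(mix) <- rownames(expr)
    d <- deconvolveSample(mix, signature, nus)
    pp <- if (nPerm > 0)
      deconvolvePermutationP(mix, signature, nPerm,
                             deriveSeed(seed, colnames(expr)[s]), nus)
    else NA_real_
    out[[s]] <- data.frame(sample = colnames(expr)[s],
                           cellType = names(d$fractions),
                           fraction = unname(d$fractions),
                           fitRmse = d$rmse, fitCorrelation = d$correlation,
                           permutationP = pp, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Screen cell fractions for challenge-specific changes
#'
#' Reuses the interaction-screen mixed model on each cell type's fraction
#' (no observation weights): null `fraction ~ Time + Challenge + Order +
#' (1|subject) + (1|date)`, test adds the interaction, LRT with df = 2, then
#' Benjamini-Hochberg FDR across cell types. Stratified re-analysis (e.g. by
#' epinephrine administration) is a pure subset operation via `subset`.
#'
#' @param fractions `data.frame` from [deconvolveStudy()].
#' @param design Sample design `data.frame` (rows matched by `sample` column
#'   or rownames).
#' @param subset Optional character vector of sample ids (or logical over
#'   design rows) restricting the analysis.
#' @return `data.frame`: `cellType`, `lrtStat`, `df`, `pRaw`, `fdr`,
#'   `converged`, sorted by `pRaw`. Cell types constant across samples get
#'   `pRaw = 1` and `converged = FALSE`.
#' @export
cellFractionScreen <- function(fractions, design, subset = NULL) {
  design <- as.data.frame(design)
  if ("sample" %in% colnames(design)) rownames(design) <- design$sample
  if (!is.null(subset)) {
    if (is.logical(subset)) subset <- rownames(design)[subset]
    design <- design[rownames(design) %in% subset, , drop = FALSE]
    fractions <- fractions[fractions$sample %in% subset, , drop = FALSE]
  }
  mat <- stats::xtabs(fraction ~ cellType + sample, data = fractions)
  miss <- setdiff(rownames(design), colnames(mat))
  if (length(miss))
    stop("fractions missing for sample(s): ", paste(miss, collapse = ", "))
  mat <- mat[, rownames(design), drop = FALSE]
  types <- rownames(mat)
  stat <- p <- rep(NA_real_, length(types))
  conv <- logical(length(types))
  for (i in seq_along(types)) {
    yv <- as.numeric(mat[i, ])
    if (stats::sd(yv) == 0) {
      stat[i] <- 0; p[i] <- 1; conv[i] <- FALSE
      next
    }
    res <- tryCatch({
      f0 <- fitGeneLmm(yv, NULL, design, lmmSpec(), withInteraction = FALSE)
      f1 <- fitGeneLmm(yv, NULL, design, lmmSpec(), withInteraction = TRUE)
      lt <- suppressWarnings(lrTest(f0$logLik, f1$logLik, df = 2))
      list(stat = lt$stat, p = lt$p, conv = f0$converged && f1$converged)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      stat[i] <- res$stat; p[i] <- res$p; conv[i] <- res$conv
    }
  }
  out <- data.frame(cellType = types, lrtStat = stat, df = 2L, pRaw = p,
                    fdr = stats::p.adjust(p, method = "BH"), converged = conv,
                    stringsAsFactors = FALSE)
  out[order(out$pRaw), , drop = FALSE]
}
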