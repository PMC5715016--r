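#' Specification of the per-gene linear mixed model
#'
#' Fixed effects: Time (unordered 3-level factor), Challenge arm, challenge
#' Order, and — in the test model only — the Time-by-Challenge interaction
#' (adding exactly 2 parameters). Random intercepts: subject and collection
#' date. `weightMode` controls how precision weights enter:
#' `"observation_weights"` (default) places them in the likelihood as
#' per-observation weights; `"covariate"` adds the weight value as a fixed
#' covariate instead, for comparability with a literal reading of the model
#' statement.
#'
#' @param weightMode `"observation_weights"` or `"covariate"`.
#' @return A list of class `"LmmSpec"`.
#' @export
lmmSpec <- function(weightMode = c("observation_weights", "covariate")) {
  structure(list(weightMode = match.arg(weightMode)), class = "LmmSpec")
}

# Internal: one ML lmer fit, with convergence capture.
# data must contain columns y, w, time, arm, order, subject, collectionDate.
fitLmm <- function(formula, data, useWeights) {
  conv <- TRUE
  fit <- withCallingHandlers(
    {
      if (useWeights)
        lme4::lmer(formula, data = data, weights = w, REML = FALSE,
                   control = lme4::lmerControl(
                     calc.derivs = FALSE,
                     check.conv.singular = lme4::.makeCC(action = "ignore",
                                                         tol = 1e-4)))
      else
        lme4::lmer(formula, data = data, REML = FALSE,
                   control = lme4::lmerControl(
                     calc.derivs = FALSE,
                     check.conv.singular = lme4::.makeCC(action = "ignore",
                                                         tol = 1e-4)))
    },
    warning = function(wrn) {
      conv <<- FALSE
      invokeRestart("muffleWarning")
    })
  list(fit = fit, converged = conv)
}

#' Fit the challenge-response mixed model for one gene
#'
#' Maximum-likelihood (not REML) estimation, as the null and test models
#' differ in fixed effects and their likelihoods feed a likelihood-ratio
#' test. The fit is deterministic for fixed data.
#'
#' @param y Per-sample expression (log2-cpm) vector aligned with `design` rows.
#' @param weights Per-observation precision weights (same length); ignored
#'   under `weightMode = "covariate"` except as the covariate values.
#' @param design Sample design `data.frame` with columns `subject`, `arm`,
#'   `time`, `order`, `collectionDate`.
#' @param spec An [lmmSpec()].
#' @param withInteraction Include the Time-by-Challenge interaction?
#' @return List with `logLik`, `fixef`, `varcomp` (SDs of subject, date and
#'   residual), `converged`, and the `fit` object.
#' @export
fitGeneLmm <- function(y, weights, design, spec = lmmSpec(),
                       withInteraction = FALSE) {
  stopifnot(inherits(spec, "LmmSpec"))
  d <- lmmData(y, weights, design)
  if (nlevels(d$time) < 2)
    stop("singular design: need >= 2 time points")
  if (withInteraction && nlevels(d$arm) < 2)
    stop("singular design: interaction needs both challenge arms")
  obsW <- spec$weightMode == "observation_weights"
  rhs <- if (withInteraction) "time * arm" else "time + arm"
  if (nlevels(d$arm) < 2) rhs <- "time"
  if (nlevels(d$order) > 1) rhs <- paste(rhs, "+ order")
  if (!obsW) rhs <- paste(rhs, "+ w")
  rhs <- paste(rhs, "+ (1 | subject)")
  if (nlevels(d$collectionDate) > 1) rhs <- paste(rhs, "+ (1 | collectionDate)")
  res <- fitLmm(stats::as.formula(paste("y ~", rhs)), d, obsW)
  vc <- as.data.frame(lme4::VarCorr(res$fit))
  sds <- stats::setNames(vc$sdcor, vc$grp)
  list(logLik = as.numeric(stats::logLik(res$fit)),
       fixef = lme4::fixef(res$fit),
       varcomp = sds, converged = res$converged, fit = res$fit)
}

# Internal: assemble the model frame with fixed factor codings; unused
# levels are dropped so single-arm or fewer-time designs stay estimable.
lmmData <- function(y, weights, design) {
  data.frame(y = as.numeric(y),
             w = if (is.null(weights)) rep(1, length(y)) else as.numeric(weights),
             time = factor(design$time,
                           levels = intersect(TIME_LEVELS, design$time)),
             arm = factor(design$arm,
                          levels = intersect(ARM_LEVELS, design$arm)),
             order = factor(design$order),
             subject = factor(design$subject),
             collectionDate = factor(design$collectionDate))
}

#' Likelihood-ratio test between nested model fits
#'
#' `stat = max(0, 2 * (llTest - llNull))`; the p-value is the upper tail of a
#' chi-square with `df` degrees of freedom. A negative statistic (numerical
#' noise from the optimizer) clamps to 0 with a warning.
#'
#' @param llNull,llTest Maximized log-likelihoods of the nested and superset
#'   models.
#' @param df Degrees of freedom (default 2: the Time-by-Challenge interaction
#'   adds (3-1)x(2-1) parameters).
#' @return List with `stat` and `p`.
#' @examples
#' lrTest(-100, -97.0045)  # stat 5.991, p ~= 0.05
#' @export
lrTest <- function(llNull, llTest, df = 2) {
  stat <- 2 * (llTest - llNull)
  if (stat < 0) {
    if (stat < -1e-8)
      warning("test log-likelihood below null by ", format(-stat / 2),
              "; statistic clamped to 0")
    stat <- 0
  }
  list(stat = stat, p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Per-gene interaction screen across a normalized study
#'
#' Fits the null (`~ Time + Challenge + Order + (1|subject) + (1|date)`) and
#' test (adds `Time:Challenge`) mixed models for every gene and tests the
#' interaction by LRT (df = 2). Bonferroni multiplies by the number of genes
#' whose fits converged (capped at 1); genes with failed or non-converged
#' fits are reported flagged and excluded from that multiplier. Results are
#' sorted by raw p.
#'
#' @param ce A normalized [ChallengeExperiment-class].
#' @param spec An [lmmSpec()].
#' @param pPeanut Raw-p threshold for the extended response-gene flag
#'   (default 0.005).
#' @param pTop Bonferroni threshold for the top-gene flag (default 0.01).
#' @return `data.frame` with columns `gene`, `lrtStat`, `df`, `pRaw`,
#'   `pBonferroni`, `deltaT4T0`, `converged`, `isPeanutGene`, `isTop`.
#' @examples
#' sim <- simulateChallengeDataset(simulationConfig(nSubjects = 5, nGenes = 40,
#'                                                  deltaT4 = 2, seed = 4))
#' ce <- normalizeChallenge(ChallengeExperiment(sim$counts, sim$design))
#' head(screenAllGenes(ce))
#' @export
screenAllGenes <- function(ce, spec = lmmSpec(), pPeanut = 0.005, pTop = 0.01) {
  stopifnot(is(ce, "ChallengeExperiment"))
  E <- log2cpm(ce)
  W <- precisionWeights(ce)
  design <- sampleDesign(ce)
  genes <- rownames(E)
  n <- length(genes)
  stat <- p <- rep(NA_real_, n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      f0 <- fitGeneLmm(E[i, ], W[i, ], design, spec, withInteraction = FALSE)
      f1 <- fitGeneLmm(E[i, ], W[i, ], design, spec, withInteraction = TRUE)
      lt <- suppressWarnings(lrTest(f0$logLik, f1$logLik, df = 2))
      list(stat = lt$stat, p = lt$p, conv = f0$converged && f1$converged)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      stat[i] <- res$stat
      p[i] <- res$p
      conv[i] <- res$conv
    }
  }
  nBad <- sum(!conv)
  if (nBad)
    message(nBad, " gene(s) flagged non-converged; excluded from the ",
            "Bonferroni multiplier")
  G <- sum(conv)
  pB <- ifelse(conv, pmin(1, p * G), NA_real_)
  delta <- vapply(genes, function(g) effectSizeDelta(ce, g), numeric(1))
  out <- data.frame(gene = genes, lrtStat = stat, df = 2L, pRaw = p,
                    pBonferroni = pB, deltaT4T0 = unname(delta),
                    converged = conv,
                    isPeanutGene = conv & !is.na(p) & p < pPeanut,
                    isTop = conv & !is.na(pB) & pB < pTop,
                    stringsAsFactors = FALSE)
  out[order(out$pRaw), , drop = FALSE]
}

#' Baseline-to-peak effect size for one gene
#'
#' Mean log2-cpm at the 4-hour peanut time point minus mean log2-cpm at
#' peanut baseline, unweighted across subjects — the descriptive effect size
#' reported alongside the interaction screen.
#'
#' @param ce A normalized [ChallengeExperiment-class].
#' @param gene Gene symbol.
#' @return A single numeric delta (log2-cpm).
#' @export
effectSizeDelta <- function(ce, gene) {
  design <- sampleDesign(ce)
  pea <- design$arm == "peanut"
  if (!any(pea)) stop("no peanut-arm samples")
  y <- log2cpm(ce)[gene, ]
  mean(y[pea & design$time == "T4"]) - mean(y[pea & design$time == "T0"])
}

#' Time-effect screen for a single-arm replication study
#'
#' For a cohort with challenge samples from one arm only, tests per gene for
#' an effect of Time: null `~ order + (1|subject) + (1|date)`, test adds the
#' 3-level Time factor (df = 2).
#'
#' @param ce A normalized single-arm [ChallengeExperiment-class].
#' @param spec An [lmmSpec()].
#' @return `data.frame` with `gene`, `lrtStat`, `df`, `pRaw`, `pBonferroni`,
#'   `converged`, sorted by `pRaw`.
#' @export
replicationScreen <- function(ce, spec = lmmSpec()) {
  stopifnot(is(ce, "ChallengeExperiment"))
  E <- log2cpm(ce)
  W <- precisionWeights(ce)
  design <- sampleDesign(ce)
  obsW <- spec$weightMode == "observation_weights"
  genes <- rownames(E)
  n <- length(genes)
  stat <- p <- rep(NA_real_, n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      d <- lmmData(E[i, ], W[i, ], design)
      base <- if (nlevels(d$order) > 1) "order" else "1"
      if (!obsW) base <- paste(base, "+ w")
      re <- "+ (1 | subject)"
      if (nlevels(d$collectionDate) > 1) re <- paste(re, "+ (1 | collectionDate)")
      f0 <- fitLmm(stats::as.formula(paste("y ~", base, re)), d, obsW)
      f1 <- fitLmm(stats::as.formula(paste("y ~ time +", base, re)), d, obsW)
      lt <- suppressWarnings(lrTest(as.numeric(stats::logLik(f0$fit)),
                                    as.numeric(stats::logLik(f1$fit)), df = 2))
      list(stat = lt$stat, p = lt$p, conv = f0$converged && f1$converged)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      stat[i] <- res$stat
      p[i] <- res$p
      conv[i] <- res$conv
    }
  }
  G <- sum(conv)
  pB <- ifelse(conv, pmin(1, p * G), NA_real_)
  out <- data.frame(gene = genes, lrtStat = stat, df = 2L, pRaw = p,
                    pBonferroni = pB, converged = conv,
                    stringsAsFactors = FALSE)
  out[order(out$pRaw), , drop = FALSE]
}
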