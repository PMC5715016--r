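# Minimal balanced crossover design used by several fixtures below.
makeDesign <- function(nSubjects = 6, seed = 1) {
  set.seed(seed)
  d <- expand.grid(time = c("T0", "T2", "T4"), arm = c("peanut", "placebo"),
                   subject = sprintf("P%02d", seq_len(nSubjects)),
                   stringsAsFactors = FALSE)
  d$order <- rep(c("peanut_first", "placebo_first"),
                 length.out = nSubjects)[match(d$subject, unique(d$subject))]
  d$collectionDate <- sprintf("2016-02-%02d",
                              1 + (match(d$subject, unique(d$subject)) +
                                     (d$arm == "peanut")) %% 9)
  d$epinephrine <- FALSE
  d
}

test_that("the mixed model recovers known cell means from clean data", {
  d <- makeDesign(8)
  cellMean <- c(T0 = 5, T2 = 5.3, T4 = 6.4)
  armBump <- ifelse(d$arm == "peanut", 0.8, 0)
  set.seed(2)
  y <- cellMean[d$time] + armBump * (d$time == "T4") + rnorm(nrow(d), 0, 1e-7)
  fit <- fitGeneLmm(y, rep(1, nrow(d)), d, withInteraction = TRUE)
  mm <- model.matrix(~ time * arm + order,
                     data = transform(d,
                                      time = factor(time),
                                      arm = factor(arm, c("peanut", "placebo")),
                                      order = factor(order)))
  pred <- as.vector(mm[, names(fit$fixef)] %*% fit$fixef)
  expect_lt(max(abs(pred - y)), 1e-6)
})

test_that("likelihoods nest and the LRT honours its closed form", {
  # chi-square df=2 closed form: p = exp(-stat / 2)
  lt <- lrTest(-100, -100 + 5.991 / 2)
  expect_equal(lt$stat, 5.991)
  expect_equal(lt$p, exp(-5.991 / 2), tolerance = 1e-12)
  expect_equal(lt$p, 0.05, tolerance = 1e-3)

  same <- lrTest(-50, -50)
  expect_identical(same$stat, 0)
  expect_identical(same$p, 1)

  expect_warning(out <- lrTest(-50, -50 - 1e-4), "clamped")
  expect_identical(out$stat, 0)

  # numerically tiny deficits clamp silently
  expect_silent(out2 <- lrTest(-50, -50 - 1e-10))
  expect_identical(out2$stat, 0)

  # nesting on real fits: test log-likelihood >= null log-likelihood
  st <- smallStudy()
  E <- log2cpm(st$ce)
  W <- precisionWeights(st$ce)
  des <- sampleDesign(st$ce)
  for (g in rownames(E)[1:5]) {
    f0 <- fitGeneLmm(E[g, ], W[g, ], des, withInteraction = FALSE)
    f1 <- fitGeneLmm(E[g, ], W[g, ], des, withInteraction = TRUE)
    expect_gte(f1$logLik, f0$logLik - 1e-6)
  }
})

test_that("estimates are invariant to rescaling the observation weights", {
  st <- smallStudy()
  E <- log2cpm(st$ce)
  W <- precisionWeights(st$ce)
  des <- sampleDesign(st$ce)
  g <- rownames(E)[3]
  f1 <- fitGeneLmm(E[g, ], W[g, ], des, withInteraction = TRUE)
  f2 <- fitGeneLmm(E[g, ], 2 * W[g, ], des, withInteraction = TRUE)
  expect_equal(f1$fixef, f2$fixef, tolerance = 1e-6)
})

test_that("singular designs are rejected", {
  d <- makeDesign(4)
  oneTime <- d[d$time == "T0", ]
  expect_error(fitGeneLmm(rnorm(nrow(oneTime)), NULL, oneTime),
               "time points")
  oneArm <- d[d$arm == "peanut", ]
  expect_error(fitGeneLmm(rnorm(nrow(oneArm)), NULL, oneArm,
                          withInteraction = TRUE),
               "both challenge arms")
})

test_that("the screen flags planted genes and obeys the Bonferroni cap", {
  st <- smallStudy()
  scr <- screenAllGenes(st$ce)
  m <- merge(scr, st$truth, by = "gene")
  # strong planted effect (2 log2-cpm): most planted genes reach p < 0.005
  expect_gt(mean(m$isPeanutGene[m$isInteraction]), 0.7)
  expect_lt(mean(m$isPeanutGene[!m$isInteraction]), 0.2)
  # Bonferroni: capped at 1 whenever pRaw > 1/G, >= pRaw always
  G <- sum(scr$converged)
  hi <- scr$pRaw > 1 / G & scr$converged
  expect_true(all(scr$pBonferroni[hi] == 1))
  expect_true(all(scr$pBonferroni >= scr$pRaw - 1e-12, na.rm = TRUE))
  expect_true(all(diff(scr$pRaw) >= 0))
  # flags consistent with thresholds
  expect_identical(scr$isPeanutGene,
                   scr$converged & !is.na(scr$pRaw) & scr$pRaw < 0.005)
})

test_that("screen results are invariant to sample order", {
  st <- smallStudy()
  scr1 <- screenAllGenes(st$ce)
  set.seed(7)
  perm <- sample(ncol(st$ce))
  scr2 <- screenAllGenes(st$ce[, perm])
  expect_equal(scr1$pRaw, scr2$pRaw, tolerance = 1e-6)
  expect_identical(scr1$gene, scr2$gene)
})

test_that("the covariate weight mode runs and differs from the default", {
  st <- smallStudy()
  sub <- st$ce[1:10, ]
  scrW <- screenAllGenes(sub)
  scrC <- screenAllGenes(sub, spec = lmmSpec("covariate"))
  expect_true(all(!is.na(scrC$pRaw)))
  expect_false(isTRUE(all.equal(scrW$lrtStat, scrC$lrtStat)))
})

test_that("the descriptive effect size measures the peanut T4 - T0 shift", {
  st <- smallStudy()
  ce <- st$ce
  g <- rownames(ce)[1]
  d <- sampleDesign(ce)
  E <- log2cpm(ce)
  manual <- mean(E[g, d$arm == "peanut" & d$time == "T4"]) -
    mean(E[g, d$arm == "peanut" & d$time == "T0"])
  expect_equal(effectSizeDelta(ce, g), manual)
  # constant gene: delta exactly 0
  ceConst <- ce
  SummarizedExperiment::assay(ceConst, "log2cpm")[g, ] <- 3
  expect_identical(effectSizeDelta(ceConst, g), 0)
  # sign agreement with the planted direction for strong effects
  scr <- screenAllGenes(ce)
  m <- merge(scr, st$truth, by = "gene")
  planted <- m[m$isInteraction, ]
  expect_gte(mean(sign(planted$deltaT4T0) == sign(planted$delta)), 0.95)
})

test_that("the single-arm replication screen tests Time with 2 df", {
  sim <- simulateChallengeDataset(simulationConfig(
    nSubjects = 8, nGenes = 30, deltaT4 = 2, fracInteractionGenes = 0.3,
    nModules = 0, seed = 23))
  peanutOnly <- sim$design$arm == "peanut"
  ce <- suppressMessages(normalizeChallenge(
    ChallengeExperiment(sim$counts[, peanutOnly], sim$design[peanutOnly, ])))
  rep <- replicationScreen(ce)
  expect_true(all(rep$df == 2))
  m <- merge(rep, sim$truth, by = "gene")
  # planted time trends in the peanut arm are detected
  expect_gt(mean(m$pRaw[m$isInteraction] < 0.05), 0.7)
})

test_that("overlap odds ratios follow the 2x2 definition", {
  eq <- overlapOddsRatio(5, 20, 25, 100)   # equal proportions
  expect_equal(eq$or, 1)
  # table (28, 2 | r, s): OR = 14 s / r by algebra
  alg <- overlapOddsRatio(28, 30, 7, 30)
  expect_equal(alg$or, 14 * 23 / 7)
  expect_error(overlapOddsRatio(0, 0, 1, 5), "non-empty")
  # Haldane correction engages on zero cells and keeps the estimate finite
  z <- overlapOddsRatio(10, 10, 3, 10)
  expect_true(is.finite(z$or))
})

test_that("Fisher p-values equal the exhaustive hypergeometric computation", {
  set.seed(8)
  for (i in 1:20) {
    N <- sample(8:20, 1)
    n <- sample(2:(N - 2), 1)
    K <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    ours <- overlapOddsRatio(k, n, K - k, N - n)
    expect_equal(ours$p, bruteFisherTwoSided(k, n, K, N), tolerance = 1e-9)
  }
})

test_that("variance components are recovered on synthetic mixed-model data", {
  d <- makeDesign(50, seed = 10)
  sSubj <- 0.6; sDate <- 0.3; sRes <- 0.5
  set.seed(11)
  ests <- replicate(8, {
    bS <- rnorm(50, 0, sSubj)[match(d$subject, unique(d$subject))]
    bD <- rnorm(length(unique(d$collectionDate)), 0,
                sDate)[match(d$collectionDate, unique(d$collectionDate))]
    y <- 5 + bS + bD + rnorm(nrow(d), 0, sRes)
    fit <- fitGeneLmm(y, NULL, d, withInteraction = FALSE)
    c(subj = unname(fit$varcomp["subject"]),
      date = unname(fit$varcomp["collectionDate"]),
      res = unname(fit$varcomp["Residual"]))
  })
  m <- rowMeans(ests)
  expect_lt(abs(m["subj"] - sSubj) / sSubj, 0.2)
  expect_lt(abs(m["date"] - sDate) / sDate, 0.2)
  expect_lt(abs(m["res"] - sRes) / sRes, 0.2)
})
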