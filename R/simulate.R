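#' Configuration for the crossover challenge simulator
#'
#' Bundles and validates all parameters of the synthetic-data generator. The
#' defaults emulate the study conditions the pipeline targets: 19 subjects
#' each sampled at three time points (0/2/4 h) in both a peanut and a placebo
#' challenge arm; a minority of genes carrying a Time-by-Challenge
#' interaction concentrated at the 4-hour peanut time point (mean shift 0.24
#' log2-cpm, with a 2-hour shift one sixth of that and 65% of affected genes
#' up-regulated); negative-binomial counts with subject random intercepts and
#' shared collection-date effects; latent-factor coexpression blocks; and a
#' planted causal DAG whose root genes can carry eQTL anchors.
#'
#' @param nSubjects Number of subjects (default 19).
#' @param nGenes Number of genes.
#' @param fracInteractionGenes Fraction of genes with a planted
#'   Time-by-Challenge interaction (default 0.125).
#' @param deltaT4 Planted log2-cpm shift at 4 h in the peanut arm (default 0.24).
#' @param deltaT2 Planted shift at 2 h; default `deltaT4 / 6`.
#' @param fracUpregulated Fraction of interaction genes shifted upward
#'   (default 0.65).
#' @param sigmaSubject SD of per-gene subject random intercepts, log2 scale
#'   (default 0.5).
#' @param sigmaDate SD of per-gene collection-date effects, log2 scale
#'   (default 0.1).
#' @param sigmaResid SD of per-observation log2 residual noise — the
#'   biological overdispersion component (default 0.5).
#' @param nbDispersion Negative-binomial dispersion phi, `Var = mu + phi mu^2`,
#'   capturing technical overdispersion beyond Poisson counting noise;
#'   biological noise is carried by `sigmaResid`, so the default is small
#'   (0.01).
#' @param libSizeMean,libSizeCV Log-normal library-size model (defaults 2e7, 0.3).
#' @param nModules,moduleSize,moduleCor Latent-factor coexpression blocks:
#'   number, genes per block, target within-block correlation of the log2
#'   residual signal.
#' @param dagNNodes,dagEdgeProb,dagEffect,dagNSamples Causal-layer DAG size,
#'   per-pair edge probability, structural edge weight, and sample count.
#' @param fracEqtl Fraction of DAG root genes given an eQTL genotype anchor.
#' @param seed Master seed; fully determines all outputs.
#' @return A validated list of class `"SimulationConfig"`.
#' @examples
#' cfg <- simulationConfig(nSubjects = 6, nGenes = 100, seed = 7)
#' @export
simulationConfig <- function(nSubjects = 19, nGenes = 1000,
                             fracInteractionGenes = 0.125,
                             deltaT4 = 0.24, deltaT2 = deltaT4 / 6,
                             fracUpregulated = 0.65,
                             sigmaSubject = 0.5, sigmaDate = 0.1,
                             sigmaResid = 0.5, nbDispersion = 0.01,
                             libSizeMean = 2e7, libSizeCV = 0.3,
                             nModules = 3, moduleSize = 50, moduleCor = 0.6,
                             dagNNodes = 10, dagEdgeProb = 0.2,
                             dagEffect = 0.8, dagNSamples = 500,
                             fracEqtl = 0.3, seed = 1) {
  cfg <- list(nSubjects = nSubjects, nGenes = nGenes,
              fracInteractionGenes = fracInteractionGenes,
              deltaT4 = deltaT4, deltaT2 = deltaT2,
              fracUpregulated = fracUpregulated,
              sigmaSubject = sigmaSubject, sigmaDate = sigmaDate,
              sigmaResid = sigmaResid, nbDispersion = nbDispersion,
              libSizeMean = libSizeMean, libSizeCV = libSizeCV,
              nModules = nModules, moduleSize = moduleSize,
              moduleCor = moduleCor, dagNNodes = dagNNodes,
              dagEdgeProb = dagEdgeProb, dagEffect = dagEffect,
              dagNSamples = dagNSamples, fracEqtl = fracEqtl, seed = seed)
  assertScalar(nSubjects, "nSubjects", 2)
  assertScalar(nGenes, "nGenes", 1)
  for (f in c("fracInteractionGenes", "fracUpregulated", "fracEqtl",
              "dagEdgeProb"))
    assertScalar(cfg[[f]], f, 0, 1)
  assertScalar(moduleCor, "moduleCor", 0, 0.999)
  for (s in c("sigmaSubject", "sigmaDate", "sigmaResid", "nbDispersion"))
    assertScalar(cfg[[s]], s, 0)
  for (s in c("libSizeMean", "libSizeCV", "moduleSize", "dagNNodes",
              "dagNSamples"))
    assertScalar(cfg[[s]], s, 1e-12)
  assertScalar(seed, "seed", -2^31, 2^31)
  if (nModules * moduleSize > nGenes)
    stop("nModules * moduleSize must not exceed nGenes")
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a placebo-controlled crossover challenge RNA-seq dataset
#'
#' Generates 6 samples per subject (3 time points x 2 arms). Counts are drawn
#' negative-binomially around per-gene base abundances multiplied by
#' `2^(subject intercept + collection-date effect + planted arm/time shift +
#' module factor + residual noise)`. Interaction genes receive the configured
#' log2 shift in the peanut arm at 4 h (and a partial shift at 2 h); samples
#' collected the same simulated day share one date effect, making the date
#' random effect identifiable. Each logical component draws from its own
#' RNG stream split off the master seed, so changing `nGenes` does not
#' perturb the subject-level draws.
#'
#' @param cfg A [simulationConfig()].
#' @return A list with `counts` (integer matrix, genes x samples), `design`
#'   (`data.frame`: sample, subject, arm, time, order, collectionDate,
#'   epinephrine), and `truth` (`data.frame`: gene, isInteraction, delta,
#'   deltaT2, module).
#' @examples
#' sim <- simulateChallengeDataset(simulationConfig(nSubjects = 4, nGenes = 60, seed = 2))
#' dim(sim$counts)
#' @export
simulateChallengeDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  nS <- cfg$nSubjects
  nG <- cfg$nGenes
  subjects <- sprintf("S%02d", seq_len(nS))
  genes <- sprintf("G%04d", seq_len(nG))

  # -- design stream: order, epinephrine, collection dates ----------------
  set.seed(deriveSeed(cfg$seed, "design"))
  order <- sample(ORDER_LEVELS, nS, replace = TRUE)
  epi <- stats::rbinom(nS, 1, 11 / 19) == 1   # epinephrine administration rate
  nDates <- max(2L, as.integer(ceiling(nS)))
  dateIdx <- sample.int(nDates, nS * 2, replace = TRUE)  # one day per subject-arm
  dates <- as.character(as.Date("2016-01-01") + sort(unique(dateIdx)))
  names(dates) <- sort(unique(dateIdx))

  design <- expand.grid(time = TIME_LEVELS, arm = ARM_LEVELS,
                        subject = subjects, stringsAsFactors = FALSE)
  design <- design[, c("subject", "arm", "time")]
  sa <- match(paste(design$subject, design$arm),
              paste(rep(subjects, each = 2), rep(ARM_LEVELS, nS)))
  design$order <- order[match(design$subject, subjects)]
  design$collectionDate <- dates[as.character(dateIdx[sa])]
  design$epinephrine <- epi[match(design$subject, subjects)]
  design$sample <- sprintf("%s_%s_%s", design$subject,
                           substr(design$arm, 1, 3), design$time)
  design <- design[, c("sample", "subject", "arm", "time", "order",
                       "collectionDate", "epinephrine")]
  nSamp <- nrow(design)

  # -- library sizes ------------------------------------------------------
  set.seed(deriveSeed(cfg$seed, "libsizes"))
  sdlog <- sqrt(log(1 + cfg$libSizeCV^2))
  libs <- stats::rlnorm(nSamp, log(cfg$libSizeMean) - sdlog^2 / 2, sdlog)

  # -- gene effects: base abundance, interaction set, signs ---------------
  # moderate abundance spread: at test-scale gene counts no single gene
  # should dominate the library sum the way none does transcriptome-wide
  set.seed(deriveSeed(cfg$seed, "genes"))
  baseLog2Cpm <- stats::rnorm(nG, mean = 5, sd = 1.2)
  nInt <- round(cfg$fracInteractionGenes * nG)
  intIdx <- sort(sample.int(nG, nInt))
  up <- stats::rbinom(nInt, 1, cfg$fracUpregulated) == 1
  delta <- numeric(nG)
  delta[intIdx] <- ifelse(up, cfg$deltaT4, -cfg$deltaT4)
  deltaT2 <- numeric(nG)
  if (cfg$deltaT4 != 0)
    deltaT2[intIdx] <- delta[intIdx] * (cfg$deltaT2 / cfg$deltaT4)

  # module blocks occupy the tail of the gene list
  module <- integer(nG)
  if (cfg$nModules > 0) {
    startAt <- nG - cfg$nModules * cfg$moduleSize
    for (m in seq_len(cfg$nModules))
      module[startAt + (m - 1) * cfg$moduleSize + seq_len(cfg$moduleSize)] <- m
  }

  # -- subject-level stream: per-gene intercepts and date effects ---------
  # gene-specific (as the per-gene mixed model presumes); a purely global
  # per-sample shift would be absorbed by cpm normalization downstream
  set.seed(deriveSeed(cfg$seed, "subjects"))
  bSubj <- matrix(stats::rnorm(nG * nS, 0, cfg$sigmaSubject), nG, nS)
  bDate <- matrix(stats::rnorm(nG * nDates, 0, cfg$sigmaDate), nG, nDates)

  # -- latent module factors ---------------------------------------------
  set.seed(deriveSeed(cfg$seed, "factors"))
  fac <- matrix(stats::rnorm(cfg$nModules * nSamp), cfg$nModules, nSamp)

  # -- per-observation residual noise ------------------------------------
  set.seed(deriveSeed(cfg$seed, "noise"))
  eps <- matrix(stats::rnorm(nG * nSamp, 0, cfg$sigmaResid), nG, nSamp)

  # planted shift per (gene, sample) on the log2 scale
  shift <- matrix(0, nG, nSamp)
  isPea <- design$arm == "peanut"
  shift[, isPea & design$time == "T4"] <- delta
  shift[, isPea & design$time == "T2"] <- deltaT2
  if (cfg$nModules > 0) {
    rho <- cfg$moduleCor
    load <- cfg$sigmaResid * sqrt(rho / (1 - rho))
    inMod <- module > 0
    shift[inMod, ] <- shift[inMod, ] + load * fac[module[inMod], , drop = FALSE]
  }

  log2mu <- baseLog2Cpm + shift + eps +
    bSubj[, match(design$subject, subjects), drop = FALSE] +
    bDate[, dateIdx[sa], drop = FALSE]
  mu <- 2^log2mu * rep(libs / 1e6, each = nG)

  set.seed(deriveSeed(cfg$seed, "counts"))
  if (cfg$nbDispersion > 0) {
    counts <- matrix(stats::rnbinom(nG * nSamp, mu = mu,
                                    size = 1 / cfg$nbDispersion), nG, nSamp)
  } else {
    counts <- matrix(stats::rpois(nG * nSamp, mu), nG, nSamp)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes, design$sample)

  truth <- data.frame(gene = genes, isInteraction = seq_len(nG) %in% intIdx,
                      delta = delta, deltaT2 = deltaT2, module = module,
                      stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth)
}

#' Simulate convolved cell-type mixture expression
#'
#' Builds per-sample expression as `signature %*% fractions`, perturbs it by
#' multiplicative log-normal noise, and rescales each sample to integer
#' counts summing to `libSize`.
#'
#' @param signature Numeric matrix, genes x cell types.
#' @param fractions Numeric matrix, cell types x samples; each column must be
#'   non-negative and sum to 1 (tolerance 1e-6).
#' @param noiseSd SD of the log-normal noise on the natural-log scale.
#' @param seed Integer seed.
#' @param libSize Target per-sample count total (default 1e6).
#' @return Integer count matrix, genes x samples.
#' @examples
#' sig <- matrix(rexp(40, 1 / 50), 20, 2, dimnames = list(paste0("g", 1:20), c("A", "B")))
#' m <- simulateMixtures(sig, cbind(s1 = c(0.6, 0.4)), noiseSd = 0, seed = 1)
#' @export
simulateMixtures <- function(signature, fractions, noiseSd = 0.1, seed = 1,
                             libSize = 1e6) {
  signature <- as.matrix(signature)
  fractions <- as.matrix(fractions)
  if (nrow(fractions) != ncol(signature))
    stop("fraction rows must match signature cell types")
  if (any(fractions < 0))
    stop("fractions must be non-negative")
  bad <- abs(colSums(fractions) - 1) > 1e-6
  if (any(bad))
    stop("fraction vector(s) not summing to 1: ",
         paste(which(bad), collapse = ", "))
  mix <- signature %*% fractions
  set.seed(deriveSeed(seed, "mixture-noise"))
  if (noiseSd > 0)
    mix <- mix * exp(matrix(stats::rnorm(length(mix), 0, noiseSd),
                            nrow(mix), ncol(mix)))
  counts <- apply(mix, 2, function(x) round(x / sum(x) * libSize))
  storage.mode(counts) <- "integer"
  rownames(counts) <- rownames(signature)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("mix%02d", seq_len(ncol(counts)))
  counts
}

#' Simulate a causal gene layer: DAG, expression, and eQTL anchors
#'
#' Draws a random DAG (or uses a supplied edge set), then generates
#' expression by linear-Gaussian structural equations with edge weight
#' `cfg$dagEffect` and unit innovation variance. A fraction of root genes
#' receive an exogenous genotype covariate in `{0, 1, 2}` whose effect enters
#' their structural equation; these are the eQTL-anchored genes a structure
#' learner may treat as preferential parents.
#'
#' @param cfg A [simulationConfig()]; uses the `dag*`, `fracEqtl` and `seed`
#'   fields.
#' @param edges Optional two-column character matrix planting an exact DAG
#'   over nodes named in it (overrides the random DAG).
#' @param eqtlGenes Optional character vector forcing the eQTL gene set.
#' @return List with `network` (truth [GeneNetwork-class]), `expr` (numeric
#'   matrix, genes x samples), `eqtlGenes` (character), `genotypes`
#'   (matrix, eQTL genes x samples).
#' @examples
#' lay <- simulateCausalLayer(simulationConfig(dagNNodes = 5, dagNSamples = 100, seed = 3))
#' lay$network
#' @export
simulateCausalLayer <- function(cfg, edges = NULL, eqtlGenes = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(deriveSeed(cfg$seed, "dag"))
  if (is.null(edges)) {
    n <- cfg$dagNNodes
    nodes <- sprintf("N%02d", seq_len(n))
    topo <- sample(nodes)                      # topological order fixed by seed
    em <- matrix(character(), 0, 2)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      if (stats::runif(1) < cfg$dagEdgeProb)
        em <- rbind(em, c(topo[i], topo[j]))
    edges <- em
  } else {
    edges <- as.matrix(edges)
    nodes <- unique(as.vector(t(edges)))
  }
  net <- geneNetwork(edges, nodes = nodes)
  g <- asIgraph(net)
  topoOrder <- names(igraph::topo_sort(g, mode = "out"))

  parents <- lapply(stats::setNames(nodes, nodes), function(v)
    if (nrow(edges)) edges[edges[, 2] == v, 1] else character())
  roots <- nodes[lengths(parents) == 0]
  if (is.null(eqtlGenes)) {
    nEq <- round(cfg$fracEqtl * length(roots))
    eqtlGenes <- if (nEq > 0) sort(sample(roots, nEq)) else character()
  }

  set.seed(deriveSeed(cfg$seed, "sem"))
  nSamp <- cfg$dagNSamples
  geno <- matrix(stats::rbinom(length(eqtlGenes) * nSamp, 2, 0.35),
                 length(eqtlGenes), nSamp,
                 dimnames = list(eqtlGenes, NULL))
  expr <- matrix(0, length(nodes), nSamp, dimnames = list(nodes, NULL))
  for (v in topoOrder) {
    x <- stats::rnorm(nSamp)
    for (p in parents[[v]]) x <- x + cfg$dagEffect * expr[p, ]
    if (v %in% eqtlGenes) x <- x + cfg$dagEffect * (geno[v, ] - mean(geno[v, ]))
    expr[v, ] <- x
  }
  colnames(expr) <- sprintf("cs%03d", seq_len(nSamp))
  list(network = net, expr = expr, eqtlGenes = eqtlGenes, genotypes = geno)
}
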