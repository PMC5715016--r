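#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

ARM_LEVELS <- c("peanut", "placebo")
TIME_LEVELS <- c("T0", "T2", "T4")
ORDER_LEVELS <- c("peanut_first", "placebo_first")
DESIGN_COLS <- c("subject", "arm", "time", "order", "collectionDate", "epinephrine")

#' ChallengeExperiment: expression data from a crossover challenge study
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding gene-level
#' expression from a placebo-controlled crossover challenge design. Columns
#' are samples; `colData` must carry the sample design: `subject`, `arm`
#' (peanut/placebo), `time` (T0/T2/T4 hours from challenge start), `order`
#' (which challenge came first), `collectionDate`, and a logical
#' `epinephrine` flag. Raw objects carry a `counts` assay; normalized objects
#' additionally carry `log2cpm` and `weights` (per-observation precision
#' weights) assays plus a `normFactor` column in `colData`.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [ChallengeExperiment()], [normalizeChallenge()]
#' @export
setClass("ChallengeExperiment", contains = "SummarizedExperiment")

validChallengeExperiment <- function(object) {
  msg <- character()
  cd <- colData(object)
  miss <- setdiff(DESIGN_COLS, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing design columns:", paste(miss, collapse = ", ")))
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene symbols (rownames) must be present and unique")
  if (!length(msg)) {
    if (any(is.na(cd$arm)) || !all(cd$arm %in% ARM_LEVELS))
      msg <- c(msg, "'arm' must be 'peanut' or 'placebo', never missing")
    if (any(is.na(cd$time)) || !all(cd$time %in% TIME_LEVELS))
      msg <- c(msg, "'time' must be one of T0/T2/T4, never missing")
    tabs <- table(cd$subject)
    if (any(tabs > 6))
      msg <- c(msg, "a subject may contribute at most 6 samples (2 arms x 3 times)")
    if ("counts" %in% assayNames(object)) {
      cnt <- assay(object, "counts")
      if (any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "'counts' must be non-negative integers")
    }
    if ("weights" %in% assayNames(object)) {
      w <- assay(object, "weights")
      if (any(!is.finite(w)) || any(w <= 0))
        msg <- c(msg, "precision weights must be strictly positive and finite")
    }
    if ("normFactor" %in% colnames(cd)) {
      nf <- cd$normFactor
      if (any(nf <= 0) || abs(exp(mean(log(nf))) - 1) > 1e-8)
        msg <- c(msg, "norm factors must be positive with geometric mean 1")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("ChallengeExperiment", validChallengeExperiment)

#' Construct a ChallengeExperiment from counts and a sample design
#'
#' @param counts Integer matrix of read counts, genes x samples, with gene
#'   symbols as rownames and sample ids as colnames.
#' @param design `data.frame` of per-sample metadata with columns `subject`,
#'   `arm`, `time`, `order`, `collectionDate`, `epinephrine`; rows are matched
#'   to count columns by a `sample` column if present, else by rownames, else
#'   by position.
#' @return A validated [ChallengeExperiment-class] object with a `counts` assay.
#' @examples
#' sim <- simulateChallengeDataset(simulationConfig(nSubjects = 4, nGenes = 50, seed = 1))
#' ce <- ChallengeExperiment(sim$counts, sim$design)
#' ce
#' @export
ChallengeExperiment <- function(counts, design) {
  counts <- as.matrix(counts)
  design <- as.data.frame(design)
  if ("sample" %in% colnames(design)) {
    rownames(design) <- design$sample
    design$sample <- NULL
  }
  if (!is.null(rownames(design)) && !is.null(colnames(counts)) &&
      all(colnames(counts) %in% rownames(design))) {
    design <- design[colnames(counts), , drop = FALSE]
  } else if (nrow(design) == ncol(counts)) {
    rownames(design) <- colnames(counts)
  } else {
    stop("design rows cannot be matched to count columns")
  }
  design$arm <- as.character(design$arm)
  design$time <- as.character(design$time)
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(design))
  new("ChallengeExperiment", se)
}

setMethod("show", "ChallengeExperiment", function(object) {
  cd <- colData(object)
  cat("ChallengeExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  subjects:", length(unique(cd$subject)),
      "| arms:", paste(names(table(cd$arm)), table(cd$arm), collapse = ", "),
      "| times:", paste(names(table(cd$time)), table(cd$time), collapse = ", "), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  if ("normFactor" %in% colnames(cd)) cat("  normalized: yes\n")
})

#' Accessors for ChallengeExperiment content
#'
#' `log2cpm()` and `precisionWeights()` return the normalized expression and
#' per-observation weight assays; `normFactors()` the per-sample composition
#' normalization factors; `sampleDesign()` the design table as a `data.frame`.
#'
#' @param object A [ChallengeExperiment-class].
#' @return A matrix, numeric vector, or `data.frame` as described.
#' @name challenge-accessors
NULL

#' @rdname challenge-accessors
#' @export
log2cpm <- function(object) {
  if (!"log2cpm" %in% assayNames(object))
    stop("object has no 'log2cpm' assay; run normalizeChallenge() first")
  assay(object, "log2cpm")
}

#' @rdname challenge-accessors
#' @export
precisionWeights <- function(object) {
  if (!"weights" %in% assayNames(object))
    stop("object has no 'weights' assay; run normalizeChallenge() first")
  assay(object, "weights")
}

#' @rdname challenge-accessors
#' @export
normFactors <- function(object) {
  cd <- colData(object)
  if (!"normFactor" %in% colnames(cd))
    stop("object has no norm factors; run normalizeChallenge() first")
  stats::setNames(cd$normFactor, rownames(cd))
}

#' @rdname challenge-accessors
#' @export
sampleDesign <- function(object) {
  as.data.frame(colData(object))[, intersect(c(DESIGN_COLS, "normFactor"),
                                             colnames(colData(object))),
                                 drop = FALSE]
}

#' GeneNetwork: a directed graph over gene symbols
#'
#' Lightweight S4 container for directed gene-gene networks: causal networks
#' from structure learning, literature edge lists, and key-driver annotated
#' subnetworks. Self-loops are forbidden; structure-learner output is
#' additionally acyclic. Node annotations (key-driver flag, FDR, path level,
#' membership flags) live in `nodeData`.
#'
#' @slot nodes Character vector of gene symbols.
#' @slot edges Two-column character matrix of directed edges (from, to).
#' @slot nodeData `data.frame` of node annotations, rownames = nodes.
#' @export
setClass("GeneNetwork",
         representation(nodes = "character", edges = "matrix",
                        nodeData = "data.frame"))

setValidity("GeneNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e)) {
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loops are not allowed")
    if (!all(e %in% object@nodes)) msg <- c(msg, "edges reference unknown nodes")
    if (anyDuplicated(paste(e[, 1], e[, 2], sep = "\r")))
      msg <- c(msg, "duplicate edges are not allowed")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate nodes")
  if (nrow(object@nodeData) &&
      !identical(sort(rownames(object@nodeData)), sort(object@nodes)))
    msg <- c(msg, "nodeData rownames must match nodes")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneNetwork
#'
#' @param edges Two-column character matrix or data.frame of directed edges.
#'   Self-loops are dropped (with a message) and duplicate edges collapsed.
#' @param nodes Optional character vector of nodes; defaults to the union of
#'   edge endpoints. Isolated nodes may be included here.
#' @param nodeData Optional `data.frame` of node annotations.
#' @return A validated [GeneNetwork-class].
#' @examples
#' net <- geneNetwork(cbind(c("A", "B"), c("B", "C")))
#' net
#' @export
geneNetwork <- function(edges = matrix(character(), 0, 2), nodes = NULL,
                        nodeData = NULL) {
  edges <- as.matrix(edges)
  if (nrow(edges)) {
    mode(edges) <- "character"
    self <- edges[, 1] == edges[, 2]
    if (any(self)) {
      message(sum(self), " self-loop(s) dropped")
      edges <- edges[!self, , drop = FALSE]
    }
    edges <- edges[!duplicated(paste(edges[, 1], edges[, 2], sep = "\r")), ,
                   drop = FALSE]
  }
  if (is.null(nodes)) nodes <- unique(as.vector(t(edges)))
  nodes <- unique(as.character(nodes))
  if (is.null(nodeData)) nodeData <- data.frame(row.names = nodes)
  dimnames(edges) <- list(NULL, c("from", "to"))
  new("GeneNetwork", nodes = nodes, edges = edges, nodeData = nodeData)
}

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork:", length(object@nodes), "nodes,", nrow(object@edges),
      "directed edges\n")
  if (ncol(object@nodeData))
    cat("  node annotations:", paste(colnames(object@nodeData), collapse = ", "), "\n")
})

#' @rdname networkAccessors
#' @export
networkNodes <- function(network) network@nodes

#' Access GeneNetwork nodes, edges and annotations
#'
#' @param network A [GeneNetwork-class].
#' @return `networkNodes()`: character vector; `networkEdges()`: two-column
#'   character matrix; `nodeData()`: `data.frame` of annotations.
#' @name networkAccessors
#' @export
networkEdges <- function(network) network@edges

#' @rdname networkAccessors
#' @export
nodeData <- function(network) network@nodeData

# Internal: igraph view of a GeneNetwork (directed).
asIgraph <- function(network) {
  igraph::graph_from_data_frame(
    as.data.frame(network@edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = network@nodes, stringsAsFactors = FALSE))
}
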