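#' Project a target gene set onto a directed network
#'
#' Seeds are the targets present in the network; the seed set is expanded by
#' all nodes adjacent to a seed (ignoring edge direction, path length one),
#' the subgraph induced on the expanded set is taken, and its largest weakly
#' connected component is returned (ties broken by the lexicographically
#' smallest node set).
#'
#' @param network A [GeneNetwork-class].
#' @param targets Character vector of target gene symbols.
#' @return A [GeneNetwork-class] subnetwork whose `nodeData` carries an
#'   `inTargets` flag.
#' @export
projectTargets <- function(network, targets) {
  seeds <- intersect(unique(targets), networkNodes(network))
  if (!length(seeds))
    stop("no target genes present in the network")
  g <- asIgraph(network)
  nb <- unique(unlist(lapply(
    igraph::ego(g, order = 1, nodes = seeds, mode = "all"), names)))
  sub <- igraph::induced_subgraph(g, nb)
  comp <- igraph::components(sub, mode = "weak")
  sizes <- comp$csize
  bestSize <- max(sizes)
  candidates <- which(sizes == bestSize)
  membSets <- lapply(candidates, function(ci)
    sort(names(comp$membership)[comp$membership == ci]))
  pick <- candidates[order(vapply(membSets, paste, character(1),
                                  collapse = "\r"))[1]]
  keep <- names(comp$membership)[comp$membership == pick]
  sub2 <- igraph::induced_subgraph(sub, keep)
  el <- igraph::as_edgelist(sub2)
  nodes <- igraph::V(sub2)$name
  nd <- data.frame(inTargets = nodes %in% seeds, row.names = nodes)
  geneNetwork(el, nodes = nodes, nodeData = nd)
}

# Internal: directed descendants of h within k steps (h excluded).
descendantsWithin <- function(g, h, k) {
  setdiff(names(igraph::ego(g, order = k, nodes = h, mode = "out")[[1]]), h)
}

#' Key driver analysis
#'
#' Defines a background subnetwork as the union of undirected K-step
#' neighborhoods of the target nodes; for each candidate node in the
#' background and each `k` in `1..K`, tests the enrichment of the node's
#' directed k-step downstream neighborhood for the target set with a
#' one-sided Fisher exact test over the background universe (the candidate
#' itself excluded). Each node's p is the minimum over k (recorded with
#' `bestK`); BH FDR is applied across candidates and drivers are called at
#' `fdr < fdrCut`. A Bonferroni-over-k adjustment of the inner minimum is
#' available via `adjustK`.
#'
#' @param network A [GeneNetwork-class].
#' @param targets Character vector of target genes.
#' @param K Maximum path length (default 7).
#' @param universe `"background"` (default) or `"network"`: the Fisher
#'   universe.
#' @param fdrCut Driver FDR threshold (default 0.05).
#' @param adjustK Multiply the minimum p by K (Bonferroni over the inner
#'   scan)? Default `FALSE`.
#' @return `data.frame`, one row per background node: `gene`, `bestK`,
#'   `downstreamCount`, `overlapWithTargets`, `fisherP`, `fdr`,
#'   `isKeyDriver`, sorted by `fisherP`.
#' @export
keyDriverAnalysis <- function(network, targets, K = 7,
                              universe = c("background", "network"),
                              fdrCut = 0.05, adjustK = FALSE) {
  if (K < 1) stop("K must be >= 1")
  universe <- match.arg(universe)
  targets <- unique(targets)
  seeds <- intersect(targets, networkNodes(network))
  if (!length(seeds)) stop("no target genes present in the network")
  g <- asIgraph(network)
  bg <- unique(unlist(lapply(
    igraph::ego(g, order = K, nodes = seeds, mode = "all"), names)))
  uni <- if (universe == "background") bg else networkNodes(network)
  rows <- lapply(sort(bg), function(h) {
    uniH <- setdiff(uni, h)
    targH <- intersect(targets, uniH)
    bestP <- 1
    bestK <- 1L
    bestDown <- 0L
    bestOv <- 0L
    for (k in seq_len(K)) {
      down <- intersect(descendantsWithin(g, h, k), uniH)
      ov <- length(intersect(down, targH))
      p <- if (!length(down)) 1 else
        moduleEnrichmentCounts(ov, length(down), length(targH),
                               length(uniH))$fisherP
      if (p < bestP) {
        bestP <- p
        bestK <- k
        bestDown <- length(down)
        bestOv <- ov
      }
    }
    data.frame(gene = h, bestK = bestK, downstreamCount = bestDown,
               overlapWithTargets = bestOv,
               fisherP = if (adjustK) min(1, bestP * K) else bestP,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$fisherP, method = "BH")
  out$isKeyDriver <- out$fdr < fdrCut
  out[order(out$fisherP, out$gene), , drop = FALSE]
}

#' Assign hierarchical path levels in a subnetwork
#'
#' Level of a node = length of the longest directed path from it to any sink
#' (sinks have level 0), so the "top level" contains the most upstream
#' regulators. Cycles, if present, are first broken by removing a greedily
#' found small feedback edge set, with a warning.
#'
#' @param subnetwork A [GeneNetwork-class].
#' @return Named integer vector: gene -> level.
#' @export
assignLevels <- function(subnetwork) {
  g <- asIgraph(subnetwork)
  if (!igraph::is_dag(g)) {
    fas <- igraph::feedback_arc_set(g, algo = "approx_eades")
    warning("subnetwork has cycles; removed ", length(fas),
            " feedback edge(s) before level assignment")
    g <- igraph::delete_edges(g, fas)
  }
  nodes <- igraph::V(g)$name
  topo <- names(igraph::topo_sort(g, mode = "in"))   # sinks first
  lev <- stats::setNames(integer(length(nodes)), nodes)
  for (v in topo) {
    succ <- names(igraph::neighbors(g, v, mode = "out"))
    lev[v] <- if (length(succ)) 1L + max(lev[succ]) else 0L
  }
  lev
}

#' Per-level key-driver enrichment
#'
#' For each path level, builds the 2x2 table of (at level vs not) by (driver
#' vs not), applies a Haldane 0.5 correction when any cell is zero, and
#' reports the odds ratio with the two-sided Fisher exact p of the
#' uncorrected table.
#'
#' @param levels Named integer vector from [assignLevels()].
#' @param drivers Character vector of key-driver genes (or named logical over
#'   the same node set).
#' @return `data.frame`: `level`, `nAtLevel`, `nDrivers`, `or`, `fisherP`,
#'   sorted by decreasing level.
#' @export
levelEnrichment <- function(levels, drivers) {
  if (is.logical(drivers)) drivers <- names(drivers)[drivers]
  nodes <- names(levels)
  isDrv <- nodes %in% drivers
  rows <- lapply(sort(unique(levels), decreasing = TRUE), function(l) {
    atL <- levels == l
    res <- overlapOddsRatio(sum(atL & isDrv), sum(atL),
                            sum(!atL & isDrv), sum(!atL))
    data.frame(level = l, nAtLevel = sum(atL), nDrivers = sum(atL & isDrv),
               or = res$or, fisherP = res$p)
  })
  do.call(rbind, rows)
}

#' Overlap of two key-driver sets
#'
#' 2x2 overlap odds ratio and Fisher exact p for two driver sets over a
#' common gene universe (delegates to [overlapOddsRatio()]; identical sets
#' yield an infinite sample odds ratio, reported as the Haldane-corrected
#' finite estimate).
#'
#' @param driversA,driversB Character vectors of genes, subsets of `universe`.
#' @param universe Character vector of eligible genes.
#' @return List with `or`, `p`, and `table`.
#' @export
compareDriverSets <- function(driversA, driversB, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  a <- intersect(unique(driversA), universe)
  b <- intersect(unique(driversB), universe)
  overlapOddsRatio(length(intersect(a, b)), length(b),
                   length(setdiff(a, b)), length(universe) - length(b))
}
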