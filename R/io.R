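#' Read a gene-level count matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene symbols and
#' whose header row holds sample ids; all cells must be non-negative
#' integers. Row and column order are preserved. Gene identity is the bare
#' symbol string, case-sensitive.
#'
#' @param path Path to a counts TSV.
#' @return Integer matrix, genes x samples, dimnames set.
#' @seealso [writeCounts()]
#' @export
readCounts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("counts file needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene symbol(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(m)[bad[1, 2]]))
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a count matrix as TSV
#'
#' Canonical formatting: a `gene` first column, tab separation, no quoting.
#' `readCounts(writeCounts(x))` is an identity.
#'
#' @param counts Integer matrix, genes x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata for a challenge study
#'
#' Columns are matched by name, not position; required columns are `sample`,
#' `subject`, `arm`, `time`, `order`, `collectionDate`, `epinephrine`.
#' The string "." denotes missing in optional metadata fields.
#'
#' @param path Path to a metadata TSV.
#' @return `data.frame` with one row per sample.
#' @export
readSampleDesign <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample", "subject", "arm", "time", "order", "collectionDate",
            "epinephrine")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing metadata columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicate sample id(s): ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (any(df$arm == "." | df$time == "."))
    stop("'arm' and 'time' must never be missing")
  if (!all(df$arm %in% ARM_LEVELS)) stop("'arm' must be peanut or placebo")
  if (!all(df$time %in% TIME_LEVELS)) stop("'time' must be one of T0/T2/T4")
  df$epinephrine <- df$epinephrine %in% c("TRUE", "true", "1", "yes")
  df
}

#' Write sample metadata TSV
#' @param design `data.frame` as returned by [readSampleDesign()] or
#'   [simulateChallengeDataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSampleDesign <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member symbols.
#' Duplicate members within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per set); each carries its
#'   description in the `"description"` attribute.
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop(sprintf("line %d: GMT lines need name, description and >=1 member", i))
    genes <- unique(f[-(1:2)])
    attr(genes, "description") <- f[2]
    sets[[f[1]]] <- genes
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    desc <- attr(genes, "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, unique(as.character(genes))), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed edge list (TSV or SIF)
#'
#' Accepts a two-column source/target TSV (with or without a header) or
#' three-column SIF (source, relation, target). Self-loops are dropped with a
#' message; duplicate edges collapse.
#'
#' @param path Path to an edge list.
#' @return A [GeneNetwork-class].
#' @seealso [writeEdgeList()]
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(geneNetwork())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  start <- 1L
  if (identical(tolower(parts[[1]][1]), "from") ||
      identical(tolower(parts[[1]][1]), "source")) start <- 2L
  edges <- matrix(character(), 0, 2)
  for (i in seq(start, length.out = length(lines) - start + 1L)) {
    f <- parts[[i]]
    if (nf[i] == 2L) edges <- rbind(edges, f)
    else if (nf[i] == 3L) edges <- rbind(edges, f[c(1L, 3L)])
    else stop(sprintf("line %d: expected 2 (TSV) or 3 (SIF) fields, got %d",
                      i, nf[i]))
  }
  # endpoints of dropped self-loops remain as isolated nodes
  geneNetwork(edges, nodes = unique(as.vector(t(edges))))
}

#' Write a GeneNetwork as a two-column directed edge TSV
#' @param network A [GeneNetwork-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(network, path) {
  df <- as.data.frame(networkEdges(network), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a leukocyte signature matrix from TSV
#'
#' First column gene symbols, header row cell-type labels, non-negative
#' reference expression values. At least two cell types are required and no
#' cell type may be all-zero.
#'
#' @param path Path to a signature TSV.
#' @return Numeric matrix, signature genes x cell types.
#' @export
readSignature <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("duplicate signature gene symbols")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(m) < 2) stop("signature matrix needs >=2 cell types")
  if (any(m < 0)) stop("signature values must be non-negative")
  zero <- colSums(m) == 0
  if (any(zero))
    stop("all-zero signature column(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  rownames(m) <- genes
  m
}

#' Write a signature matrix as TSV
#' @param signature Numeric matrix, genes x cell types.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSignature <- function(signature, path) {
  df <- data.frame(gene = rownames(signature), signature, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
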