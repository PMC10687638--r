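## Thresholded Pearson coexpression network and Leiden modules.

#' Filter to the most variable expressed genes
#'
#' Keeps genes whose maximum TPM exceeds `minTPM` in at least one sample,
#' ranks them by variance of their log2(TPM + 1) profile, and keeps the
#' top fraction (ceiling).
#'
#' @param tpm TPM matrix (genes x samples).
#' @param minTPM expression floor (default 1, i.e. TPM > 1 somewhere).
#' @param topFraction fraction of expressed genes kept (default 0.2).
#' @return character vector of selected gene ids.
#' @export
filterVariableGenes <- function(tpm, minTPM = 1, topFraction = 0.2) {
  expressed <- rownames(tpm)[apply(tpm, 1, max) > minTPM]
  if (!length(expressed))
    stop("no gene has TPM > ", minTPM,
      "; lower minTPM or check the expression matrix")
  v <- apply(log2(tpm[expressed, , drop = FALSE] + 1), 1, var)
  keep <- ceiling(topFraction * length(expressed))
  expressed[order(-v, expressed)][seq_len(keep)]
}

#' Pearson correlation edges above a threshold
#'
#' Correlations are computed on log2(TPM + 1) per-sample profiles; pairs
#' with r strictly above `rThreshold` become edges (signed: negative
#' correlations are never edges). Zero-variance genes are excluded with a
#' warning.
#'
#' @param tpm TPM matrix restricted to the filtered gene set.
#' @param rThreshold edge threshold (default 0.7).
#' @param averageReplicates if `TRUE` with `condition` given, correlate
#'   condition means instead of per-sample values.
#' @param condition optional sample grouping for `averageReplicates`.
#' @return a [S4Vectors::DataFrame] with columns geneA, geneB, r
#'   (geneA < geneB; each unordered pair once).
#' @export
correlationEdges <- function(tpm, rThreshold = 0.7,
                             averageReplicates = FALSE, condition = NULL) {
  mat <- log2(as.matrix(tpm) + 1)
  if (averageReplicates) {
    if (is.null(condition)) stop("condition required to average replicates")
    mat <- t(apply(mat, 1, function(z) tapply(z, condition, mean)))
  }
  if (ncol(mat) < 3)
    stop("need >= 3 observations per gene for correlation")
  vz <- apply(mat, 1, sd) == 0
  if (any(vz)) {
    warning(sum(vz), " zero-variance gene(s) excluded")
    mat <- mat[!vz, , drop = FALSE]
  }
  cc <- cor(t(mat))
  ut <- upper.tri(cc)
  hit <- which(ut & cc > rThreshold, arr.ind = TRUE)
  DataFrame(
    geneA = rownames(cc)[hit[, 1]],
    geneB = rownames(cc)[hit[, 2]],
    r = cc[hit])
}

#' Leiden community detection on the edge list
#'
#' Runs Leiden with the modularity objective (edges weighted by r) under a
#' fixed seed; genes in `genes` that carry no edge become singleton
#' modules. Module ids are reassigned in decreasing size order.
#'
#' @param edges edge DataFrame/data.frame (geneA, geneB, r).
#' @param genes node set to partition; defaults to the genes on edges.
#' @param resolution Leiden resolution (default 1).
#' @param seed RNG seed (mandatory for a deterministic partition).
#' @return named integer vector, gene -> module id.
#' @export
detectModules <- function(edges, genes = NULL, resolution = 1, seed = 1) {
  onEdges <- unique(c(edges$geneA, edges$geneB))
  if (is.null(genes)) genes <- onEdges
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$geneA, to = edges$geneB),
    directed = FALSE, vertices = data.frame(name = genes))
  memb <- .withSeed(seed, {
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
      resolution = resolution, weights = edges$r,
      n_iterations = 3)
    igraph::membership(cl)
  })
  ## relabel by size, largest module first; ties by first gene id
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), names(sizes))
  relabel <- structure(seq_along(ord), names = names(sizes)[ord])
  structure(as.integer(relabel[as.character(memb)]), names = names(memb))
}

#' Build the full coexpression network
#'
#' Filter variable genes, threshold Pearson correlations, detect Leiden
#' modules; one call per the usual workflow.
#'
#' @inheritParams filterVariableGenes
#' @inheritParams correlationEdges
#' @inheritParams detectModules
#' @return a [CoexpressionNetwork-class].
#' @export
buildCoexpressionNetwork <- function(tpm, minTPM = 1, topFraction = 0.2,
                                     rThreshold = 0.7, resolution = 1,
                                     seed = 1, averageReplicates = FALSE,
                                     condition = NULL) {
  sel <- filterVariableGenes(tpm, minTPM, topFraction)
  edges <- correlationEdges(tpm[sel, , drop = FALSE], rThreshold,
    averageReplicates, condition)
  mods <- detectModules(edges, genes = sel, resolution = resolution,
    seed = seed)
  new("CoexpressionNetwork", edges = edges, modules = mods,
    params = list(minTPM = minTPM, topFraction = topFraction,
      rThreshold = rThreshold, resolution = resolution, seed = seed,
      averageReplicates = averageReplicates,
      correlationScale = "log2(TPM + 1), per-sample values"))
}

#' Per-module differential-expression counts
#'
#' @param modules named integer vector (gene -> module) or a
#'   [CoexpressionNetwork-class].
#' @param deResults output of [deTest()] (gene, call). Module genes
#'   absent from the DE table count toward size only (with a message).
#' @return a [S4Vectors::DataFrame]: module, size, nUp, nDown, sorted by
#'   module id.
#' @export
moduleDESummary <- function(modules, deResults) {
  if (is(modules, "CoexpressionNetwork")) modules <- modules(modules)
  if (!length(modules))
    return(DataFrame(module = integer(), size = integer(),
      nUp = integer(), nDown = integer()))
  calls <- structure(as.character(deResults$call),
    names = as.character(deResults$gene))
  absent <- setdiff(names(modules), names(calls))
  if (length(absent))
    message(length(absent), " module gene(s) absent from the DE table")
  ids <- sort(unique(modules))
  res <- DataFrame(
    module = ids,
    size = vapply(ids, function(m) sum(modules == m), integer(1)),
    nUp = vapply(ids, function(m)
      sum(calls[intersect(names(modules)[modules == m],
        names(calls))] == "up"), integer(1)),
    nDown = vapply(ids, function(m)
      sum(calls[intersect(names(modules)[modules == m],
        names(calls))] == "down"), integer(1)))
  res
}
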