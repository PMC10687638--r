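## Hypergeometric over-representation of terms in a gene set.

#' Hypergeometric term enrichment
#'
#' One-sided over-representation test: for a term carried by K of the N
#' background genes and k of the n set genes, p = P(X >= k) with
#' X ~ Hypergeometric(N, K, n). Terms absent from the set (k = 0) are
#' skipped; p-values are BH-adjusted across the tested terms.
#'
#' @param geneSet character vector of genes to test (must be a subset of
#'   `background`).
#' @param termMap data.frame/DataFrame with columns `gene`, `term` (an
#'   optional `name` column is carried through).
#' @param background character vector, the gene universe (typically all
#'   genes in the count matrix). Background genes without any term are
#'   allowed (and reported via a message).
#' @return a [S4Vectors::DataFrame] sorted by q then p: term, k, K, n, N,
#'   p, q.
#' @examples
#' tm <- data.frame(gene = paste0("g", 1:5), term = "T1")
#' hypergeomEnrich(paste0("g", 1:5), tm, paste0("g", 1:20))$p
#' # 1 / choose(20, 5)
#' @export
hypergeomEnrich <- function(geneSet, termMap, background) {
  geneSet <- unique(as.character(geneSet))
  background <- unique(as.character(background))
  if (!length(geneSet)) stop("empty gene set")
  if (!length(background)) stop("empty background")
  out <- setdiff(geneSet, background)
  if (length(out))
    stop("gene set is not a subset of the background (e.g. ",
      out[1], ")")
  termMap <- as.data.frame(termMap)
  termMap <- termMap[termMap$gene %in% background, , drop = FALSE]
  uncovered <- length(setdiff(background, termMap$gene))
  if (uncovered)
    message(uncovered, " background gene(s) carry no term")
  N <- length(background)
  n <- length(geneSet)
  terms <- split(unique(termMap[, c("gene", "term")])$gene,
    unique(termMap[, c("gene", "term")])$term)
  k <- vapply(terms, function(g) length(intersect(g, geneSet)), integer(1))
  K <- lengths(terms)
  keep <- k > 0
  if (!any(keep))
    return(DataFrame(term = character(), k = integer(), K = integer(),
      n = integer(), N = integer(), p = numeric(), q = numeric()))
  k <- k[keep]; K <- K[keep]
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- DataFrame(term = names(k), k = unname(k), K = unname(K),
    n = n, N = N, p = unname(p), q = unname(bhAdjust(p)))
  res[order(res$q, res$p, res$term), ]
}
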