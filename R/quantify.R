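## Expression quantification: FPKM, TPM, and TMM between-sample factors.

.countsAndLengths <- function(x, lengths) {
  if (is(x, "HomeologExperiment")) {
    if (is.null(lengths)) lengths <- geneLengths(x)
    x <- counts(x)
  }
  x <- as.matrix(x)
  if (is.null(lengths))
    stop("gene lengths are required (length_bp rowData or 'lengths')")
  miss <- setdiff(rownames(x), names(lengths))
  if (length(miss))
    stop("no length for gene(s): ", paste(head(miss), collapse = ", "))
  lengths <- lengths[rownames(x)]
  if (any(is.na(lengths) | lengths <= 0))
    stop("non-positive or missing length for gene(s): ",
      paste(head(rownames(x)[is.na(lengths) | lengths <= 0]),
        collapse = ", "))
  list(counts = x, lengths = as.numeric(lengths))
}

#' Compute FPKM
#'
#' FPKM(g, s) = count(g, s) * 1e9 / (librarySize(s) * length(g)), with the
#' library size taken as the column sum (or `libSizes` if supplied).
#'
#' @param x a [HomeologExperiment-class] or a count matrix.
#' @param lengths named numeric gene lengths in bp; taken from `rowData`
#'   when `x` is a `HomeologExperiment`.
#' @param libSizes optional per-sample library sizes; default column sums.
#' @return numeric matrix of FPKM values with attribute `unit = "FPKM"`.
#' @examples
#' cts <- matrix(c(100, 0), 1, 2, dimnames = list("g1", c("a", "b")))
#' computeFPKM(rbind(cts, g2 = c(9999900, 50)),
#'   lengths = c(g1 = 2000, g2 = 1000))["g1", "a"]  # 5.0
#' @export
computeFPKM <- function(x, lengths = NULL, libSizes = NULL) {
  cl <- .countsAndLengths(x, lengths)
  if (is.null(libSizes)) libSizes <- colSums(cl$counts)
  if (any(libSizes <= 0))
    stop("zero library size in sample(s): ",
      paste(colnames(cl$counts)[libSizes <= 0], collapse = ", "))
  fpkm <- sweep(cl$counts / cl$lengths, 2, libSizes, "/") * 1e9
  attr(fpkm, "unit") <- "FPKM"
  fpkm
}

#' Compute TPM
#'
#' TPM(g, s) = rate(g, s) / sum_g rate(g, s) * 1e6 with rate =
#' count / length; columns sum to 1e6. An all-zero sample yields an
#' all-zero column with a warning.
#'
#' @inheritParams computeFPKM
#' @return numeric matrix of TPM values with attribute `unit = "TPM"`.
#' @export
computeTPM <- function(x, lengths = NULL) {
  cl <- .countsAndLengths(x, lengths)
  rate <- cl$counts / cl$lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample(s): ",
      paste(colnames(cl$counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  attr(tpm, "unit") <- "TPM"
  tpm
}

## One TMM factor: sample obs vs sample ref (canonical doubly trimmed
## weighted mean of library-normalized log ratios).
.tmmPair <- function(obs, ref, libObs, libRef,
                     logratioTrim = 0.3, sumTrim = 0.05, minGenes = 10L) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  M <- log2((obs / libObs) / (ref / libRef))
  A <- 0.5 * log2((obs / libObs) * (ref / libRef))
  w <- (libObs - obs) / (libObs * obs) + (libRef - ref) / (libRef * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (sum(keep) < minGenes) {
    warning("fewer than ", minGenes,
      " genes survive TMM trimming; factor set to 1")
    return(1)
  }
  if (max(abs(M[keep])) < 1e-6) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: per sample, M = library-normalized log2 ratios
#' and A = average log abundances versus a reference sample, computed on
#' genes positive in both; 30% of extreme M and 5% of extreme A values are
#' trimmed and the factor is 2 to the inverse-variance-weighted mean of the
#' remaining M. Factors are rescaled to geometric mean 1. The reference
#' defaults to the sample whose scaled upper-quartile count is closest to
#' the mean upper quartile.
#'
#' @param x a [HomeologExperiment-class] or a count matrix (>= 2 samples).
#' @param reference reference sample name or index; `NULL` for automatic.
#' @param libSizes optional per-sample library sizes; default column sums.
#' @param logratioTrim fraction of extreme M values trimmed each side (0.3).
#' @param sumTrim fraction of extreme A values trimmed each side (0.05).
#' @return named numeric factors with geometric mean 1.
#' @export
tmmFactors <- function(x, reference = NULL, libSizes = NULL,
                       logratioTrim = 0.3, sumTrim = 0.05) {
  if (is(x, "HomeologExperiment")) x <- counts(x)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("TMM requires at least 2 samples")
  if (is.null(libSizes)) libSizes <- colSums(x)
  if (is.null(reference)) {
    q75 <- vapply(seq_len(ncol(x)),
      function(j) quantile(x[, j], 0.75) / libSizes[j], numeric(1))
    reference <- which.min(abs(q75 - mean(q75)))
  } else if (is.character(reference)) {
    reference <- match(reference, colnames(x))
  }
  f <- vapply(seq_len(ncol(x)), function(j) {
    if (j == reference) return(1)
    .tmmPair(x[, j], x[, reference], libSizes[j], libSizes[reference],
      logratioTrim, sumTrim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  f
}

#' Read gene lengths from a two-column TSV (gene, length_bp)
#'
#' @param file path to a TSV with columns `gene` and `length_bp`.
#' @return named numeric vector of lengths.
#' @export
readGeneLengths <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("gene", "length_bp") %in% colnames(d)))
    stop("lengths TSV needs columns 'gene' and 'length_bp'")
  structure(as.numeric(d$length_bp), names = d$gene)
}

#' Derive gene lengths from a GFF3 annotation
#'
#' Sums exon widths (1-based inclusive coordinates) per transcript and
#' takes, for each gene, the exon-length sum of its longest transcript.
#'
#' @param file path to a GFF3 file.
#' @return named numeric vector, gene id -> length in bp.
#' @export
geneLengthsFromGFF <- function(file) {
  gff <- rtracklayer::import(file, format = "gff3")
  ex <- gff[tolower(as.character(gff$type)) == "exon"]
  if (!length(ex)) stop("no exon features in ", file)
  parent <- vapply(ex$Parent, function(p) p[1], character(1))
  txLen <- tapply(BiocGenerics::width(ex), parent, sum)
  tx <- gff[tolower(as.character(gff$type)) %in%
    c("mrna", "transcript")]
  txGene <- structure(
    vapply(tx$Parent, function(p)
      if (length(p)) p[1] else NA_character_, character(1)),
    names = tx$ID)
  gene <- txGene[names(txLen)]
  gene[is.na(gene)] <- names(txLen)[is.na(gene)]  # exons parented by genes
  res <- tapply(as.numeric(txLen), gene, max)
  structure(as.numeric(res), names = names(res))
}
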