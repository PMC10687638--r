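## Control-condition dominance classification of homeolog triplets.
##
## A triplet's three copies are ranked by mean FPKM under control
## conditions (ties broken lexicographically by gene id). Class 1: the top
## copy beats BOTH others (p < 0.01 and FPKM fold change > 2). Class 2:
## the top two copies EACH beat the third (same thresholds) without the
## top-vs-mid pair satisfying the Class 1 condition. Class 3: all three
## pairwise fold changes < 1.5. Anything else is unclassified. Classes
## additionally require at least 1, 2 and 3 expressed copies respectively.

#' Count expressed copies of a triplet
#'
#' @param means numeric control-condition mean FPKM of the three copies.
#' @param expressedThreshold a copy is expressed when its mean exceeds
#'   this (default 0, i.e. any positive mean counts).
#' @return integer in 0..3.
#' @examples
#' presenceCategory(c(5, 3, 0))            # 2
#' presenceCategory(c(0.4, 0.4, 0.4), 0.5) # 0
#' @export
presenceCategory <- function(means, expressedThreshold = 0) {
  sum(means > expressedThreshold)
}

.pairFC <- function(a, b) {
  if (a == 0 && b == 0) return(1)
  if (min(a, b) == 0) return(Inf)
  max(a, b) / min(a, b)
}

#' Classify one triplet from means, pairwise p-values and fold changes
#'
#' @param means named numeric length 3, control mean FPKM per copy.
#' @param pairP,pairFC numeric length 3 in the pair order (1,2), (1,3),
#'   (2,3) of `means`; fold changes are >= 1 (larger over smaller).
#' @param presence expressed-copy count; computed from `means` when `NULL`.
#' @param pThreshold,fcDominant,fcSimilar rule thresholds (0.01, 2, 1.5).
#' @return one of "class1", "class2", "class3", "unclassified".
#' @examples
#' classifyTriplet(c(a = 20, b = 5, c = 4),
#'   pairP = c(0.001, 0.001, 0.4), pairFC = c(4, 5, 1.25))  # class1
#' @export
classifyTriplet <- function(means, pairP, pairFC, presence = NULL,
                            pThreshold = 0.01, fcDominant = 2,
                            fcSimilar = 1.5) {
  stopifnot(length(means) == 3, length(pairP) == 3, length(pairFC) == 3)
  if (is.null(names(means))) names(means) <- as.character(1:3)
  if (is.null(presence)) presence <- presenceCategory(means)
  P <- matrix(1, 3, 3); FC <- matrix(1, 3, 3)
  idx <- rbind(c(1, 2), c(1, 3), c(2, 3))
  P[idx] <- pairP; P[idx[, 2:1]] <- pairP
  FC[idx] <- pairFC; FC[idx[, 2:1]] <- pairFC
  o <- order(-means, names(means))  # descending, lexicographic tie-break
  top <- o[1]; mid <- o[2]; low <- o[3]
  beats <- function(i, j) P[i, j] < pThreshold & FC[i, j] > fcDominant
  if (presence >= 1 && beats(top, mid) && beats(top, low))
    return("class1")
  if (presence >= 2 && beats(top, low) && beats(mid, low))
    return("class2")
  if (presence == 3 && all(FC[idx] < fcSimilar))
    return("class3")
  "unclassified"
}

#' Pairwise exact tests between the copies of a triplet
#'
#' Comparing two different genes' counts requires removing length bias:
#' the (already library-equalized) pseudo-counts are scaled to per-kilobase
#' pseudo-counts and rounded before the NB exact test. The reported fold
#' change is the ratio of mean FPKMs (>= 1 orientation). Both copies zero
#' in all samples gives p = 1 and FC = 1.
#'
#' @param pseudo matrix of library-equalized pseudo-counts (control
#'   samples), rows = the three member genes.
#' @param fpkmMeans numeric length 3, mean control FPKM per copy.
#' @param lengths numeric length 3, gene lengths in bp.
#' @param phi common dispersion.
#' @return list with `p` and `fc`, each length 3 in pair order (1,2),
#'   (1,3), (2,3).
#' @export
pairwiseHomeologTests <- function(pseudo, fpkmMeans, lengths, phi) {
  stopifnot(nrow(pseudo) == 3, length(lengths) == 3)
  perKb <- round(pseudo * 1000 / lengths)
  idx <- rbind(c(1, 2), c(1, 3), c(2, 3))
  p <- numeric(3); fc <- numeric(3)
  for (k in 1:3) {
    i <- idx[k, 1]; j <- idx[k, 2]
    p[k] <- nbExactTest(perKb[i, ], perKb[j, ], phi)
    fc[k] <- .pairFC(fpkmMeans[i], fpkmMeans[j])
  }
  list(p = p, fc = fc)
}

#' Classify every triplet's control-condition dominance
#'
#' Computes control FPKM means, presence categories, pairwise exact tests
#' on length-scaled equalized pseudo-counts, and the Class 1/2/3 rules for
#' every triplet in the map.
#'
#' @param tripletMap a [TripletMap-class].
#' @param x a [HomeologExperiment-class] with `length_bp` rowData.
#' @param model optional [DispersionModel-class] fitted on the control
#'   samples; estimated when `NULL`.
#' @param normFactors optional TMM factors for the control samples.
#' @param expressedThreshold FPKM threshold for presence (default 0).
#' @param pThreshold,fcDominant,fcSimilar classification thresholds.
#' @return a [S4Vectors::DataFrame] with one row per triplet: anchor,
#'   copy1..3, mean1..3, p12/p13/p23, fc12/fc13/fc23, presence, class.
#' @export
classifyTriplets <- function(tripletMap, x, model = NULL,
                             normFactors = NULL, expressedThreshold = 0,
                             pThreshold = 0.01, fcDominant = 2,
                             fcSimilar = 1.5) {
  stopifnot(is(x, "HomeologExperiment"))
  mem <- tripletMembers(tripletMap)
  missing <- setdiff(as.vector(mem), rownames(x))
  if (length(missing))
    stop("triplet member(s) absent from the count matrix: ",
      paste(head(missing), collapse = ", "))
  ctrl <- x[, conditions(x) == "control"]
  cts <- counts(ctrl)
  lengths <- geneLengths(ctrl)
  if (is.null(lengths)) stop("gene lengths (length_bp rowData) required")
  if (is.null(normFactors)) normFactors <- tmmFactors(cts)
  if (is.null(model))
    model <- estimateCommonDispersion(cts,
      groups = rep("control", ncol(cts)), normFactors = normFactors)
  phi <- dispersion(model)
  pseudo <- equalizePseudoCounts(cts, phi, effectiveLibSizes(model))
  fpkm <- computeFPKM(cts, lengths,
    libSizes = effectiveLibSizes(model))
  fmean <- rowMeans(fpkm)

  n <- length(anchors(tripletMap))
  out <- data.frame(
    anchor = anchors(tripletMap),
    copy1 = mem[, 1], copy2 = mem[, 2], copy3 = mem[, 3],
    mean1 = NA_real_, mean2 = NA_real_, mean3 = NA_real_,
    p12 = NA_real_, p13 = NA_real_, p23 = NA_real_,
    fc12 = NA_real_, fc13 = NA_real_, fc23 = NA_real_,
    presence = NA_integer_, class = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- mem[i, ]
    m <- fmean[g]
    pw <- pairwiseHomeologTests(pseudo[g, , drop = FALSE], m,
      lengths[g], phi)
    pres <- presenceCategory(m, expressedThreshold)
    out$mean1[i] <- m[1]; out$mean2[i] <- m[2]; out$mean3[i] <- m[3]
    out$p12[i] <- pw$p[1]; out$p13[i] <- pw$p[2]; out$p23[i] <- pw$p[3]
    out$fc12[i] <- pw$fc[1]; out$fc13[i] <- pw$fc[2]; out$fc23[i] <- pw$fc[3]
    out$presence[i] <- pres
    out$class[i] <- classifyTriplet(m, pw$p, pw$fc, presence = pres,
      pThreshold = pThreshold, fcDominant = fcDominant,
      fcSimilar = fcSimilar)
  }
  res <- DataFrame(out, row.names = out$anchor)
  metadata(res) <- list(
    phi = phi,
    expressedThreshold = expressedThreshold,
    pThreshold = pThreshold, fcDominant = fcDominant,
    fcSimilar = fcSimilar,
    lengthHandling = "pairwise tests on per-kilobase pseudo-counts")
  res
}
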