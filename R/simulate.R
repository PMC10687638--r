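## Negative-binomial simulator with planted truth.
##
## Counts are drawn NB(mu, phi) with variance mu + phi*mu^2 (phi = 0 is the
## Poisson limit). A gene's control mean is baselineMean x abundance x
## length/2750 x per-sample library factor, so FPKM and raw-count ranks
## differ and the length-normalization path is exercised. Unexpressed copies
## have mean exactly 0 so presence-category truth is unambiguous.

.AVG_LEN <- 2750  # midpoint of the U[500, 5000] bp length distribution

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

.rnb <- function(n, mu, phi) {
  if (phi <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
}

#' Build a simulation configuration
#'
#' Defaults mirror the study design being emulated: two conditions (control
#' and cold) with two biological replicates each; 8,320 syntelog triplets
#' with presence-category proportions matching the observed 6,323 / 529 /
#' 499 / 969 split (3 / 2 / 1 / 0 expressed copies); dominance-class
#' proportions among fully expressed triplets matching the observed
#' 587 / 502 / 1,044 (one-high / two-high / all-equal) with the remainder
#' unstructured; and a cold-induction mix in which roughly a quarter of
#' fully expressed triplets have at least one induced copy.
#'
#' @param nTriplets number of homeolog triplets (default 8320).
#' @param nSingletons number of non-triplet genes (default 5000).
#' @param repsPerCondition biological replicates per condition (default 2).
#' @param baselineMean expected count of a baseline expressed copy of
#'   average length (default 100).
#' @param dispersion NB dispersion phi; default 0.05 (a documented choice,
#'   not an estimate from any study).
#' @param classProportions named fractions over class1/class2/class3/
#'   unstructured, applied to fully expressed triplets.
#' @param presenceProportions named fractions over "3","2","1","0"
#'   expressed copies.
#' @param inductionProportions named fractions over type1/type2/type3/none,
#'   applied to fully expressed triplets.
#' @param dominanceFC planted fold change of high vs low copies (> 2,
#'   default 4).
#' @param inductionLFC planted log2 fold change of induced genes (> 1,
#'   default 2).
#' @param divergentType1Fraction fraction of Type 1 triplets planted with a
#'   divergent inducibility spread (default 0.10).
#' @param divergentRatio planted rank-1 / rank-3 inducibility ratio of
#'   divergent Type 1 triplets (>= 2, default 4).
#' @param librarySize expected reads per sample before the library factor;
#'   `NA` (default) leaves the scale set by `baselineMean`.
#' @param seed RNG seed.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- SimulationConfig(nTriplets = 10, nSingletons = 5, seed = 7)
#' cfg
#' @export
SimulationConfig <- function(nTriplets = 8320,
                             nSingletons = 5000,
                             repsPerCondition = 2,
                             baselineMean = 100,
                             dispersion = 0.05,
                             classProportions = c(
                               class1 = 587 / 6323, class2 = 502 / 6323,
                               class3 = 1044 / 6323,
                               unstructured = 4190 / 6323),
                             presenceProportions = c(
                               "3" = 6323 / 8320, "2" = 529 / 8320,
                               "1" = 499 / 8320, "0" = 969 / 8320),
                             inductionProportions = c(
                               type1 = 0.037, type2 = 0.047,
                               type3 = 0.064, none = 0.852),
                             dominanceFC = 4,
                             inductionLFC = 2,
                             divergentType1Fraction = 0.10,
                             divergentRatio = 4,
                             librarySize = NA_real_,
                             seed = 1) {
  obj <- new("SimulationConfig",
    nTriplets = as.integer(nTriplets),
    nSingletons = as.integer(nSingletons),
    repsPerCondition = as.integer(repsPerCondition),
    baselineMean = as.numeric(baselineMean),
    dispersion = as.numeric(dispersion),
    classProportions = classProportions,
    presenceProportions = presenceProportions,
    inductionProportions = inductionProportions,
    dominanceFC = as.numeric(dominanceFC),
    inductionLFC = as.numeric(inductionLFC),
    divergentType1Fraction = as.numeric(divergentType1Fraction),
    divergentRatio = as.numeric(divergentRatio),
    librarySize = as.numeric(librarySize),
    seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d triplets + %d singletons, %d reps/condition\n",
    object@nTriplets, object@nSingletons, object@repsPerCondition))
  cat(sprintf("  baselineMean %.3g, phi %.3g, dominanceFC %.3g, inductionLFC %.3g\n",
    object@baselineMean, object@dispersion, object@dominanceFC,
    object@inductionLFC))
})

## Sample planted per-triplet categories; deterministic given the RNG state.
.sampleCategory <- function(n, props) {
  if (n == 0L) return(character())
  sample(names(props), n, replace = TRUE, prob = props)
}

#' Simulate a homeolog-triplet RNA-seq dataset with planted truth
#'
#' Generates a count matrix (genes x samples, two conditions x
#' `repsPerCondition` replicates), a syntelog triplet map, per-gene lengths
#' (uniform on 500-5000 bp) and a full truth record. Structure is planted
#' per triplet: a presence category (how many copies are expressed), a
#' dominance class among fully expressed triplets (class 1: one copy at
#' `dominanceFC` x the others; class 2: two high copies; class 3: all
#' equal; unstructured: a 1.7x top copy satisfying no class rule), and a
#' cold-response type (3 / 2 / 1 induced copies at `inductionLFC`).
#' A planted fraction of Type 1 triplets is divergent: its top copy's
#' inducibility is `divergentRatio` times the others'. Triplets with fewer
#' than three expressed copies carry deterministic class truth (one
#' expressed copy: class 1; two: class 2; none: unclassified) and no
#' planted induction.
#'
#' Per-sample library factors are drawn log-uniform on \[0.7, 1.4\] to
#' exercise between-sample normalization.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements `experiment`
#'   ([HomeologExperiment-class] with counts, sample metadata and
#'   `length_bp` rowData), `tripletMap` ([TripletMap-class]) and `truth`
#'   ([SimulationTruth-class]).
#' @examples
#' sim <- simulateTripletDataset(SimulationConfig(nTriplets = 20,
#'   nSingletons = 5, seed = 42))
#' sim$experiment
#' @export
simulateTripletDataset <- function(config) {
  validObject(config)
  .withSeed(config@seed, {
    nt <- config@nTriplets
    ns <- config@nSingletons
    reps <- config@repsPerCondition
    phi <- config@dispersion

    anchors <- sprintf("ANC%05d", seq_len(nt))
    members <- if (nt > 0L) {
      t(vapply(seq_len(nt), function(i)
        sprintf("CsG%05d%s", i, c("a", "b", "c")), character(3)))
    } else {
      matrix(character(), 0, 3)
    }
    singles <- if (ns > 0L) sprintf("CsS%05d", seq_len(ns)) else character()
    genes <- c(as.vector(t(members)), singles)
    ngene <- length(genes)

    lengths <- structure(round(runif(ngene, 500, 5000)), names = genes)

    ## per-triplet planted structure
    presence <- as.integer(.sampleCategory(nt, config@presenceProportions))
    cls <- rep("unclassified", nt)
    type <- rep("none", nt)
    divergent <- rep("n/a", nt)
    full <- which(presence == 3L)
    cls[full] <- .sampleCategory(length(full), config@classProportions)
    cls[cls == "unstructured"] <- "unclassified"
    cls[presence == 1L] <- "class1"
    cls[presence == 2L] <- "class2"
    type[full] <- .sampleCategory(length(full), config@inductionProportions)
    t1 <- which(type == "type1")
    if (length(t1)) {
      ndiv <- round(config@divergentType1Fraction * length(t1))
      divergent[t1] <- "similar"
      if (ndiv > 0)
        divergent[sample(t1, ndiv)] <- "divergent"
    }

    ## per-gene abundances (FPKM-like scale) and true induction LFC
    abundance <- numeric(ngene)
    trueLFC <- numeric(ngene)
    expressed <- logical(ngene)
    geneAnchor <- rep(NA_character_, ngene)
    geneCopy <- rep(NA_character_, ngene)
    unstructuredTop <- 1.7  # satisfies no class rule: fails FC>2 and FC<1.5

    fullCls <- character(nt)  # class drawn for full triplets incl. unstructured
    fullCls[full] <- ifelse(cls[full] == "unclassified", "unstructured",
      cls[full])

    for (i in seq_len(nt)) {
      idx <- (i - 1L) * 3L + 1:3
      geneAnchor[idx] <- anchors[i]
      geneCopy[idx] <- c("a", "b", "c")
      expr <- rep(FALSE, 3)
      if (presence[i] > 0L)
        expr[sample(3, presence[i])] <- TRUE
      a <- numeric(3)
      if (presence[i] == 3L) {
        a[] <- 1
        which3 <- sample(3)  # random copy order for the multipliers
        a <- switch(fullCls[i],
          class1 = { a[which3[1]] <- config@dominanceFC; a },
          class2 = { a[which3[1:2]] <- config@dominanceFC; a },
          class3 = a,
          unstructured = { a[which3[1]] <- unstructuredTop; a })
      } else {
        a[expr] <- 1
      }
      lfc <- numeric(3)
      nInd <- switch(type[i], type1 = 3L, type2 = 2L, type3 = 1L, none = 0L)
      if (nInd > 0L) {
        ind <- sample(3, nInd)
        lfc[ind] <- config@inductionLFC
        if (divergent[i] == "divergent")
          lfc[ind[1]] <- config@inductionLFC + log2(config@divergentRatio)
      }
      abundance[idx] <- a
      trueLFC[idx] <- lfc
      expressed[idx] <- expr
    }
    if (ns > 0L) {
      idx <- nt * 3L + seq_len(ns)
      expr <- runif(ns) < 0.85
      expressed[idx] <- expr
      abundance[idx] <- as.numeric(expr)
      ind <- expr & runif(ns) < 0.10
      trueLFC[idx][ind] <- config@inductionLFC
    }

    ## mean counts: baseline x abundance x length scaling x library factor
    baseMu <- config@baselineMean * abundance * lengths / .AVG_LEN
    if (!is.na(config@librarySize) && sum(baseMu) > 0)
      baseMu <- baseMu * config@librarySize / sum(baseMu)
    nsamp <- 2L * reps
    condition <- rep(c("control", "cold"), each = reps)
    replicate <- rep(seq_len(reps), 2)
    libFactor <- exp(runif(nsamp, log(0.7), log(1.4)))
    mu <- outer(baseMu, libFactor)
    coldCols <- condition == "cold"
    mu[, coldCols] <- mu[, coldCols] * 2^trueLFC

    countsMat <- matrix(.rnb(length(mu), as.vector(mu), phi),
      nrow = ngene,
      dimnames = list(genes, sprintf("%s_%d", condition, replicate)))
    countsMat[abundance == 0, ] <- 0L
    storage.mode(countsMat) <- "integer"

    he <- HomeologExperiment(countsMat, condition, replicate,
      lengths = lengths)
    metadata(he)$libFactor <- structure(libFactor, names = colnames(countsMat))
    tm <- TripletMap(anchors, members)

    trueRatio <- rep(NA_real_, nt)
    if (length(t1)) {
      for (i in t1) {
        l <- trueLFC[(i - 1L) * 3L + 1:3]
        trueRatio[i] <- 2^(max(l) - min(l))
      }
    }
    truth <- new("SimulationTruth",
      tripletTruth = DataFrame(
        anchor = anchors, presence = presence, class = cls,
        type = type, divergent = divergent,
        trueInducibilityRatio = trueRatio),
      geneTruth = DataFrame(
        gene = genes, anchor = geneAnchor, copy = geneCopy,
        length_bp = as.numeric(lengths), expressed = expressed,
        abundance = abundance, controlMean = baseMu,
        trueLFC = trueLFC, induced = trueLFC > 0))

    list(experiment = he, tripletMap = tm, truth = truth)
  })
}

#' Build a gene-to-term map with one planted enriched term
#'
#' One term (`TERM_planted`) is assigned to `enrichedTermSize` genes drawn
#' from the members of planted class-1 triplets, so term enrichment on the
#' recovered class-1 set has a known positive. The remaining
#' `backgroundTerms` terms are each assigned to a uniform random gene
#' subset of the same size.
#'
#' @param truth a [SimulationTruth-class].
#' @param enrichedTermSize genes carrying the planted term.
#' @param backgroundTerms number of uniform background terms.
#' @param seed RNG seed.
#' @return a [S4Vectors::DataFrame] with columns `gene`, `term`.
#' @export
makeTermMap <- function(truth, enrichedTermSize, backgroundTerms, seed = 1) {
  tt <- tripletTruth(truth)
  gt <- geneTruth(truth)
  class1Anchors <- tt$anchor[tt$class == "class1" & tt$presence == 3L]
  class1Genes <- gt$gene[!is.na(gt$anchor) & gt$anchor %in% class1Anchors]
  if (enrichedTermSize > length(class1Genes))
    stop("enrichedTermSize (", enrichedTermSize,
      ") exceeds the planted class-1 gene count (", length(class1Genes), ")")
  .withSeed(seed, {
    genes <- sample(class1Genes, enrichedTermSize)
    terms <- rep("TERM_planted", enrichedTermSize)
    if (backgroundTerms > 0) {
      for (b in seq_len(backgroundTerms)) {
        g <- sample(gt$gene, min(enrichedTermSize, length(gt$gene)))
        genes <- c(genes, g)
        terms <- c(terms, rep(sprintf("TERM%04d", b), length(g)))
      }
    }
    DataFrame(gene = genes, term = terms)
  })
}

#' Simulate coexpressed gene blocks
#'
#' Each block shares a latent profile across samples; member genes are the
#' latent profile plus independent Gaussian noise on the log2 scale, then
#' mapped back to a positive TPM-like matrix. Genes from different blocks
#' are uncorrelated in expectation, so at the default network parameters
#' the blocks separate into distinct modules.
#'
#' @param nBlocks number of blocks (default 2).
#' @param genesPerBlock genes per block (default 50).
#' @param nSamples samples (default 10).
#' @param noiseSD sd of the per-gene log2 noise (default 0.3).
#' @param seed RNG seed.
#' @return a numeric matrix (genes x samples) of TPM-like abundances with
#'   gene names `block<i>.g<j>`; attribute `block` gives the planted block
#'   of each gene.
#' @export
simulateCoexpressionBlocks <- function(nBlocks = 2, genesPerBlock = 50,
                                       nSamples = 10, noiseSD = 0.3,
                                       seed = 1) {
  .withSeed(seed, {
    latent <- matrix(rnorm(nBlocks * nSamples, sd = 2), nBlocks)
    expr <- matrix(0, nBlocks * genesPerBlock, nSamples)
    block <- rep(seq_len(nBlocks), each = genesPerBlock)
    for (i in seq_len(nrow(expr)))
      expr[i, ] <- latent[block[i], ] + rnorm(nSamples, sd = noiseSD)
    tpm <- 2^(expr + 5) - 1
    tpm[tpm < 0] <- 0
    rownames(tpm) <- sprintf("block%d.g%02d", block,
      sequence(rep(genesPerBlock, nBlocks)))
    colnames(tpm) <- sprintf("s%02d", seq_len(nSamples))
    attr(tpm, "block") <- structure(block, names = rownames(tpm))
    tpm
  })
}
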