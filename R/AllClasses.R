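#' @importFrom methods new validObject is slot callNextMethod setValidity show
#' @importFrom stats rnbinom rpois runif rnorm var cor optimize dnbinom
#'   dpois pnbinom ppois qnbinom qpois phyper p.adjust quantile sd
#' @importFrom utils read.delim write.table head
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   colData rowData assayNames
#' @importFrom BiocGenerics counts
NULL

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for the homeolog-triplet generator
#'
#' Parameterizes the negative-binomial simulator: how many syntelog triplets
#' and singleton genes to generate, the replication design (two conditions,
#' control and cold, with `repsPerCondition` replicates each), the expression
#' scale and dispersion, and the planted structure: presence categories
#' (how many of the three copies are expressed), dominance classes
#' (one-high / two-high / all-equal / unstructured), and cold-induction
#' types (three / two / one induced copies).
#'
#' @slot nTriplets integer, number of homeolog triplets.
#' @slot nSingletons integer, number of non-triplet genes.
#' @slot repsPerCondition integer, replicates per condition (default 2).
#' @slot baselineMean numeric, expected count of a baseline (non-dominant)
#'   expressed copy of average length.
#' @slot dispersion numeric, NB dispersion phi (variance = mu + phi * mu^2);
#'   0 is the Poisson limit.
#' @slot classProportions named numeric over class1/class2/class3/unstructured,
#'   summing to 1; applied to triplets with all three copies expressed.
#' @slot presenceProportions named numeric over "3","2","1","0" expressed
#'   copies, summing to 1.
#' @slot inductionProportions named numeric over type1/type2/type3/none,
#'   summing to 1; applied to triplets with all three copies expressed.
#' @slot dominanceFC numeric > 2, planted fold change of high vs low copies.
#' @slot inductionLFC numeric > 1, planted log2 fold change of induced genes.
#' @slot divergentType1Fraction numeric in \[0, 1\], fraction of Type 1 triplets
#'   planted with a divergent (>= 2x) inducibility spread.
#' @slot divergentRatio numeric >= 2, planted rank-1 / rank-3 inducibility
#'   ratio of divergent Type 1 triplets.
#' @slot librarySize numeric, expected reads per sample before the per-sample
#'   library factor; `NA` leaves the count scale set by `baselineMean`.
#' @slot seed integer RNG seed.
#'
#' @seealso [SimulationConfig()], [simulateTripletDataset()]
#' @name SimulationConfig-class
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nTriplets = "integer",
    nSingletons = "integer",
    repsPerCondition = "integer",
    baselineMean = "numeric",
    dispersion = "numeric",
    classProportions = "numeric",
    presenceProportions = "numeric",
    inductionProportions = "numeric",
    dominanceFC = "numeric",
    inductionLFC = "numeric",
    divergentType1Fraction = "numeric",
    divergentRatio = "numeric",
    librarySize = "numeric",
    seed = "integer"
  )
)

.checkProportions <- function(p, nms, field) {
  if (!identical(sort(names(p)), sort(nms)))
    return(sprintf("%s must be named %s", field, paste(nms, collapse = ", ")))
  if (any(p < 0)) return(sprintf("%s has negative entries", field))
  if (abs(sum(p) - 1) > 1e-9)
    return(sprintf("%s must sum to 1 (got %.12g)", field, sum(p)))
  NULL
}

setValidity("SimulationConfig", function(object) {
  msg <- character()
  for (f in c("nTriplets", "nSingletons", "repsPerCondition"))
    if (slot(object, f) < 0L) msg <- c(msg, sprintf("%s must be >= 0", f))
  if (object@repsPerCondition < 1L)
    msg <- c(msg, "repsPerCondition must be >= 1")
  if (object@baselineMean <= 0) msg <- c(msg, "baselineMean must be > 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  m <- .checkProportions(object@classProportions,
    c("class1", "class2", "class3", "unstructured"), "classProportions")
  if (!is.null(m)) msg <- c(msg, m)
  m <- .checkProportions(object@presenceProportions,
    c("3", "2", "1", "0"), "presenceProportions")
  if (!is.null(m)) msg <- c(msg, m)
  m <- .checkProportions(object@inductionProportions,
    c("type1", "type2", "type3", "none"), "inductionProportions")
  if (!is.null(m)) msg <- c(msg, m)
  if (object@dominanceFC <= 2) msg <- c(msg, "dominanceFC must be > 2")
  if (object@inductionLFC <= 1) msg <- c(msg, "inductionLFC must be > 1")
  if (object@divergentType1Fraction < 0 || object@divergentType1Fraction > 1)
    msg <- c(msg, "divergentType1Fraction must be in [0, 1]")
  if (object@divergentRatio < 2) msg <- c(msg, "divergentRatio must be >= 2")
  if (!is.na(object@librarySize) && object@librarySize <= 0)
    msg <- c(msg, "librarySize must be > 0 (or NA)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## TripletMap
## ---------------------------------------------------------------------------

#' Syntelog triplet map
#'
#' Anchor-keyed groups of exactly three homeologous gene identifiers, the
#' unit of all divergence analyses. Emulates the 3:1 camelina:Arabidopsis
#' syntelog output of a synteny pipeline: each anchor (a diploid reference
#' gene) keys the three retained polyploid copies.
#'
#' @slot anchors character vector of anchor gene ids (unique).
#' @slot members character matrix with one row per anchor and exactly three
#'   columns, the homeologous copies; no gene appears twice.
#'
#' @seealso [TripletMap()], [anchors()], [tripletMembers()]
#' @name TripletMap-class
#' @aliases TripletMap-class
#' @exportClass TripletMap
setClass("TripletMap",
  representation(anchors = "character", members = "matrix")
)

setValidity("TripletMap", function(object) {
  msg <- character()
  if (!is.character(object@members))
    msg <- c(msg, "members must be a character matrix")
  if (ncol(object@members) != 3L && length(object@members))
    msg <- c(msg, "members must have exactly 3 columns")
  if (nrow(object@members) != length(object@anchors))
    msg <- c(msg, "one member row per anchor required")
  if (anyDuplicated(object@anchors))
    msg <- c(msg, "anchors must be unique")
  mem <- as.vector(object@members)
  if (anyDuplicated(mem))
    msg <- c(msg, "a gene appears in more than one triplet slot")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## HomeologExperiment
## ---------------------------------------------------------------------------

#' Count container for the cold-stress homeolog analysis
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a `counts` assay
#' (non-negative integers), per-sample `condition` (control or cold) and
#' `replicate` columns, and an optional per-gene `length_bp` rowData column
#' used by FPKM/TPM computation.
#'
#' @seealso [HomeologExperiment()], [geneLengths()], [conditions()]
#' @name HomeologExperiment-class
#' @aliases HomeologExperiment-class
#' @exportClass HomeologExperiment
setClass("HomeologExperiment", contains = "SummarizedExperiment")

setValidity("HomeologExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    return("a 'counts' assay is required")
  cts <- assay(object, "counts")
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  cd <- colData(object)
  if (!"condition" %in% colnames(cd)) {
    msg <- c(msg, "colData must have a 'condition' column")
  } else if (!all(cd$condition %in% c("control", "cold"))) {
    msg <- c(msg, "condition must be 'control' or 'cold'")
  }
  if (!"replicate" %in% colnames(cd))
    msg <- c(msg, "colData must have a 'replicate' column")
  if ("length_bp" %in% colnames(rowData(object))) {
    len <- rowData(object)$length_bp
    if (any(!is.na(len) & len <= 0))
      msg <- c(msg, "length_bp must be > 0")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DispersionModel
## ---------------------------------------------------------------------------

#' Common-dispersion model for the NB exact test
#'
#' Holds the common dispersion phi (variance = mu + phi * mu^2) and the
#' per-sample effective library sizes (library size times TMM factor) that
#' the exact test conditions on.
#'
#' @slot phi numeric >= 0, common NB dispersion.
#' @slot effectiveLibSizes named numeric > 0, reads per sample after
#'   normalization.
#'
#' @seealso [estimateCommonDispersion()], [nbExactTest()]
#' @name DispersionModel-class
#' @aliases DispersionModel-class
#' @exportClass DispersionModel
setClass("DispersionModel",
  representation(phi = "numeric", effectiveLibSizes = "numeric")
)

setValidity("DispersionModel", function(object) {
  msg <- character()
  if (length(object@phi) != 1L || is.na(object@phi) || object@phi < 0)
    msg <- c(msg, "phi must be a single value >= 0")
  if (any(object@effectiveLibSizes <= 0))
    msg <- c(msg, "effective library sizes must be > 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CoexpressionNetwork
## ---------------------------------------------------------------------------

#' Thresholded Pearson coexpression network with Leiden modules
#'
#' Holds the filtered gene set, the correlation edges above the threshold,
#' the module partition, and the parameters (top variable fraction, r
#' threshold, Leiden resolution, seed) that produced them.
#'
#' @slot edges a [S4Vectors::DataFrame] with columns geneA, geneB, r.
#' @slot modules named integer vector, gene -> module id (ids ordered by
#'   module size, largest first).
#' @slot params list of the parameters used.
#'
#' @seealso [buildCoexpressionNetwork()], [detectModules()]
#' @name CoexpressionNetwork-class
#' @aliases CoexpressionNetwork-class
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
  representation(edges = "DataFrame", modules = "integer", params = "list")
)

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  if (!all(c("geneA", "geneB", "r") %in% colnames(ed)))
    msg <- c(msg, "edges must have columns geneA, geneB, r")
  thr <- object@params$rThreshold
  if (!is.null(thr) && nrow(ed) && any(ed$r <= thr))
    msg <- c(msg, "all edges must have r above the threshold")
  if (nrow(ed) && any(ed$geneA == ed$geneB))
    msg <- c(msg, "self-edges are not allowed")
  if (is.null(names(object@modules)) && length(object@modules))
    msg <- c(msg, "modules must be named by gene")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SimulationTruth
## ---------------------------------------------------------------------------

#' Planted truth labels of a simulated dataset
#'
#' Records, per triplet, the planted presence category, dominance class,
#' cold-response type and divergence flag, and per gene the expression
#' status, true mean abundances and true induction log2 fold change —
#' everything downstream classifiers are later scored against.
#'
#' @slot tripletTruth a [S4Vectors::DataFrame], one row per triplet.
#' @slot geneTruth a [S4Vectors::DataFrame], one row per gene.
#'
#' @seealso [simulateTripletDataset()]
#' @name SimulationTruth-class
#' @aliases SimulationTruth-class
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  representation(tripletTruth = "DataFrame", geneTruth = "DataFrame")
)
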