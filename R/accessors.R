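## Constructors, accessors and show methods for the core classes.

#' Construct a TripletMap
#'
#' @param anchors character vector of anchor gene ids.
#' @param members character matrix (or data.frame) with three columns, the
#'   homeologous copies, one row per anchor.
#' @return a [TripletMap-class] object.
#' @examples
#' tm <- TripletMap(c("AT1", "AT2"),
#'   rbind(c("g1a", "g1b", "g1c"), c("g2a", "g2b", "g2c")))
#' anchors(tm)
#' @export
TripletMap <- function(anchors, members) {
  members <- as.matrix(members)
  mode(members) <- "character"
  rownames(members) <- anchors
  new("TripletMap", anchors = as.character(anchors), members = members)
}

#' @rdname TripletMap-class
#' @export
setMethod("anchors", "TripletMap", function(x) x@anchors)

#' @rdname TripletMap-class
#' @export
setMethod("tripletMembers", "TripletMap", function(x) x@members)

#' @rdname TripletMap-class
#' @export
setMethod("length", "TripletMap", function(x) length(x@anchors))

setMethod("show", "TripletMap", function(object) {
  cat("TripletMap with", length(object@anchors), "triplets\n")
  if (length(object@anchors)) {
    n <- min(3L, length(object@anchors))
    for (i in seq_len(n))
      cat("  ", object@anchors[i], "->",
        paste(object@members[i, ], collapse = ", "), "\n")
    if (length(object@anchors) > n) cat("  ...\n")
  }
})

#' Construct a HomeologExperiment
#'
#' @param counts integer matrix, genes x samples, rownames = gene ids.
#' @param condition character/factor, "control" or "cold" per sample.
#' @param replicate integer replicate index per sample.
#' @param lengths optional named numeric, gene length in bp.
#' @return a [HomeologExperiment-class].
#' @examples
#' cts <- matrix(rpois(8, 20), 2,
#'   dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' he <- HomeologExperiment(cts, rep(c("control", "cold"), each = 2),
#'   rep(1:2, 2), lengths = c(g1 = 1000, g2 = 2000))
#' conditions(he)
#' @export
HomeologExperiment <- function(counts, condition, replicate,
                               lengths = NULL) {
  counts <- as.matrix(counts)
  cd <- DataFrame(
    condition = as.character(condition),
    replicate = as.integer(replicate),
    row.names = colnames(counts)
  )
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(lengths)) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss))
      stop("missing gene length for: ", paste(head(miss), collapse = ", "))
    rd$length_bp <- as.numeric(lengths[rownames(counts)])
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
    colData = cd, rowData = rd)
  new("HomeologExperiment", se)
}

#' @rdname HomeologExperiment-class
#' @export
setMethod("counts", "HomeologExperiment",
  function(object) assay(object, "counts"))

#' @rdname HomeologExperiment-class
#' @export
setMethod("conditions", "HomeologExperiment",
  function(x) colData(x)$condition)

#' @rdname HomeologExperiment-class
#' @export
setMethod("geneLengths", "HomeologExperiment", function(x) {
  rd <- rowData(x)
  if (!"length_bp" %in% colnames(rd)) return(NULL)
  structure(as.numeric(rd$length_bp), names = rownames(x))
})

setMethod("show", "HomeologExperiment", function(object) {
  callNextMethod()
  tab <- table(conditions(object))
  cat("conditions:",
    paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

#' Construct a DispersionModel
#'
#' @param phi common NB dispersion (>= 0).
#' @param effectiveLibSizes named numeric, per-sample effective library size.
#' @return a [DispersionModel-class].
#' @export
DispersionModel <- function(phi, effectiveLibSizes) {
  new("DispersionModel", phi = as.numeric(phi),
    effectiveLibSizes = effectiveLibSizes)
}

#' @rdname DispersionModel-class
#' @export
setMethod("dispersion", "DispersionModel", function(object) object@phi)

#' @rdname DispersionModel-class
#' @export
setMethod("effectiveLibSizes", "DispersionModel",
  function(object) object@effectiveLibSizes)

setMethod("show", "DispersionModel", function(object) {
  cat(sprintf("DispersionModel: phi = %.4g over %d samples\n",
    object@phi, length(object@effectiveLibSizes)))
})

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("modules", "CoexpressionNetwork", function(x) x@modules)

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)

setMethod("show", "CoexpressionNetwork", function(object) {
  nmod <- length(unique(object@modules))
  cat(sprintf(
    "CoexpressionNetwork: %d genes, %d edges (r > %.2f), %d modules\n",
    length(object@modules), nrow(object@edges),
    object@params$rThreshold, nmod))
})

#' @rdname SimulationTruth-class
#' @export
setMethod("tripletTruth", "SimulationTruth", function(x) x@tripletTruth)

#' @rdname SimulationTruth-class
#' @export
setMethod("geneTruth", "SimulationTruth", function(x) x@geneTruth)

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", nrow(object@tripletTruth), "triplets,",
    nrow(object@geneTruth), "genes\n")
  if (nrow(object@tripletTruth)) {
    cat("planted classes:\n")
    print(table(object@tripletTruth$class))
  }
})
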