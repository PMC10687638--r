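#' @rdname TripletMap-class
#' @param x a `TripletMap`.
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname TripletMap-class
#' @export
setGeneric("tripletMembers", function(x) standardGeneric("tripletMembers"))

#' @rdname HomeologExperiment-class
#' @param x object.
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname HomeologExperiment-class
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname DispersionModel-class
#' @param object object.
#' @export
setGeneric("dispersion", function(object) standardGeneric("dispersion"))

#' @rdname DispersionModel-class
#' @export
setGeneric("effectiveLibSizes",
  function(object) standardGeneric("effectiveLibSizes"))

#' @rdname CoexpressionNetwork-class
#' @param x a `CoexpressionNetwork`.
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname SimulationTruth-class
#' @param x a `SimulationTruth`.
#' @export
setGeneric("tripletTruth", function(x) standardGeneric("tripletTruth"))

#' @rdname SimulationTruth-class
#' @export
setGeneric("geneTruth", function(x) standardGeneric("geneTruth"))
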