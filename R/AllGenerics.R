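#' @rdname SECallSet-class
#' @param x an object.
#' @export
setGeneric("seCalls", function(x) standardGeneric("seCalls"))

#' @rdname SECallSet-class
#' @export
setGeneric("rankCurve", function(x) standardGeneric("rankCurve"))

#' @rdname CircuitGraph-class
#' @param x an object.
#' @export
setGeneric("circuitNodes", function(x) standardGeneric("circuitNodes"))

#' @rdname CircuitGraph-class
#' @export
setGeneric("circuitEdges", function(x) standardGeneric("circuitEdges"))

#' @rdname CircuitGraph-class
#' @export
setGeneric("inDegree", function(x) standardGeneric("inDegree"))

#' @rdname CircuitGraph-class
#' @export
setGeneric("outDegree", function(x) standardGeneric("outDegree"))

#' @rdname DropletSet-class
#' @param x an object.
#' @export
setGeneric("droplets", function(x) standardGeneric("droplets"))

#' @rdname FRAPFit-class
#' @param x an object.
#' @export
setGeneric("mobileFraction", function(x) standardGeneric("mobileFraction"))
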