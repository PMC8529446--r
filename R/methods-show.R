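# Accessors and show methods for the package's S4 containers.

#' @rdname SECallSet-class
#' @export
setMethod("seCalls", "SECallSet", function(x) x@calls)

#' @rdname SECallSet-class
#' @export
setMethod("rankCurve", "SECallSet", function(x) x@curve)

#' @rdname CircuitGraph-class
#' @export
setMethod("circuitNodes", "CircuitGraph", function(x) x@nodes)

#' @rdname CircuitGraph-class
#' @export
setMethod("circuitEdges", "CircuitGraph", function(x) x@edges)

#' @rdname CircuitGraph-class
#' @export
setMethod("inDegree", "CircuitGraph", function(x) x@inDegree)

#' @rdname CircuitGraph-class
#' @export
setMethod("outDegree", "CircuitGraph", function(x) x@outDegree)

#' @rdname DropletSet-class
#' @export
setMethod("droplets", "DropletSet", function(x) x@droplets)

#' @rdname FRAPFit-class
#' @export
setMethod("mobileFraction", "FRAPFit", function(x) x@mobileFraction)

setMethod("show", "PWMRecord", function(object) {
  cat("PWMRecord for", object@tfName,
      sprintf("(length %d, max log-odds %.2f bits)\n",
              ncol(object@profile), pwmMaxScore(object)))
  cat("consensus:", pwmConsensus(object), "\n")
})

setMethod("show", "SERankCurve", function(object) {
  n <- length(object@signal)
  cat(sprintf("SERankCurve over %d regions\n", n))
  if (is.na(object@cutoffIndex)) {
    cat("no slope-1 cutoff (degenerate or never-steep curve)\n")
  } else {
    cat(sprintf("cutoff at rank %d/%d, scaled signal %.4f\n",
                object@cutoffIndex, n, object@cutoffSignal))
  }
})

setMethod("show", "SECallSet", function(object) {
  lab <- object@calls$label
  cat(sprintf("SECallSet: %d stitched regions (%d SE, %d TE)\n",
              length(object@calls), sum(lab == "SE"), sum(lab == "TE")))
  show(object@curve)
})

setMethod("show", "CircuitGraph", function(object) {
  cat(sprintf("CircuitGraph: %d SE-driven TFs, %d edges (%d self-loops)\n",
              length(object@nodes), nrow(object@edges),
              sum(object@edges$source == object@edges$target)))
  if (length(object@nodes)) {
    tot <- object@inDegree + object@outDegree
    top <- head(order(-tot), 5L)
    cat("top total degree:",
        paste(sprintf("%s=%d", object@nodes[top], tot[top]), collapse = ", "),
        "\n")
  }
})

setMethod("show", "DyadDensityProfile", function(object) {
  cat(sprintf(
    "DyadDensityProfile: +/-%d bp around %d motifs, %d fragments, %d dyads in window\n",
    max(object@offsets), object@nMotifs, object@nFragments,
    sum(object@counts)))
})

setMethod("show", "FRAPFit", function(object) {
  if (!object@converged) {
    cat("FRAPFit: fit did not converge:", object@message, "\n")
  } else {
    cat(sprintf(
      "FRAPFit: k = %.4g /s (t1/2 = %.3g s), plateau = %.3f, floor = %.3f, mobile fraction = %.3f\n",
      object@rate, object@tHalf, object@plateau, object@postBleachFloor,
      object@mobileFraction))
  }
})

setMethod("show", "DropletSet", function(object) {
  cat(sprintf("DropletSet '%s'%s: %d droplets\n", object@imageId,
              if (nzchar(object@channel)) paste0(" [", object@channel, "]") else "",
              nrow(object@droplets)))
})
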