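#' @rdname forceFieldParams
#' @export
setGeneric("toSearchVector", function(params, nParams = 5L)
  standardGeneric("toSearchVector"))

#' @rdname pairEnergy
#' @export
setGeneric("pairEnergy", function(a, b, params, truncation = truncationScheme())
  standardGeneric("pairEnergy"))

#' @rdname molecularDipole
#' @export
setGeneric("molecularDipole", function(params) standardGeneric("molecularDipole"))

#' @rdname buildSiteGeometry
#' @export
setGeneric("buildSiteGeometry", function(params) standardGeneric("buildSiteGeometry"))

#' @rdname rdf
#' @export
setGeneric("rdf", function(trajectory, scheme, ...) standardGeneric("rdf"))

#' @rdname edf
#' @export
setGeneric("edf", function(trajectory, params, scheme, ...) standardGeneric("edf"))

#' @rdname virialPressure
#' @export
setGeneric("virialPressure", function(trajectory, params, ...)
  standardGeneric("virialPressure"))

## ---- accessors ----

#' Accessors for BinScheme and DistributionFunction
#'
#' @param x A \linkS4class{BinScheme} or \linkS4class{DistributionFunction}.
#' @return \code{binEdges}: numeric edge vector; \code{binWidths}: per-bin
#'   widths; \code{binKind}: "radial" or "energy"; \code{dfValues},
#'   \code{dfUncertainties}: per-bin numeric vectors; \code{nBlocks}: integer.
#' @name df-accessors
NULL

#' @rdname df-accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname df-accessors
#' @export
setGeneric("binWidths", function(x) standardGeneric("binWidths"))
#' @rdname df-accessors
#' @export
setGeneric("binKind", function(x) standardGeneric("binKind"))
#' @rdname df-accessors
#' @export
setGeneric("dfValues", function(x) standardGeneric("dfValues"))
#' @rdname df-accessors
#' @export
setGeneric("dfUncertainties", function(x) standardGeneric("dfUncertainties"))
#' @rdname df-accessors
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))

#' Accessors for Trajectory and SimulationBox
#'
#' @param x A \linkS4class{Trajectory} or \linkS4class{SimulationBox}.
#' @return \code{nFrames}/\code{nMolecules}: integer counts; \code{boxLength}:
#'   cubic edge in nm; \code{species}: "lj" or "water3".
#' @name trajectory-accessors
NULL

#' @rdname trajectory-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname trajectory-accessors
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))
#' @rdname trajectory-accessors
#' @export
setGeneric("boxLength", function(x) standardGeneric("boxLength"))
#' @rdname trajectory-accessors
#' @export
setGeneric("species", function(x) standardGeneric("species"))

setMethod("binEdges", "BinScheme", function(x) x@edges)
setMethod("binWidths", "BinScheme", function(x) diff(x@edges))
setMethod("binKind", "BinScheme", function(x) x@kind)
setMethod("binEdges", "DistributionFunction", function(x) x@scheme@edges)
setMethod("binWidths", "DistributionFunction", function(x) diff(x@scheme@edges))
setMethod("binKind", "DistributionFunction", function(x) x@scheme@kind)
setMethod("dfValues", "DistributionFunction", function(x) x@values)
setMethod("dfUncertainties", "DistributionFunction", function(x) x@uncertainties)
setMethod("nBlocks", "DistributionFunction", function(x) x@nBlocks)

setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
setMethod("nMolecules", "Trajectory", function(x) x@box@n)
setMethod("boxLength", "Trajectory", function(x) x@box@L)
setMethod("species", "Trajectory", function(x) x@box@species)
setMethod("nMolecules", "SimulationBox", function(x) x@n)
setMethod("boxLength", "SimulationBox", function(x) x@L)
setMethod("species", "SimulationBox", function(x) x@species)

## ---- show methods ----

setMethod("show", "ForceFieldParams", function(object) {
  cat("ForceFieldParams (rigid 3-site / LJ)\n")
  cat(sprintf("  sigma   %10.6f nm\n", object@sigma))
  cat(sprintf("  epsilon %10.6f kJ/mol\n", object@epsilon))
  cat(sprintf("  q       %10.4f e   (H sites carry -q/2)\n", object@q))
  cat(sprintf("  d       %10.5f nm\n", object@d))
  cat(sprintf("  a       %10.2f deg\n", object@a))
})

setMethod("show", "SimulationBox", function(object) {
  cat(sprintf("SimulationBox: %d x %s, L = %.4f nm, T = %.2f K\n",
              object@n, object@species, object@L, object@temperature))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames, %d %s molecules, L = %.4f nm\n",
              nFrames(object), nMolecules(object), species(object),
              boxLength(object)))
  if (!is.null(object@meta$acceptanceRate))
    cat(sprintf("  production acceptance rate: %.3f\n",
                object@meta$acceptanceRate))
})

setMethod("show", "BinScheme", function(object) {
  cat(sprintf("BinScheme (%s): %d bins spanning [%.6g, %.6g]",
              object@kind, length(object@edges) - 1L,
              object@edges[1], object@edges[length(object@edges)]))
  if (!is.null(object@meta$id)) cat(sprintf(", definition ID %d", object@meta$id))
  cat("\n")
})

setMethod("show", "DistributionFunction", function(object) {
  cat(sprintf("DistributionFunction (%s): %d bins", binKind(object),
              length(dfValues(object))))
  if (nBlocks(object) > 0L)
    cat(sprintf(", uncertainties from %d blocks", nBlocks(object)))
  cat("\n")
})

setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf("OptimizationResult (%s fitness): %s after %d generations\n",
              object@fitnessKind,
              if (object@converged) "converged" else "NOT converged",
              length(object@history)))
  cat(sprintf("  best fitness %.6g (threshold %.6g), total budget %g sweeps\n",
              object@bestFitness, object@threshold, object@totalBudget))
  cat("  best parameters:\n")
  show(object@bestParams)
})
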