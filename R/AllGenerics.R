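#' Accessors for relaxometry objects
#'
#' Small accessor generics for the S4 classes of the package: echo times and
#' signals of an [EchoSeries-class], basis T2 constants and compartment
#' names of a [CompartmentBasis-class], fitted amplitude/T2/fractions of the
#' fit result classes, and the retained draws of a
#' [PosteriorSamples-class].
#'
#' @param object an object of the documented class.
#' @return the slot value (numeric vector/scalar, character vector or
#'   matrix as appropriate).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("echoTimes", function(object) standardGeneric("echoTimes"))

#' @rdname accessors
#' @export
setGeneric("signals", function(object) standardGeneric("signals"))

#' @rdname accessors
#' @export
setGeneric("t2Values", function(object) standardGeneric("t2Values"))

#' @rdname accessors
#' @export
setGeneric("compartmentNames",
  function(object) standardGeneric("compartmentNames"))

#' @rdname accessors
#' @export
setGeneric("s0", function(object) standardGeneric("s0"))

#' @rdname accessors
#' @export
setGeneric("t2", function(object) standardGeneric("t2"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("mwf", function(object) standardGeneric("mwf"))

#' @rdname accessors
#' @export
setGeneric("residualNorm", function(object) standardGeneric("residualNorm"))

#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))

#' @rdname accessors
#' @export
setGeneric("posteriorSamples",
  function(object) standardGeneric("posteriorSamples"))

#' @rdname accessors
#' @export
setGeneric("acceptanceRate",
  function(object) standardGeneric("acceptanceRate"))

setMethod("echoTimes", "EchoSeries", function(object) object@echoTimes)
setMethod("signals", "EchoSeries", function(object) object@signals)
setMethod("t2Values", "CompartmentBasis", function(object) object@t2Values)
setMethod("compartmentNames", "CompartmentBasis",
  function(object) object@compartmentNames)

setMethod("s0", "MonoFit", function(object) object@s0)
setMethod("t2", "MonoFit", function(object) object@t2)
setMethod("residualNorm", "MonoFit", function(object) object@residualNorm)
setMethod("converged", "MonoFit", function(object) object@converged)
setMethod("nIterations", "MonoFit", function(object) object@nIterations)

setMethod("s0", "MultiFit", function(object) object@s0)
setMethod("fractions", "MultiFit", function(object) {
  v <- object@fractions
  names(v) <- object@basis@compartmentNames
  v
})
setMethod("mwf", "MultiFit", function(object) object@mwf)
setMethod("residualNorm", "MultiFit", function(object) object@residualNorm)

setMethod("posteriorSamples", "PosteriorSamples",
  function(object) object@samples)
setMethod("acceptanceRate", "PosteriorSamples",
  function(object) object@acceptanceRate)

setMethod("show", "EchoSeries", function(object) {
  cat(sprintf(
    "EchoSeries with %d echoes, TE %g-%g ms\n",
    length(object@echoTimes), min(object@echoTimes), max(object@echoTimes)
  ))
  cat("  signals:", paste(signif(object@signals, 5), collapse = " "), "\n")
})

setMethod("show", "CompartmentBasis", function(object) {
  cat("CompartmentBasis:",
    paste(sprintf("%s=%g ms", object@compartmentNames, object@t2Values),
      collapse = ", "), "\n")
})

setMethod("show", "MonoFit", function(object) {
  cat(sprintf(
    "MonoFit: S0 = %.6g, T2 = %.6g ms (SSE %.4g, %d iter, %s)\n",
    object@s0, object@t2, object@residualNorm, object@nIterations,
    if (object@converged) "converged" else "not converged"
  ))
})

setMethod("show", "MultiFit", function(object) {
  if (object@degenerate) {
    cat("MultiFit: degenerate (all-zero amplitude)\n")
  } else {
    v <- fractions(object)
    cat(sprintf("MultiFit: S0 = %.6g, MWF = %.4f\n", object@s0, object@mwf))
    cat("  fractions:",
      paste(sprintf("%s=%.4f", names(v), v), collapse = ", "), "\n")
  }
})

setMethod("show", "ChainConfig", function(object) {
  cat(sprintf(
    "ChainConfig: burn %d, run %d, keep %d, kappa %g, seed %d\n",
    object@nBurn, object@nRun, object@nKeep,
    object@proposalConcentration, object@seed
  ))
})

setMethod("show", "PosteriorSamples", function(object) {
  m <- colMeans(object@samples)
  s <- apply(object@samples, 2, stats::sd)
  cat(sprintf(
    "PosteriorSamples: %d draws, acceptance rate %.3f\n",
    nrow(object@samples), object@acceptanceRate
  ))
  cat("  posterior mean +/- sd:",
    paste(sprintf("%s %.4f+/-%.4f", colnames(object@samples), m, s),
      collapse = ", "), "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d strata, %d subjects, grid %s, SNR %g, seed %d\n",
    nrow(object@strata), sum(object@strata$n),
    paste(object@gridShape, collapse = "x"), object@snr, object@seed
  ))
})
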