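#' @rdname accessors
#' @param object An object.
#' @export
setGeneric("ligandId", function(object) standardGeneric("ligandId"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("temperature", function(object) standardGeneric("temperature"))
#' @rdname accessors
#' @export
setGeneric("rescaledTimes", function(object) standardGeneric("rescaledTimes"))
#' @rdname accessors
#' @export
setGeneric("wallTimes", function(object) standardGeneric("wallTimes"))
#' @rdname accessors
#' @export
setGeneric("tauHat", function(object) standardGeneric("tauHat"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("isReliable", function(object) standardGeneric("isReliable"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("meanTau", function(object) standardGeneric("meanTau"))
#' @rdname accessors
#' @export
setGeneric("semTau", function(object) standardGeneric("semTau"))
#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setGeneric("gridEdges", function(object) standardGeneric("gridEdges"))
#' @rdname accessors
#' @export
setGeneric("occupiedBins", function(object) standardGeneric("occupiedBins"))

#' Accessors for MetadKinetics classes
#'
#' Small read-only accessors for the S4 containers; prefer these over
#' direct slot access.
#'
#' @name accessors
#' @param object An object of the documented class.
NULL

#' @rdname accessors
setMethod("ligandId", "BiasedTrajectory", function(object) object@ligandId)
#' @rdname accessors
setMethod("ligandId", "DissociationSample", function(object) object@ligandId)
#' @rdname accessors
setMethod("frames", "BiasedTrajectory", function(object) object@frames)
#' @rdname accessors
setMethod("temperature", "BiasedTrajectory", function(object) object@temperature)
#' @rdname accessors
setMethod("temperature", "WeightedEnsemble", function(object) object@temperature)
#' @rdname accessors
setMethod("temperature", "FreeEnergySurface", function(object) object@temperature)
#' @rdname accessors
setMethod("rescaledTimes", "DissociationSample", function(object) object@rescaledTimes)
#' @rdname accessors
setMethod("wallTimes", "DissociationSample", function(object) object@wallTimes)
#' @rdname accessors
setMethod("tauHat", "PoissonFit", function(object) object@tauHat)
#' @rdname accessors
setMethod("pValue", "PoissonFit", function(object) object@pValue)
#' @rdname accessors
setMethod("isReliable", "PoissonFit", function(object) object@reliable)
#' @rdname accessors
setMethod("nEvents", "PoissonFit", function(object) object@nEvents)
#' @rdname accessors
setMethod("meanTau", "BootstrapResult", function(object) object@meanTau)
#' @rdname accessors
setMethod("semTau", "BootstrapResult", function(object) object@semTau)
#' @rdname accessors
setMethod("freeEnergy", "FreeEnergySurface", function(object) object@freeEnergy)
#' @rdname accessors
setMethod("gridEdges", "FreeEnergySurface", function(object) object@edges)
#' @rdname accessors
setMethod("occupiedBins", "FreeEnergySurface", function(object) object@occupied)

#' @export
setMethod("show","BiasSchedule", function(object) {
  cat("BiasSchedule:", object@growthModel,
      sprintf("| stride %g ps | hill %g kcal/mol | cap %g kcal/mol | %g K\n",
              object@depositionStride, object@hillHeight, object@biasCap,
              object@temperature))
})

#' @export
setMethod("show","BiasedTrajectory", function(object) {
  fr <- object@frames
  cat(sprintf("BiasedTrajectory '%s': %d frames, %.1f-%.1f ps, max bias %.2f kcal/mol\n",
              object@ligandId, nrow(fr), min(fr$time), max(fr$time),
              max(fr$bias)))
})

#' @export
setMethod("show","DissociationSample", function(object) {
  cat(sprintf("DissociationSample '%s': %d events, median rescaled time %.3g s\n",
              object@ligandId, length(object@rescaledTimes),
              stats::median(object@rescaledTimes)))
})

#' @export
setMethod("show","PoissonFit", function(object) {
  cat(sprintf("PoissonFit: tau = %.4g s (n = %d)%s\n", object@tauHat,
              object@nEvents,
              if (!object@converged) " [fallback: sample mean]" else ""))
  if (is.finite(object@pValue))
    cat(sprintf("  KS p = %.3g -> %s (threshold %g, strict)\n", object@pValue,
                if (isTRUE(object@reliable)) "reliable" else "not reliable",
                object@threshold))
})

#' @export
setMethod("show","BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: tau = %.4g +/- %.3g s (%d resamples of size %d)\n",
              object@meanTau, object@semTau, object@nBoot, object@sampleSize))
})

#' @export
setMethod("show","WeightedEnsemble", function(object) {
  cat(sprintf("WeightedEnsemble: %d frames x %d observable(s), ESS %.1f\n",
              nrow(object@values), ncol(object@values),
              1 / sum(object@weights^2)))
})

#' @export
setMethod("show","FreeEnergySurface", function(object) {
  dims <- vapply(object@edges, function(e) length(e) - 1L, integer(1))
  cat(sprintf("FreeEnergySurface: %s bins, %d occupied, range 0-%.2f kcal/mol\n",
              paste(dims, collapse = " x "), sum(object@occupied),
              max(object@freeEnergy[object@occupied])))
})

#' @export
setMethod("show","SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: tau_true = %.4g s, %d draws, %d planted pair(s), seed %d\n",
              object@tauTrue, length(object@rescaledTimesTrue),
              sum(object@plantedWeights != 0), object@seed))
})

#' @export
setMethod("show","CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult: log10(%s) vs log10(%s) [%s]\n",
              object@xField, object@yField, object@subsetRule))
  cat(sprintf("  n = %d, r = %.3f, slope = %.3f, intercept = %.3f\n",
              object@n, object@r, object@slope, object@intercept))
  if (length(object@excluded))
    cat("  excluded (missing values):", paste(object@excluded, collapse = ", "), "\n")
})
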