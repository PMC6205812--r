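## Accessor generics. Slot access from user code is discouraged; these are the
## supported surface.

#' @name accessors
#' @title Accessors for MechanoATP result and data classes
#' @description Small, read-only accessors for the S4 containers. Each returns
#'   the corresponding slot; `activationRate()` additionally errors on a
#'   transient with no measurable response, since the rate is undefined there.
#' @param x an object of the documented class.
#' @return The slot value (numeric, character, data.frame as documented).
NULL

#' @rdname accessors
#' @export
setGeneric("roiId", function(x) standardGeneric("roiId"))

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("stimulusTime", function(x) standardGeneric("stimulusTime"))

#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @rdname accessors
#' @export
setGeneric("tAct", function(x) standardGeneric("tAct"))

#' @rdname accessors
#' @export
setGeneric("tauDecay", function(x) standardGeneric("tauDecay"))

#' @rdname accessors
#' @export
setGeneric("activationRate", function(x) standardGeneric("activationRate"))

#' @rdname accessors
#' @export
setGeneric("percentResponders", function(x) standardGeneric("percentResponders"))

#' @rdname accessors
#' @export
setGeneric("perNeighbor", function(x) standardGeneric("perNeighbor"))

#' @rdname accessors
#' @export
setGeneric("sourceStrength", function(x) standardGeneric("sourceStrength"))

#' @rdname accessors
#' @export
setGeneric("totalAmount", function(x) standardGeneric("totalAmount"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("basalDensity", function(x) standardGeneric("basalDensity"))

#' @rdname accessors
#' @export
setGeneric("cumulativeRelease", function(x) standardGeneric("cumulativeRelease"))

#' @rdname accessors
#' @export
setGeneric("injuryClass", function(x) standardGeneric("injuryClass"))

#' @rdname accessors
#' @export
setGeneric("retainedFraction", function(x) standardGeneric("retainedFraction"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

## -- methods ----------------------------------------------------------------

#' @rdname accessors
setMethod("roiId", "FluorescenceTrace", function(x) x@roiId)
#' @rdname accessors
setMethod("roiId", "TransientParams", function(x) x@roiId)
#' @rdname accessors
setMethod("roiId", "InjuryCall", function(x) x@roiId)

#' @rdname accessors
setMethod("traceTimes", "FluorescenceTrace", function(x) x@times)
#' @rdname accessors
setMethod("traceValues", "FluorescenceTrace", function(x) x@values)
#' @rdname accessors
setMethod("samplingRate", "FluorescenceTrace", function(x) x@samplingRate)
#' @rdname accessors
setMethod("stimulusTime", "FluorescenceTrace", function(x) x@stimulusTime)

#' @rdname accessors
setMethod("amplitude", "TransientParams", function(x) x@amplitude)
#' @rdname accessors
setMethod("tAct", "TransientParams", function(x) x@tAct)
#' @rdname accessors
setMethod("tauDecay", "TransientParams", function(x) x@tauDecay)

#' @rdname accessors
setMethod("activationRate", "TransientParams", function(x) {
    if (!is.finite(x@tAct) || x@tAct <= 0 || x@amplitude <= 0)
        stop("activation rate undefined: transient has no measurable response")
    x@amplitude / x@tAct
})

#' @rdname accessors
setMethod("percentResponders", "SecondaryResponseSummary",
          function(x) x@percentResponders)
#' @rdname accessors
setMethod("perNeighbor", "SecondaryResponseSummary", function(x) x@perNeighbor)

#' @rdname accessors
setMethod("sourceStrength", "SourceEstimate", function(x) x@sigma)
#' @rdname accessors
setMethod("totalAmount", "SourceEstimate", function(x) x@MTotal)

#' @rdname accessors
setMethod("eventTable", "VesicleKinetics", function(x) x@events)
#' @rdname accessors
setMethod("basalDensity", "VesicleKinetics", function(x) x@density)
#' @rdname accessors
setMethod("cumulativeRelease", "VesicleKinetics", function(x) x@cumulative)

#' @rdname accessors
setMethod("injuryClass", "InjuryCall", function(x) x@klass)
#' @rdname accessors
setMethod("retainedFraction", "InjuryCall", function(x) x@retainedFraction)

## -- show methods -----------------------------------------------------------

setMethod("show", "FluorescenceTrace", function(object) {
    cat(sprintf(
        "FluorescenceTrace '%s': %d samples @ %.3g Hz, t = [%.3g, %.3g] s, stimulus at %.3g s\n",
        object@roiId, length(object@values), object@samplingRate,
        object@times[1L], object@times[length(object@times)],
        object@stimulusTime))
})

setMethod("show", "TransientParams", function(object) {
    cat(sprintf("TransientParams '%s'\n", object@roiId))
    cat(sprintf("  baseline  %.4g   amplitude %.4g\n",
                object@baseline, object@amplitude))
    cat(sprintf("  tPeak     %.4g s tAct      %.4g s tauDecay %.4g s\n",
                object@tPeak, object@tAct, object@tauDecay))
    cat(sprintf("  activation rate %.4g /s  decay-fit R2 %.3f\n",
                object@activationRate, object@fitR2))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "FieldRecording", function(object) {
    cat(sprintf("FieldRecording: primary '%s' + %d neighbors\n",
                object@primaryId, length(object@traces) - 1L))
})

setMethod("show", "SecondaryResponseSummary", function(object) {
    cat(sprintf("SecondaryResponseSummary: %d/%d neighbors responded (%.1f%%)\n",
                object@nResponders, object@nNeighbors,
                object@percentResponders))
})

setMethod("show", "CalibrationCurve", function(object) {
    cat(sprintf(
        "CalibrationCurve (%s): log10(signal) = %.4g + %.4g log10([ATP]/uM)\n",
        object@model, object@intercept, object@slope))
    cat(sprintf("  valid range %.3g - %.3g uM, residual SD %.3g (log10)\n",
                object@validRange[1L], object@validRange[2L],
                object@residualSd))
})

setMethod("show", "ConcentrationProfile", function(object) {
    cat(sprintf(
        "ConcentrationProfile: %d observations, x in [%.3g, %.3g] um, t in [%.3g, %.3g] s\n",
        length(object@distances), min(object@distances),
        max(object@distances), min(object@times), max(object@times)))
})

setMethod("show", "SourceEstimate", function(object) {
    cat(sprintf("SourceEstimate (%s%s):\n", object@method,
                if (object@converged) "" else ", fallback"))
    cat(sprintf("  sigma %.4g amol/um^2, M %.4g amol (area %.4g um^2)\n",
                object@sigma, object@MTotal, object@effectiveArea))
    cat(sprintf("  D %.4g um^2/s, t0 offset %.3g s, R2 %.4f\n",
                object@D, object@t0Offset, object@r2))
})

setMethod("show", "RationalFit", function(object) {
    cat(sprintf(
        "RationalFit: y = %.4g x / (%.4g + x); asymptote %.4g, RSS %.3g\n",
        object@a, object@b, object@asymptote, object@rss))
})

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf(
        "ImageStack: %d x %d px, %d frames, %.3g um/px, %.3g s/frame%s\n",
        d[1L], d[2L], d[3L], object@pixelSize, object@frameInterval,
        if (is.null(object@cellMask)) "" else sprintf(
            ", cell mask %.4g um^2",
            sum(object@cellMask != 0) * object@pixelSize^2)))
})

setMethod("show", "PunctaSet", function(object) {
    cat(sprintf("PunctaSet: %d puncta (frame %d)\n",
                nrow(object@centroids), object@frameIndex))
})

setMethod("show", "VesicleKinetics", function(object) {
    cat(sprintf("VesicleKinetics: density %.4g /um^2, %d events\n",
                object@density, nrow(object@events)))
    if (length(object@cumulative))
        cat(sprintf("  cumulative release over %.3g s: %.4g /um^2\n",
                    object@windowS, object@cumulative[length(object@cumulative)]))
})

setMethod("show", "InjuryCall", function(object) {
    cat(sprintf("InjuryCall '%s': %s (retained fraction %.3f)\n",
                object@roiId, object@klass, object@retainedFraction))
})

setMethod("show", "LesionBracket", function(object) {
    cat(sprintf("LesionBracket: [%.3g, %s) nm over %d dyes\n",
                object@lowerNm,
                if (is.finite(object@upperNm))
                    sprintf("%.3g", object@upperNm) else "Inf",
                nrow(object@dyes)))
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth (%s), seed %d; parameters: %s\n", object@kind,
                object@seed, paste(names(object@parameters), collapse = ", ")))
})
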