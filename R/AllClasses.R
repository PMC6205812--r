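#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## Calcium signal containers
## ---------------------------------------------------------------------------

#' FluorescenceTrace: a single-ROI fluorescence time series
#'
#' Holds one uniformly sampled fluorescence recording from a region of
#' interest: either a ratiometric Fura-2 signal (f340/f380, dimensionless) or
#' a raw intensity channel (e.g. 340 ex / 510 em for dye-leakage assays, or a
#' pericellular luciferin signal). The stimulus time marks the application of
#' the mechanical stimulus and splits the trace into a pre-stimulus baseline
#' window and a response segment.
#'
#' @slot roiId character, identifier of the region of interest.
#' @slot times numeric, sample times in seconds, strictly increasing and
#'   uniformly spaced (within 1\% jitter).
#' @slot values numeric, fluorescence values (ratio units or intensity).
#' @slot samplingRate numeric, acquisition rate in Hz (2 Hz in the standard
#'   protocol).
#' @slot stimulusTime numeric, stimulus application time in seconds; must lie
#'   within the recorded interval.
#'
#' @seealso [FluorescenceTrace()] for construction,
#'   [characterizeTransient()], [classifyInjuryTrace()]
#' @exportClass FluorescenceTrace
setClass("FluorescenceTrace",
    representation(
        roiId = "character",
        times = "numeric",
        values = "numeric",
        samplingRate = "numeric",
        stimulusTime = "numeric"
    )
)

setValidity("FluorescenceTrace", function(object) {
    msg <- character()
    if (length(object@times) != length(object@values))
        msg <- c(msg, "'times' and 'values' must have equal length")
    if (length(object@times) >= 2L && any(diff(object@times) <= 0))
        msg <- c(msg, "'times' must be strictly increasing")
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
        msg <- c(msg, "'samplingRate' must be a single positive number")
    if (!all(is.finite(object@values)))
        msg <- c(msg, "'values' must be finite")
    if (length(object@stimulusTime) != 1L || !is.finite(object@stimulusTime))
        msg <- c(msg, "'stimulusTime' must be a single finite number")
    else if (length(object@times) &&
             (object@stimulusTime < object@times[1L] ||
              object@stimulusTime > object@times[length(object@times)]))
        msg <- c(msg, "'stimulusTime' must lie within the recorded interval")
    if (length(msg)) msg else TRUE
})

#' Construct a FluorescenceTrace
#'
#' @param roiId region-of-interest identifier.
#' @param times sample times (s), strictly increasing. If missing, a uniform
#'   grid starting at 0 is built from `samplingRate`.
#' @param values fluorescence values (ratio or intensity units).
#' @param samplingRate acquisition rate (Hz). Defaults to the grid spacing of
#'   `times` when those are supplied.
#' @param stimulusTime stimulus application time (s).
#' @return A [FluorescenceTrace-class] object.
#' @examples
#' tr <- FluorescenceTrace("cell1", values = rep(1, 41),
#'                         samplingRate = 2, stimulusTime = 10)
#' @export
FluorescenceTrace <- function(roiId, times = NULL, values, samplingRate = NULL,
                              stimulusTime) {
    if (is.null(times)) {
        if (is.null(samplingRate))
            stop("supply either 'times' or 'samplingRate'")
        times <- seq(0, by = 1 / samplingRate, length.out = length(values))
    }
    if (is.null(samplingRate))
        samplingRate <- 1 / stats::median(diff(times))
    new("FluorescenceTrace", roiId = as.character(roiId), times = times,
        values = values, samplingRate = samplingRate,
        stimulusTime = stimulusTime)
}

#' TransientParams: descriptors of one calcium transient
#'
#' Parameterization of a single evoked transient: pre-stimulus baseline level,
#' response amplitude above baseline, time of peak, 10--90\% activation time,
#' exponential decay constant of the deactivation phase, and the activation
#' rate (amplitude / activation time). `fitR2` reports the goodness of the
#' exponential decay fit; `flags` records degenerate conditions
#' (`"no_response"`, `"decay_fit_failed"`, `"peak_truncated"`).
#'
#' @slot roiId character.
#' @slot baseline numeric, ratio units.
#' @slot amplitude numeric, ratio units above baseline (>= 0).
#' @slot tPeak numeric, peak time (s, absolute).
#' @slot tAct numeric, 10--90\% rise time (s); `NA` when no response.
#' @slot tauDecay numeric, decay constant (s); `NA` when the fit fails.
#' @slot activationRate numeric, amplitude / tAct (ratio units/s).
#' @slot fitR2 numeric, R^2 of the decay fit.
#' @slot flags character vector of quality flags.
#' @exportClass TransientParams
setClass("TransientParams",
    representation(
        roiId = "character",
        baseline = "numeric",
        amplitude = "numeric",
        tPeak = "numeric",
        tAct = "numeric",
        tauDecay = "numeric",
        activationRate = "numeric",
        fitR2 = "numeric",
        flags = "character"
    )
)

setValidity("TransientParams", function(object) {
    msg <- character()
    if (is.finite(object@amplitude) && object@amplitude < 0)
        msg <- c(msg, "'amplitude' must be >= 0")
    if (is.finite(object@tAct) && object@tAct <= 0 && object@amplitude > 0)
        msg <- c(msg, "'tAct' must be > 0 for a nonzero response")
    if (is.finite(object@tauDecay) && object@tauDecay <= 0)
        msg <- c(msg, "'tauDecay' must be > 0 when defined")
    if (length(msg)) msg else TRUE
})

#' FieldRecording: a stimulated cell and its neighbors
#'
#' A multi-ROI recording from one micropipette-stimulation experiment: the
#' mechanically stimulated (primary) cell plus neighboring (secondary) cells,
#' with ROI centroid positions in micrometers used to relate response delays
#' to distance.
#'
#' @slot traces list of [FluorescenceTrace-class], named by ROI id.
#' @slot positions numeric matrix, one row per ROI (x, y in um), rownames are
#'   ROI ids.
#' @slot primaryId character, ROI id of the stimulated cell.
#' @exportClass FieldRecording
setClass("FieldRecording",
    representation(
        traces = "list",
        positions = "matrix",
        primaryId = "character"
    )
)

setValidity("FieldRecording", function(object) {
    msg <- character()
    ids <- vapply(object@traces, function(tr) tr@roiId, character(1))
    if (!object@primaryId %in% ids)
        msg <- c(msg, "'primaryId' must match the roiId of one trace")
    if (!is.null(object@positions) && nrow(object@positions)) {
        if (!all(is.finite(object@positions)))
            msg <- c(msg, "'positions' must be finite")
        if (!all(ids %in% rownames(object@positions)))
            msg <- c(msg, "every trace must have a row in 'positions'")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname FieldRecording-class
#' @param traces list of [FluorescenceTrace-class] objects.
#' @param positions matrix of ROI centroids (um), rownames = ROI ids.
#' @param primaryId identifier of the stimulated cell.
#' @return A [FieldRecording-class] object.
#' @export
FieldRecording <- function(traces, positions, primaryId) {
    ids <- vapply(traces, function(tr) tr@roiId, character(1))
    names(traces) <- ids
    new("FieldRecording", traces = traces, positions = positions,
        primaryId = as.character(primaryId))
}

#' SecondaryResponseSummary: responder calls for the neighbors of a field
#'
#' @slot nNeighbors integer count of neighboring (non-primary) ROIs.
#' @slot nResponders integer count of neighbors called as responders.
#' @slot percentResponders numeric, 100 * nResponders / nNeighbors.
#' @slot perNeighbor data.frame with columns `roi_id`, `responded`,
#'   `delay_s`, `activation_rate`.
#' @exportClass SecondaryResponseSummary
setClass("SecondaryResponseSummary",
    representation(
        nNeighbors = "integer",
        nResponders = "integer",
        percentResponders = "numeric",
        perNeighbor = "data.frame"
    )
)

setValidity("SecondaryResponseSummary", function(object) {
    msg <- character()
    if (object@nResponders < 0L || object@nResponders > object@nNeighbors)
        msg <- c(msg, "'nResponders' must lie in [0, nNeighbors]")
    if (object@nNeighbors > 0L &&
        abs(object@percentResponders -
            100 * object@nResponders / object@nNeighbors) > 1e-9)
        msg <- c(msg, "'percentResponders' inconsistent with counts")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ATP quantification containers
## ---------------------------------------------------------------------------

#' CalibrationCurve: log-log linear luciferin/luciferase ATP calibration
#'
#' Fitted relation log10(signal) = intercept + slope * log10([ATP]/uM), valid
#' over the concentration range spanned by the standards. Conversions outside
#' that range are returned but flagged as extrapolated.
#'
#' @slot model character, `"loglog-linear"`.
#' @slot slope numeric, > 0 (signal increases with ATP).
#' @slot intercept numeric, log10 signal units.
#' @slot validRange numeric length-2, min/max standard concentration (uM).
#' @slot residualSd numeric, residual SD of the fit in log10 units.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
    representation(
        model = "character",
        slope = "numeric",
        intercept = "numeric",
        validRange = "numeric",
        residualSd = "numeric"
    )
)

setValidity("CalibrationCurve", function(object) {
    msg <- character()
    if (object@slope <= 0)
        msg <- c(msg, "'slope' must be > 0")
    if (length(object@validRange) != 2L ||
        object@validRange[1L] >= object@validRange[2L])
        msg <- c(msg, "'validRange' must be c(min, max) with min < max")
    if (length(msg)) msg else TRUE
})

#' ConcentrationProfile: pericellular [ATP] observations
#'
#' A set of (distance, time, concentration) triples measured around a
#' stimulated cell, typically within the pericellular region (< 15 um from
#' the cell). The triples may come from spatial profiles at fixed times,
#' temporal decays at fixed distances, or any mixture; the plane-source fit
#' uses them jointly.
#'
#' @slot distances numeric, um from the source plane (>= 0).
#' @slot times numeric, s since stimulus (> 0).
#' @slot concentrations numeric, uM (>= 0).
#' @slot regionLimit numeric, pericellular limit in um (default 15).
#' @exportClass ConcentrationProfile
setClass("ConcentrationProfile",
    representation(
        distances = "numeric",
        times = "numeric",
        concentrations = "numeric",
        regionLimit = "numeric"
    ),
    prototype(regionLimit = 15)
)

setValidity("ConcentrationProfile", function(object) {
    msg <- character()
    n <- length(object@distances)
    if (length(object@times) != n || length(object@concentrations) != n)
        msg <- c(msg, "'distances', 'times', 'concentrations' must have equal length")
    if (any(object@distances < 0))
        msg <- c(msg, "'distances' must be >= 0")
    if (any(object@times <= 0))
        msg <- c(msg, "'times' must be > 0")
    if (any(object@concentrations < 0))
        msg <- c(msg, "'concentrations' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname ConcentrationProfile-class
#' @param distances um from the source plane.
#' @param times s since release.
#' @param concentrations uM.
#' @param regionLimit pericellular region limit (um).
#' @return A [ConcentrationProfile-class] object.
#' @export
ConcentrationProfile <- function(distances, times, concentrations,
                                 regionLimit = 15) {
    new("ConcentrationProfile", distances = distances, times = times,
        concentrations = concentrations, regionLimit = regionLimit)
}

#' SourceEstimate: fitted instantaneous-plane-source strength
#'
#' Result of fitting the plane-source diffusion law to a
#' [ConcentrationProfile-class]: the areal source strength sigma (amol/um^2),
#' the implied total released amount M = sigma * effectiveArea (amol), the
#' diffusion coefficient used, an optional release-time offset, and fit
#' diagnostics.
#'
#' @slot sigma numeric, areal source strength (amol/um^2, >= 0).
#' @slot MTotal numeric, total amount (amol); equals sigma * effectiveArea.
#' @slot effectiveArea numeric, um^2 (NA when not supplied).
#' @slot D numeric, diffusion coefficient (um^2/s, > 0).
#' @slot t0Offset numeric, release-time offset (s; 0 unless fitted).
#' @slot rss numeric, residual sum of squares (uM^2).
#' @slot r2 numeric, coefficient of determination.
#' @slot method character, `"linear"` (closed form) or `"nls"`.
#' @slot converged logical, FALSE when a nonlinear fit fell back to the
#'   closed-form solution.
#' @exportClass SourceEstimate
setClass("SourceEstimate",
    representation(
        sigma = "numeric",
        MTotal = "numeric",
        effectiveArea = "numeric",
        D = "numeric",
        t0Offset = "numeric",
        rss = "numeric",
        r2 = "numeric",
        method = "character",
        converged = "logical"
    )
)

setValidity("SourceEstimate", function(object) {
    msg <- character()
    if (object@sigma < 0) msg <- c(msg, "'sigma' must be >= 0")
    if (object@D <= 0) msg <- c(msg, "'D' must be > 0")
    if (is.finite(object@effectiveArea) &&
        abs(object@MTotal - object@sigma * object@effectiveArea) >
            1e-9 * max(1, abs(object@MTotal)))
        msg <- c(msg, "'MTotal' must equal sigma * effectiveArea")
    if (length(msg)) msg else TRUE
})

#' RationalFit: saturating dose-response fit y = a x / (b + x)
#'
#' First-order rational (Michaelis-type) fit of release against stimulus dose;
#' `a` is the horizontal asymptote (maximal response), `b` the half-saturating
#' dose.
#'
#' @slot a numeric, asymptote (response units, > 0).
#' @slot b numeric, half-saturation dose (> 0).
#' @slot rss numeric, residual sum of squares.
#' @slot asymptote numeric, equal to `a` by construction.
#' @exportClass RationalFit
setClass("RationalFit",
    representation(a = "numeric", b = "numeric", rss = "numeric",
                   asymptote = "numeric")
)

setValidity("RationalFit", function(object) {
    msg <- character()
    if (object@a <= 0 || object@b <= 0)
        msg <- c(msg, "'a' and 'b' must be > 0")
    if (!identical(object@asymptote, object@a))
        msg <- c(msg, "'asymptote' must equal 'a'")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Vesicle imaging containers
## ---------------------------------------------------------------------------

#' ImageStack: a fluorescence time-lapse recording
#'
#' Frames are stored as a numeric array (rows x cols x frames) with pixel
#' size and frame interval metadata; the optional cell mask marks the
#' footprint of the imaged cell (nonzero pixels) and supplies the area used
#' to normalize vesicle counts.
#'
#' @slot frames numeric 3-D array, dim = c(nrow, ncol, nframes).
#' @slot pixelSize numeric, um/pixel (> 0).
#' @slot frameInterval numeric, s between frames (> 0; 0.5 s at 2 Hz).
#' @slot cellMask matrix (logical/numeric) of the frame dimensions, or NULL.
#' @exportClass ImageStack
setClass("ImageStack",
    representation(
        frames = "array",
        pixelSize = "numeric",
        frameInterval = "numeric",
        cellMask = "matrixOrNULL"
    )
)

setValidity("ImageStack", function(object) {
    msg <- character()
    d <- dim(object@frames)
    if (length(d) != 3L)
        msg <- c(msg, "'frames' must be a 3-D array (rows x cols x frames)")
    if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
    if (object@frameInterval <= 0) msg <- c(msg, "'frameInterval' must be > 0")
    if (!is.null(object@cellMask) && length(d) == 3L &&
        !identical(dim(object@cellMask), d[1:2]))
        msg <- c(msg, "'cellMask' must match the frame dimensions")
    if (length(msg)) msg else TRUE
})

#' @rdname ImageStack-class
#' @param frames 3-D array or list of matrices.
#' @param pixelSize um/pixel.
#' @param frameInterval s between frames.
#' @param cellMask optional matrix, nonzero = cell.
#' @return An [ImageStack-class] object.
#' @export
ImageStack <- function(frames, pixelSize, frameInterval, cellMask = NULL) {
    if (is.list(frames))
        frames <- array(unlist(frames),
                        dim = c(dim(frames[[1L]]), length(frames)))
    new("ImageStack", frames = frames, pixelSize = pixelSize,
        frameInterval = frameInterval, cellMask = cellMask)
}

#' PunctaSet: detected vesicle puncta in one frame
#'
#' @slot centroids numeric matrix (n x 2), x/y in um.
#' @slot radii numeric, detection scale per punctum (um, > 0).
#' @slot intensities numeric, blob response or intensity at the maximum.
#' @slot frameIndex integer, frame the detection was run on.
#' @exportClass PunctaSet
setClass("PunctaSet",
    representation(
        centroids = "matrix",
        radii = "numeric",
        intensities = "numeric",
        frameIndex = "integer"
    )
)

setValidity("PunctaSet", function(object) {
    msg <- character()
    if (nrow(object@centroids) && ncol(object@centroids) != 2L)
        msg <- c(msg, "'centroids' must have two columns (x, y)")
    if (any(object@radii <= 0))
        msg <- c(msg, "'radii' must be > 0")
    if (length(msg)) msg else TRUE
})

#' VesicleKinetics: exocytosis events and release kinetics for one cell
#'
#' @slot density numeric, basal vesicular density (vesicles/um^2).
#' @slot events data.frame of release events: `t_s`, `x_um`, `y_um`,
#'   `punctum_id`, `delta_intensity`, `partial`.
#' @slot rateTimecourse numeric per frame, events/s/um^2.
#' @slot cumulative numeric per frame, vesicles/um^2 released since stimulus.
#' @slot windowS numeric, summary window (s, default 100).
#' @slot cellArea numeric, um^2 used for normalization (NA if no mask).
#' @exportClass VesicleKinetics
setClass("VesicleKinetics",
    representation(
        density = "numeric",
        events = "data.frame",
        rateTimecourse = "numeric",
        cumulative = "numeric",
        windowS = "numeric",
        cellArea = "numeric"
    )
)

setValidity("VesicleKinetics", function(object) {
    msg <- character()
    if (length(object@cumulative) >= 2L &&
        any(diff(object@cumulative) < -1e-12))
        msg <- c(msg, "'cumulative' must be non-decreasing")
    if (length(object@cumulative) && is.finite(object@density) &&
        max(object@cumulative) > object@density + 1e-12)
        msg <- c(msg, "'cumulative' cannot exceed the basal density")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Membrane injury containers
## ---------------------------------------------------------------------------

#' InjuryCall: membrane-injury classification of one stimulated cell
#'
#' Classes follow the dye-leakage taxonomy: minor (`mIn`, fluorescence returns
#' to baseline), intermediate (`iIn`, partially reduced) and severe (`sIn`,
#' complete loss of intracellular dye).
#'
#' @slot roiId character.
#' @slot klass character, one of `"mIn"`, `"iIn"`, `"sIn"`.
#' @slot baseline numeric, pre-stimulus intensity.
#' @slot postPlateau numeric, post-stimulus plateau intensity.
#' @slot retainedFraction numeric in [0, 1], floor-referenced fraction of
#'   baseline fluorescence retained.
#' @exportClass InjuryCall
setClass("InjuryCall",
    representation(
        roiId = "character",
        klass = "character",
        baseline = "numeric",
        postPlateau = "numeric",
        retainedFraction = "numeric"
    )
)

setValidity("InjuryCall", function(object) {
    msg <- character()
    if (!object@klass %in% c("mIn", "iIn", "sIn"))
        msg <- c(msg, "'klass' must be one of mIn, iIn, sIn")
    if (object@retainedFraction < 0 || object@retainedFraction > 1)
        msg <- c(msg, "'retainedFraction' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' LesionBracket: permeability-derived bounds on membrane lesion radius
#'
#' The lesion must be at least as large as the largest tracer that crossed the
#' membrane (lower bound) and smaller than the smallest tracer that was
#' excluded (upper bound; `Inf` when no tracer was excluded).
#'
#' @slot lowerNm numeric, largest permeant dye radius (nm).
#' @slot upperNm numeric, smallest excluded dye radius (nm), possibly `Inf`.
#' @slot dyes data.frame of the dye table used (name, mw_da, radius_nm,
#'   permeant).
#' @exportClass LesionBracket
setClass("LesionBracket",
    representation(lowerNm = "numeric", upperNm = "numeric",
                   dyes = "data.frame")
)

setValidity("LesionBracket", function(object) {
    if (is.finite(object@upperNm) && object@lowerNm >= object@upperNm)
        "'lowerNm' must be < 'upperNm' when both are defined"
    else TRUE
})

## ---------------------------------------------------------------------------
## Ground truth sidecar
## ---------------------------------------------------------------------------

#' GroundTruth: generating parameters of a synthetic artifact
#'
#' Every synthetic-data generator returns its artifact together with a
#' GroundTruth sidecar carrying the generating parameter values (amplitudes,
#' decay constants, source strengths, event times, class labels, ...) and the
#' seed, so that recovery metrics can be computed without re-reading generator
#' internals. Regeneration with the same parameters and seed is bit-identical.
#'
#' @slot kind character, one of `"transient"`, `"field"`, `"profile"`,
#'   `"stack"`, `"injury"`, `"dose"`.
#' @slot parameters named list of generating values.
#' @slot seed integer seed used.
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(kind = "character", parameters = "list", seed = "integer")
)

setValidity("GroundTruth", function(object) {
    if (!object@kind %in% c("transient", "field", "profile", "stack",
                            "injury", "dose"))
        "'kind' must be one of transient/field/profile/stack/injury/dose"
    else TRUE
})
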