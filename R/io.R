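## Readers and writers for the external formats: tidy trace tables
## (CSV + YAML sidecar), multi-page TIFF stacks (float, with a YAML sidecar
## carrying pixel size, frame interval and intensity scale), dye tables, and
## JSON result records.

.sidecarPath <- function(path) {
    paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".yaml")
}

#' Read a tidy trace table
#'
#' The CSV holds long-format columns `time_s`, `roi_id`, `value`; the YAML
#' sidecar holds `sampling_rate_hz`, `stimulus_time_s` and optionally
#' `positions` (a map roi_id -> [x, y] in um) and `primary_roi`. Sampling is
#' validated to be uniform within 1\% jitter. When positions and a primary
#' ROI are present a [FieldRecording-class] is returned, otherwise a named
#' list of [FluorescenceTrace-class] objects.
#'
#' @param csvPath path to the trace CSV.
#' @param yamlPath path to the sidecar (default: csv path with `.yaml`).
#' @return A [FieldRecording-class] or a named list of traces.
#' @export
readTraceTable <- function(csvPath, yamlPath = .sidecarPath(csvPath)) {
    tab <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
    req <- c("time_s", "roi_id", "value")
    if (!all(req %in% names(tab)))
        stop("trace table must have columns time_s, roi_id, value")
    meta <- yaml::read_yaml(yamlPath)
    rate <- meta$sampling_rate_hz
    stim <- meta$stimulus_time_s
    if (is.null(rate) || is.null(stim))
        stop("sidecar must define sampling_rate_hz and stimulus_time_s")
    traces <- lapply(split(tab, tab$roi_id), function(d) {
        d <- d[order(d$time_s), ]
        dtv <- diff(d$time_s)
        if (length(dtv) &&
            (max(dtv) - min(dtv)) > 0.01 * stats::median(dtv))
            stop("non-uniform sampling (> 1% jitter) for ROI '",
                 d$roi_id[1L], "'")
        FluorescenceTrace(d$roi_id[1L], times = d$time_s, values = d$value,
                          samplingRate = rate, stimulusTime = stim)
    })
    if (!is.null(meta$positions) && !is.null(meta$primary_roi)) {
        pos <- do.call(rbind, meta$positions)
        rownames(pos) <- names(meta$positions)
        colnames(pos) <- c("x", "y")
        FieldRecording(traces[rownames(pos)], pos, meta$primary_roi)
    } else {
        traces
    }
}

#' Write traces as a tidy table with a YAML sidecar
#'
#' @param x a [FieldRecording-class] or a list of
#'   [FluorescenceTrace-class] objects.
#' @param csvPath output CSV path.
#' @param yamlPath sidecar path (default: csv path with `.yaml`).
#' @return Invisibly, `csvPath`.
#' @export
writeTraceTable <- function(x, csvPath, yamlPath = .sidecarPath(csvPath)) {
    if (is(x, "FieldRecording")) {
        traces <- x@traces
        meta <- list(
            sampling_rate_hz = traces[[1L]]@samplingRate,
            stimulus_time_s = traces[[1L]]@stimulusTime,
            primary_roi = x@primaryId,
            positions = stats::setNames(
                lapply(seq_len(nrow(x@positions)),
                       function(i) as.numeric(x@positions[i, ])),
                rownames(x@positions)))
    } else {
        traces <- x
        meta <- list(sampling_rate_hz = traces[[1L]]@samplingRate,
                     stimulus_time_s = traces[[1L]]@stimulusTime)
    }
    tab <- do.call(rbind, lapply(traces, function(tr)
        data.frame(time_s = tr@times, roi_id = tr@roiId,
                   value = tr@values)))
    utils::write.csv(tab, csvPath, row.names = FALSE)
    yaml::write_yaml(meta, yamlPath)
    invisible(csvPath)
}

#' Read a time-lapse stack from a multi-page TIFF with a YAML sidecar
#'
#' The sidecar defines `pixel_size_um`, `frame_interval_s`, the intensity
#' scale (`intensity_min`, `intensity_max`) used to map the stored [0, 1]
#' float range back to physical units, and optionally `mask_tiff` (a
#' single-page TIFF, nonzero = cell, resolved relative to the stack path).
#'
#' @param tiffPath path to the stack.
#' @param yamlPath sidecar path (default: tiff path with `.yaml`).
#' @return An [ImageStack-class].
#' @export
readImageStack <- function(tiffPath, yamlPath = .sidecarPath(tiffPath)) {
    pages <- tiff::readTIFF(tiffPath, all = TRUE)
    meta <- yaml::read_yaml(yamlPath)
    if (is.null(meta$pixel_size_um) || is.null(meta$frame_interval_s))
        stop("sidecar must define pixel_size_um and frame_interval_s")
    lo <- if (is.null(meta$intensity_min)) 0 else meta$intensity_min
    hi <- if (is.null(meta$intensity_max)) 1 else meta$intensity_max
    frames <- array(unlist(pages),
                    dim = c(dim(pages[[1L]]), length(pages)))
    frames <- frames * (hi - lo) + lo
    mask <- NULL
    if (!is.null(meta$mask_tiff)) {
        mpath <- file.path(dirname(tiffPath), meta$mask_tiff)
        mask <- (tiff::readTIFF(mpath) > 0) * 1
    }
    new("ImageStack", frames = frames, pixelSize = meta$pixel_size_um,
        frameInterval = meta$frame_interval_s, cellMask = mask)
}

#' Write a time-lapse stack as multi-page float TIFF plus sidecar
#'
#' Intensities are affinely mapped to [0, 1] for storage (32-bit float); the
#' mapping is recorded in the sidecar so [readImageStack()] restores the
#' original values to float precision. The cell mask, if present, is written
#' alongside and referenced from the sidecar.
#'
#' @param stack an [ImageStack-class].
#' @param tiffPath output path.
#' @param yamlPath sidecar path (default: tiff path with `.yaml`).
#' @return Invisibly, `tiffPath`.
#' @export
writeImageStack <- function(stack, tiffPath,
                            yamlPath = .sidecarPath(tiffPath)) {
    stopifnot(is(stack, "ImageStack"))
    lo <- min(stack@frames); hi <- max(stack@frames)
    span <- if (hi > lo) hi - lo else 1
    nf <- dim(stack@frames)[3L]
    pages <- lapply(seq_len(nf), function(k)
        (stack@frames[, , k] - lo) / span)
    tiff::writeTIFF(pages, tiffPath, bits.per.sample = 32L)
    meta <- list(pixel_size_um = stack@pixelSize,
                 frame_interval_s = stack@frameInterval,
                 intensity_min = lo, intensity_max = lo + span)
    if (!is.null(stack@cellMask)) {
        mpath <- paste0(sub("\\.[A-Za-z0-9]+$", "", tiffPath), "_mask.tif")
        tiff::writeTIFF((stack@cellMask != 0) * 1, mpath,
                        bits.per.sample = 8L)
        meta$mask_tiff <- basename(mpath)
    }
    yaml::write_yaml(meta, yamlPath)
    invisible(tiffPath)
}

#' Read/write a dye table
#'
#' CSV with columns `name`, `mw_da`, optional `radius_nm`, logical
#' `permeant`.
#'
#' @param path CSV path.
#' @return data.frame (for the reader); invisibly the path (writer).
#' @export
readDyeTable <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("name", "mw_da", "permeant") %in% names(d)))
        stop("dye table must have columns name, mw_da, permeant")
    d$permeant <- as.logical(d$permeant)
    if (is.null(d$radius_nm)) d$radius_nm <- NA_real_
    d
}

#' @rdname readDyeTable
#' @param dyes data.frame in dye-table layout.
#' @export
writeDyeTable <- function(dyes, path) {
    utils::write.csv(dyes, path, row.names = FALSE)
    invisible(path)
}

#' Read calibration standards
#'
#' CSV with columns `atp_um`, `signal`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readStandards <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("atp_um", "signal") %in% names(d)))
        stop("standards file must have columns atp_um, signal")
    d
}

#' Read a concentration profile
#'
#' CSV with columns `x_um`, `t_s`, `conc_um`.
#'
#' @param path CSV path.
#' @param regionLimit pericellular limit recorded on the object (um).
#' @return A [ConcentrationProfile-class].
#' @export
readProfile <- function(path, regionLimit = 15) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("x_um", "t_s", "conc_um") %in% names(d)))
        stop("profile file must have columns x_um, t_s, conc_um")
    ConcentrationProfile(d$x_um, d$t_s, d$conc_um, regionLimit = regionLimit)
}

#' @rdname readProfile
#' @param profile a [ConcentrationProfile-class].
#' @export
writeProfile <- function(profile, path) {
    utils::write.csv(data.frame(x_um = profile@distances,
                                t_s = profile@times,
                                conc_um = profile@concentrations),
                     path, row.names = FALSE)
    invisible(path)
}

#' Convert a result object to a plain list record
#'
#' Used for JSON export of fit and summary results; see
#' [writeResultJSON()].
#'
#' @param x a result object.
#' @return A named list of plain values.
#' @export
setGeneric("asRecord", function(x) standardGeneric("asRecord"))

#' @rdname asRecord
setMethod("asRecord", "SourceEstimate", function(x)
    list(sigma_amol_per_um2 = x@sigma, M_amol = x@MTotal,
         effective_area_um2 = x@effectiveArea, D_um2_per_s = x@D,
         t0_offset_s = x@t0Offset, rss = x@rss, r2 = x@r2,
         method = x@method, converged = x@converged))

#' @rdname asRecord
setMethod("asRecord", "CalibrationCurve", function(x)
    list(model = x@model, slope = x@slope, intercept = x@intercept,
         valid_range_um = x@validRange, residual_sd_log10 = x@residualSd))

#' @rdname asRecord
setMethod("asRecord", "RationalFit", function(x)
    list(a = x@a, b = x@b, asymptote = x@asymptote, rss = x@rss))

#' @rdname asRecord
setMethod("asRecord", "TransientParams", function(x)
    list(roi_id = x@roiId, baseline = x@baseline, amplitude = x@amplitude,
         t_peak_s = x@tPeak, t_act_s = x@tAct, tau_decay_s = x@tauDecay,
         activation_rate = x@activationRate, fit_r2 = x@fitR2,
         flags = x@flags))

#' @rdname asRecord
setMethod("asRecord", "SecondaryResponseSummary", function(x)
    list(n_neighbors = x@nNeighbors, n_responders = x@nResponders,
         percent_responders = x@percentResponders,
         per_neighbor = x@perNeighbor))

#' @rdname asRecord
setMethod("asRecord", "VesicleKinetics", function(x)
    list(density_per_um2 = x@density, n_events = nrow(x@events),
         events = x@events, window_s = x@windowS,
         cell_area_um2 = x@cellArea,
         cumulative_per_um2 = if (length(x@cumulative))
             x@cumulative[length(x@cumulative)] else NA_real_))

#' @rdname asRecord
setMethod("asRecord", "InjuryCall", function(x)
    list(roi_id = x@roiId, class = x@klass, baseline = x@baseline,
         post_plateau = x@postPlateau,
         retained_fraction = x@retainedFraction))

#' @rdname asRecord
setMethod("asRecord", "LesionBracket", function(x)
    list(lower_nm = x@lowerNm, upper_nm = x@upperNm, dyes = x@dyes))

#' @rdname asRecord
setMethod("asRecord", "GroundTruth", function(x)
    list(kind = x@kind, seed = x@seed, parameters = x@parameters))

#' Write a result object (or list of them) to JSON
#'
#' @param x an object with an [asRecord()] method, or a plain list.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
writeResultJSON <- function(x, path) {
    rec <- if (is.list(x)) x else asRecord(x)
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    invisible(path)
}

#' Write/read a ground-truth sidecar as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON path.
#' @return `writeGroundTruth`: invisibly `path`; `readGroundTruth`: a plain
#'   list (kind, seed, parameters).
#' @export
writeGroundTruth <- function(truth, path) {
    stopifnot(is(truth, "GroundTruth"))
    jsonlite::write_json(asRecord(truth), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE)
}
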