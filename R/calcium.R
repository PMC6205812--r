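## Calcium transient parameterization and secondary responsiveness.

#' Estimate the pre-stimulus baseline of a trace
#'
#' Returns the median of the samples in the window of length `windowS` ending
#' at the stimulus time. Recordings in the standard protocol open with ~10 s
#' of baseline at 2 Hz, i.e. 20 samples; the median is robust to single-frame
#' artifacts.
#'
#' @param trace a [FluorescenceTrace-class].
#' @param windowS length of the baseline window in seconds (default 10).
#' @return The baseline level (same units as the trace values).
#' @examples
#' tr <- FluorescenceTrace("c1", values = c(rep(1, 21), rep(2, 20)),
#'                         samplingRate = 2, stimulusTime = 10)
#' estimateBaseline(tr)
#' @export
estimateBaseline <- function(trace, windowS = 10) {
    stopifnot(is(trace, "FluorescenceTrace"), windowS > 0)
    idx <- baselineIndices(trace, windowS)
    if (length(idx) < 4L)
        stop("insufficient baseline: need >= 4 pre-stimulus samples in the ",
             "window, got ", length(idx))
    stats::median(trace@values[idx])
}

#' Parameterize a single evoked calcium transient
#'
#' Extracts the standard descriptors of one post-stimulus transient:
#' amplitude (maximum post-stimulus value minus baseline), peak time, the
#' 10--90\% activation time `tAct` (linear interpolation between bracketing
#' samples; multiple noise-induced crossings are resolved by taking the last
#' crossing before the peak), the decay constant `tauDecay` from a
#' least-squares fit of `b + A * exp(-(t - tPeak)/tau)` over the deactivation
#' segment, and the activation rate (amplitude / tAct). The decay segment runs
#' from the peak to the first return to within `returnFrac` of baseline
#' (5\% of the amplitude by default) or the end of the trace, whichever comes
#' first. Only the first post-stimulus peak is parameterized; later peaks are
#' ignored.
#'
#' Degenerate inputs are flagged rather than erroring: an amplitude at or
#' below `minAmplitude` yields amplitude 0 with `tAct`/`tauDecay` undefined
#' and flag `"no_response"`; a non-convergent decay fit leaves `tauDecay`
#' undefined with flag `"decay_fit_failed"` while all other fields are still
#' returned.
#'
#' @param trace a [FluorescenceTrace-class] with a post-stimulus segment.
#' @param baseline baseline level, e.g. from [estimateBaseline()].
#' @param minAmplitude detection threshold in trace units (default 0: any
#'   positive excursion is characterized).
#' @param returnFrac fraction of amplitude defining "returned to baseline"
#'   for the decay-fit window (default 0.05).
#' @return A [TransientParams-class] object.
#' @examples
#' sim <- simulateTransient(seed = 1, snr = Inf)
#' characterizeTransient(sim$trace, estimateBaseline(sim$trace))
#' @export
characterizeTransient <- function(trace, baseline, minAmplitude = 0,
                                  returnFrac = 0.05) {
    stopifnot(is(trace, "FluorescenceTrace"), is.finite(baseline))
    t <- trace@times
    v <- trace@values
    post <- which(t >= trace@stimulusTime)
    if (length(post) < 2L)
        stop("trace has no post-stimulus segment to characterize")

    flags <- character()
    ipk <- post[which.max(v[post])]
    amp <- v[ipk] - baseline

    if (amp <= minAmplitude || amp <= 0) {
        return(new("TransientParams", roiId = trace@roiId,
                   baseline = baseline, amplitude = 0,
                   tPeak = NA_real_, tAct = NA_real_, tauDecay = NA_real_,
                   activationRate = NA_real_, fitR2 = NA_real_,
                   flags = "no_response"))
    }
    if (ipk == length(v)) flags <- c(flags, "peak_truncated")

    ## Rising phase: from the last sample before the stimulus up to the peak,
    ## so that a step coincident with the stimulus is still bracketed.
    i0 <- max(1L, post[1L] - 1L)
    rise <- i0:ipk
    lev10 <- baseline + 0.10 * amp
    lev90 <- baseline + 0.90 * amp
    tAct <- NA_real_
    if (length(rise) >= 2L) {
        rl <- rise[-length(rise)]
        up90 <- rl[v[rl] < lev90 & v[rl + 1L] >= lev90]
        if (length(up90)) {
            i90 <- up90[length(up90)]       # last crossing before the peak
            t90 <- crossingTime(t, v, i90, lev90)
            up10 <- rl[rl <= i90 & v[rl] < lev10 & v[rl + 1L] >= lev10]
            if (length(up10)) {
                i10 <- up10[length(up10)]
                t10 <- crossingTime(t, v, i10, lev10)
                tAct <- t90 - t10
            }
        }
    }
    if (!is.finite(tAct) || tAct <= 0) {
        ## Sub-resolution rise (e.g. an ideal step between two samples):
        ## bound it by a tenth of the sampling interval rather than zero.
        tAct <- 0.1 / trace@samplingRate
        flags <- c(flags, "rise_unresolved")
    }

    ## Decay segment: peak -> first return to within returnFrac of baseline.
    dec <- ipk:length(v)
    back <- dec[v[dec] <= baseline + returnFrac * amp]
    if (length(back)) dec <- ipk:back[1L]
    tauDecay <- NA_real_
    fitR2 <- NA_real_
    if (length(dec) >= 4L) {
        td <- t[dec] - t[ipk]
        vd <- v[dec]
        below <- which(vd <= baseline + exp(-1) * amp)
        tau0 <- if (length(below)) max(td[below[1L]], td[2L]) else
                    max(td) / 3
        fit <- tryCatch(
            minpack.lm::nlsLM(vd ~ b + A * exp(-td / tau),
                start = list(b = baseline, A = amp, tau = tau0),
                lower = c(-Inf, 0, 1e-6),
                control = minpack.lm::nls.lm.control(maxiter = 200)),
            error = function(e) NULL)
        if (!is.null(fit)) {
            cf <- stats::coef(fit)
            tauDecay <- unname(cf["tau"])
            rss <- sum(stats::residuals(fit)^2)
            tss <- sum((vd - mean(vd))^2)
            fitR2 <- if (tss > 0) 1 - rss / tss else NA_real_
        } else {
            flags <- c(flags, "decay_fit_failed")
        }
    } else {
        flags <- c(flags, "decay_fit_failed")
    }

    new("TransientParams", roiId = trace@roiId, baseline = baseline,
        amplitude = amp, tPeak = t[ipk], tAct = tAct, tauDecay = tauDecay,
        activationRate = amp / tAct, fitR2 = fitR2, flags = flags)
}

#' Detect secondary responders among the neighbors of a stimulated cell
#'
#' A neighboring cell is called a responder when its post-stimulus signal
#' exceeds its own baseline by `kSd` baseline-window standard deviations for
#' at least `minConsecutive` consecutive samples. The response delay is the
#' onset time of the first qualifying run minus the stimulus time. Secondary
#' responsiveness is the percentage of neighbors called responders.
#'
#' A neighbor whose baseline window has zero variance and whose post-stimulus
#' segment never rises above baseline is a non-responder (no division by
#' zero); zero variance with any genuine elevation still responds because the
#' threshold then sits at the baseline itself plus a negligible guard.
#'
#' @param field a [FieldRecording-class] with at least one neighbor.
#' @param kSd threshold in baseline SD units (default 4).
#' @param minDelayS earliest credible response delay (s); supra-threshold
#'   runs starting earlier than `stimulus + minDelayS` are ignored
#'   (default 0).
#' @param baselineWindowS baseline window length (s, default 10).
#' @param minConsecutive consecutive supra-threshold samples required
#'   (default 2).
#' @return A [SecondaryResponseSummary-class].
#' @export
detectSecondaryResponders <- function(field, kSd = 4, minDelayS = 0,
                                      baselineWindowS = 10,
                                      minConsecutive = 2L) {
    stopifnot(is(field, "FieldRecording"))
    ids <- names(field@traces)
    neighbors <- setdiff(ids, field@primaryId)
    if (!length(neighbors))
        stop("field has no neighbors; secondary responsiveness undefined")

    rows <- lapply(neighbors, function(id) {
        tr <- field@traces[[id]]
        bidx <- baselineIndices(tr, baselineWindowS)
        if (length(bidx) < 4L)
            stop("neighbor '", id, "' lacks a pre-stimulus baseline window")
        bl <- stats::median(tr@values[bidx])
        sdb <- stats::sd(tr@values[bidx])
        guard <- if (sdb > 0) 0 else
            max(1e-12, 1e-9 * max(abs(bl), 1))   # zero-variance guard
        thr <- bl + kSd * sdb + guard
        post <- which(tr@times >= tr@stimulusTime + minDelayS)
        above <- tr@values[post] > thr
        ## first run of >= minConsecutive supra-threshold samples
        onset <- NA_real_
        if (any(above)) {
            r <- rle(above)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            ok <- which(r$values & r$lengths >= minConsecutive)
            if (length(ok))
                onset <- tr@times[post[starts[ok[1L]]]]
        }
        responded <- is.finite(onset)
        rate <- NA_real_
        if (responded) {
            pr <- characterizeTransient(tr, bl)
            if (pr@amplitude > 0 && is.finite(pr@tAct))
                rate <- pr@amplitude / pr@tAct
        }
        data.frame(roi_id = id, responded = responded,
                   delay_s = if (responded)
                       onset - tr@stimulusTime else NA_real_,
                   activation_rate = rate, stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, rows)
    nN <- length(neighbors)
    nR <- sum(per$responded)
    new("SecondaryResponseSummary", nNeighbors = nN, nResponders = nR,
        percentResponders = 100 * nR / nN, perNeighbor = per)
}

#' Pointwise mean-difference curve between two groups of traces
#'
#' Computes the pointwise difference of group means (A minus B) together with
#' the pointwise SEM of the difference, `sqrt(SEM_A^2 + SEM_B^2)`, for
#' stimulus-aligned traces on a common time grid. Used to display the
#' contribution of a pharmacological treatment as the difference between mean
#' vehicle and mean treatment transients.
#'
#' @param groupA,groupB lists of [FluorescenceTrace-class] objects on
#'   identical time grids.
#' @return A data.frame with columns `time_s`, `mean_diff`, `sem_diff`,
#'   `mean_a`, `sem_a`, `mean_b`, `sem_b`.
#' @export
meanDifferenceCurve <- function(groupA, groupB) {
    stopifnot(length(groupA) >= 1L, length(groupB) >= 1L)
    grids <- lapply(c(groupA, groupB), function(tr) tr@times)
    ref <- grids[[1L]]
    same <- vapply(grids, function(g)
        length(g) == length(ref) && all(abs(g - ref) < 1e-9), logical(1))
    if (!all(same))
        stop("traces are not on a common time grid; resample them onto a ",
             "shared grid before computing the difference curve")
    matA <- vapply(groupA, function(tr) tr@values, numeric(length(ref)))
    matB <- vapply(groupB, function(tr) tr@values, numeric(length(ref)))
    matA <- matrix(matA, nrow = length(ref))
    matB <- matrix(matB, nrow = length(ref))
    semA <- apply(matA, 1L, stats::sd) / sqrt(ncol(matA))
    semB <- apply(matB, 1L, stats::sd) / sqrt(ncol(matB))
    if (ncol(matA) == 1L) semA <- rep(0, length(ref))
    if (ncol(matB) == 1L) semB <- rep(0, length(ref))
    data.frame(time_s = ref,
               mean_diff = rowMeans(matA) - rowMeans(matB),
               sem_diff = sqrt(semA^2 + semB^2),
               mean_a = rowMeans(matA), sem_a = semA,
               mean_b = rowMeans(matB), sem_b = semB)
}
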