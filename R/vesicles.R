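## Quinacrine puncta detection and exocytosis event calling by temporal
## reversal of the time-lapse stack.

#' Preprocess a vesicle time-lapse stack
#'
#' Three steps, in order: (1) photobleaching detrend -- each frame is divided
#' by its whole-frame median relative to the first frame, flattening global
#' exponential bleaching; (2) per-frame background subtraction -- the residual
#' after a wide median filter, which removes diffuse cytoplasmic signal while
#' preserving puncta much smaller than the filter radius; (3) robust
#' normalization -- the whole stack is rescaled so that its 1st--99th
#' intensity percentiles map to [0, 1]. Event calling downstream is invariant
#' to the absolute scale, so the normalization is cosmetic but keeps
#' diagnostics comparable across recordings.
#'
#' @param stack an [ImageStack-class] with >= 2 frames.
#' @param medianRadius radius of the background median filter, pixels
#'   (default 6; must exceed the punctum radius).
#' @param detrend,backgroundSubtract,normalize logical switches for the three
#'   steps.
#' @return A preprocessed [ImageStack-class].
#' @export
preprocessStack <- function(stack, medianRadius = 6L, detrend = TRUE,
                            backgroundSubtract = TRUE, normalize = TRUE) {
    stopifnot(is(stack, "ImageStack"))
    fr <- stack@frames
    nf <- dim(fr)[3L]
    if (nf < 2L) stop("need at least 2 frames")
    meds <- apply(fr, 3L, stats::median)
    if (any(meds == 0 & apply(fr, 3L, function(f) all(f == 0))))
        stop("stack contains an all-zero frame")

    if (detrend) {
        if (any(meds <= 0))
            stop("whole-frame medians must be positive for bleach detrending")
        for (k in seq_len(nf))
            fr[, , k] <- fr[, , k] * (meds[1L] / meds[k])
    }

    if (backgroundSubtract) {
        lo <- min(fr); hi <- max(fr)
        span <- if (hi > lo) hi - lo else 1
        for (k in seq_len(nf)) {
            f01 <- (fr[, , k] - lo) / span
            bg <- EBImage::medianFilter(f01, medianRadius) * span + lo
            fr[, , k] <- fr[, , k] - bg
        }
    }

    if (normalize) {
        q <- stats::quantile(fr, c(0.01, 0.99), names = FALSE)
        if (q[2L] > q[1L])
            fr <- (fr - q[1L]) / (q[2L] - q[1L])
        else
            fr <- fr - q[1L]
    }

    new("ImageStack", frames = fr, pixelSize = stack@pixelSize,
        frameInterval = stack@frameInterval, cellMask = stack@cellMask)
}

## Laplacian-of-Gaussian kernel, scale-normalized and sign-flipped so bright
## blobs of scale ~sigma give positive responses.
.logKernel <- function(sigmaPx) {
    half <- max(2L, as.integer(ceiling(4 * sigmaPx)))
    g <- seq(-half, half)
    xx <- outer(rep(1, length(g)), g)
    yy <- t(xx)
    r2 <- xx^2 + yy^2
    G <- exp(-r2 / (2 * sigmaPx^2))
    k <- -(r2 - 2 * sigmaPx^2) / sigmaPx^2 * G   # -sigma^2 * LoG
    k - mean(k)                                   # zero-DC: flat fields -> 0
}

#' Detect vesicle puncta in a single frame
#'
#' Laplacian-of-Gaussian blob detection at scale `sigmaUm`: the frame is
#' convolved with a scale-normalized LoG kernel, local maxima of the response
#' are thresholded at `median + thresholdK * MAD` of the response image, and
#' surviving maxima undergo greedy non-maximum suppression with mutual
#' exclusion radius `sigmaUm` (two blobs closer than that merge into the
#' stronger one). Centroids are refined by intensity-weighted averaging of
#' the response in a small window, and reported in micrometers (x = column,
#' y = row direction).
#'
#' @param frame numeric matrix (one image), finite.
#' @param pixelSize um/pixel.
#' @param sigmaUm blob scale in um, within (0.2, 3).
#' @param thresholdK MAD-threshold multiplier (default 8).
#' @param frameIndex index recorded in the result (default 1).
#' @return A [PunctaSet-class].
#' @export
detectPuncta <- function(frame, pixelSize, sigmaUm = 0.5, thresholdK = 8,
                         frameIndex = 1L) {
    stopifnot(is.matrix(frame), all(is.finite(frame)), pixelSize > 0)
    if (sigmaUm <= 0.2 || sigmaUm >= 3)
        stop("'sigmaUm' must lie in (0.2, 3) um")
    sigmaPx <- sigmaUm / pixelSize
    kern <- .logKernel(sigmaPx)
    resp <- EBImage::filter2(frame, kern)
    resp <- matrix(as.numeric(resp), nrow(frame), ncol(frame))

    thr <- stats::median(resp) + thresholdK * stats::mad(resp)
    rpx <- max(1L, as.integer(round(sigmaPx)))

    ## local maxima: strictly greater than every neighbor in a square window
    ismax <- resp > thr
    nr <- nrow(resp); nc <- ncol(resp)
    for (di in -rpx:rpx) for (dj in -rpx:rpx) {
        if (di == 0L && dj == 0L) next
        shifted <- matrix(-Inf, nr, nc)
        ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
        okR <- ri >= 1L & ri <= nr; okC <- cj >= 1L & cj <= nc
        shifted[okR, okC] <- resp[ri[okR], cj[okC]]
        ismax <- ismax & (resp >= shifted)
        if (!any(ismax)) break
    }
    cand <- which(ismax, arr.ind = TRUE)
    if (!nrow(cand))
        return(new("PunctaSet",
                   centroids = matrix(numeric(), 0L, 2L,
                                      dimnames = list(NULL, c("x", "y"))),
                   radii = numeric(), intensities = numeric(),
                   frameIndex = as.integer(frameIndex)))

    vals <- resp[cand]
    ord <- order(vals, decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    vals <- vals[ord]

    ## greedy NMS with exclusion radius sigmaUm
    exclPx <- sigmaUm / pixelSize
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
        if (i == 1L) { keep[1L] <- TRUE; next }
        kept <- cand[keep, , drop = FALSE]
        d2 <- (kept[, 1L] - cand[i, 1L])^2 + (kept[, 2L] - cand[i, 2L])^2
        keep[i] <- all(d2 > exclPx^2)
    }
    cand <- cand[keep, , drop = FALSE]
    vals <- vals[keep]

    ## sub-pixel refinement: response-weighted centroid in a (2r+1) window
    cen <- matrix(NA_real_, nrow(cand), 2L,
                  dimnames = list(NULL, c("x", "y")))
    inten <- numeric(nrow(cand))
    for (i in seq_len(nrow(cand))) {
        r0 <- cand[i, 1L]; c0 <- cand[i, 2L]
        rs <- max(1L, r0 - rpx):min(nr, r0 + rpx)
        cs <- max(1L, c0 - rpx):min(nc, c0 + rpx)
        w <- pmax(resp[rs, cs, drop = FALSE], 0)
        if (sum(w) == 0) w[] <- 1
        rr <- sum(rowSums(w) * rs) / sum(w)
        ccm <- sum(colSums(w) * cs) / sum(w)
        cen[i, ] <- c(ccm, rr) * pixelSize
        inten[i] <- frame[r0, c0]
    }
    new("PunctaSet", centroids = cen, radii = rep(sigmaUm, nrow(cand)),
        intensities = inten, frameIndex = as.integer(frameIndex))
}

#' Vesicular density
#'
#' Punctum count normalized to the (projected) cell area.
#'
#' @param puncta a [PunctaSet-class].
#' @param cellArea cell area in um^2 (> 0).
#' @return Density in vesicles/um^2.
#' @examples
#' # 35 puncta over 500 um^2 -> 0.07 vesicles/um^2
#' @export
vesicularDensity <- function(puncta, cellArea) {
    stopifnot(is(puncta, "PunctaSet"))
    if (cellArea <= 0) stop("'cellArea' must be > 0")
    nrow(puncta@centroids) / cellArea
}

#' Detect vesicular release events by temporal reversal
#'
#' Identifies abrupt disappearances of fluorescent puncta -- the signature of
#' vesicular exocytosis -- in a time-lapse stack. Puncta are detected once on
#' the average of the first `refFrames` (pre-stimulus) frames; each punctum's
#' mean intensity inside a fixed disk of radius `roiRadiusUm` is then traced
#' over all frames. A disappearance leaves nothing to track, so tracks are
#' anchored at the detection-time centroids (adherent cells do not
#' translocate appreciably over the 2-minute recording).
#'
#' The time axis is then reversed so a sudden loss appears as a sudden rise,
#' and a release event is called where the frame-to-frame increase of the
#' reversed trace exceeds `mean + k * SD` of that punctum's frame-to-frame
#' differences (the two largest-magnitude differences are excluded from the
#' mean/SD so the event itself does not inflate its own threshold), AND the
#' transition completes within `maxRiseFrames` frames: the rise accumulated
#' over `maxRiseFrames` frames must account for at least `completenessFrac`
#' of the total level change across the transition. Vesicles that gradually
#' come in and out of focus spread their intensity change over many frames
#' and fail both tests. At most one release event is called per punctum (a
#' vesicle releases its content once); the strongest candidate wins. Frames
#' whose whole-field median jumps by more than `frameJumpFrac` (focus/stage
#' artifacts) are masked from calling, and puncta within `edgeMarginPx`
#' pixels of the cell-mask boundary are discarded as edge artifacts.
#'
#' Events are mapped back to forward time; the event time is the first frame
#' at which the punctum fluorescence is lost. Density, rate time course
#' (events/s/um^2) and cumulative release (vesicles/um^2) are normalized by
#' the cell-mask area; without a mask the raw event list is still returned
#' but normalized outputs are unavailable.
#'
#' @param stack an [ImageStack-class] (>= 10 frames).
#' @param k event threshold in SD units of the per-punctum frame-to-frame
#'   differences (default 4).
#' @param maxRiseFrames maximum frames for a complete transition (default 2,
#'   i.e. 1 s at 2 Hz).
#' @param completenessFrac fraction of the total level change that must occur
#'   within `maxRiseFrames` (default 0.7).
#' @param minDeltaFrac minimum event size as a fraction of the punctum's
#'   elevation above its darkest level (default 0.35); steps smaller than
#'   this are residual noise or fade tails, not release events.
#' @param sigmaUm,thresholdK passed to [detectPuncta()].
#' @param refFrames number of initial frames averaged for punctum detection
#'   (default 5).
#' @param roiRadiusUm radius of the per-punctum measurement disk (default 1).
#' @param edgeMarginPx discard puncta this close to the mask boundary
#'   (default 2).
#' @param frameJumpFrac whole-field relative intensity jump that masks a
#'   frame (default 0.2).
#' @param windowS summary window for cumulative release (default 100 s).
#' @param stimulusS stimulus time (s) from which the summary window runs
#'   (default: end of the reference frames).
#' @param preprocess run [preprocessStack()] first (default TRUE).
#' @return A [VesicleKinetics-class].
#' @export
detectReleaseEvents <- function(stack, k = 4, maxRiseFrames = 2L,
                                completenessFrac = 0.7,
                                minDeltaFrac = 0.35,
                                sigmaUm = 0.5, thresholdK = 8,
                                refFrames = 5L, roiRadiusUm = 1,
                                edgeMarginPx = 2L, frameJumpFrac = 0.2,
                                windowS = 100, stimulusS = NULL,
                                preprocess = TRUE) {
    stopifnot(is(stack, "ImageStack"))
    nf <- dim(stack@frames)[3L]
    if (nf < 10L) stop("need at least 10 frames for event detection")
    dt <- stack@frameInterval
    if (is.null(stimulusS)) stimulusS <- refFrames * dt

    ## frame-artifact mask from the raw stack (preprocessing flattens medians)
    medsRaw <- apply(stack@frames, 3L, stats::median)
    jump <- c(FALSE, abs(diff(medsRaw)) / pmax(abs(medsRaw[-nf]), 1e-12) >
                     frameJumpFrac)

    mask <- stack@cellMask
    hasMask <- !is.null(mask)
    cellArea <- if (hasMask) sum(mask != 0) * stack@pixelSize^2 else NA_real_
    if (!hasMask)
        warning("no cell mask: density/rate/cumulative are unavailable, ",
                "returning the raw event list only")

    if (preprocess) stack <- preprocessStack(stack)
    fr <- stack@frames
    nr <- dim(fr)[1L]; nc <- dim(fr)[2L]

    ref <- apply(fr[, , seq_len(min(refFrames, nf)), drop = FALSE],
                 c(1L, 2L), mean)
    pts <- detectPuncta(ref, stack@pixelSize, sigmaUm = sigmaUm,
                        thresholdK = thresholdK)

    ## drop puncta outside the mask or within edgeMarginPx of its boundary
    if (hasMask && nrow(pts@centroids)) {
        ok <- vapply(seq_len(nrow(pts@centroids)), function(i) {
            cpx <- round(pts@centroids[i, c("y", "x")] / stack@pixelSize)
            r0 <- cpx[1L]; c0 <- cpx[2L]
            rs <- (r0 - edgeMarginPx):(r0 + edgeMarginPx)
            cs <- (c0 - edgeMarginPx):(c0 + edgeMarginPx)
            if (any(rs < 1L | rs > nr | cs < 1L | cs > nc)) return(FALSE)
            all(mask[rs, cs] != 0)
        }, logical(1))
        pts <- new("PunctaSet", centroids = pts@centroids[ok, , drop = FALSE],
                   radii = pts@radii[ok], intensities = pts@intensities[ok],
                   frameIndex = pts@frameIndex)
    }
    np <- nrow(pts@centroids)
    density <- if (hasMask) np / cellArea else NA_real_

    times <- (seq_len(nf) - 1L) * dt
    emptyEv <- data.frame(t_s = numeric(), x_um = numeric(), y_um = numeric(),
                          punctum_id = integer(),
                          delta_intensity = numeric(), partial = logical())
    if (np == 0L)
        return(new("VesicleKinetics", density = density, events = emptyEv,
                   rateTimecourse = if (hasMask) rep(0, nf) else numeric(),
                   cumulative = if (hasMask) rep(0, nf) else numeric(),
                   windowS = windowS, cellArea = cellArea))

    ## per-punctum disk-mean intensity traces
    rpx <- max(1L, as.integer(round(roiRadiusUm / stack@pixelSize)))
    frMat <- matrix(fr, nr * nc, nf)
    traces <- matrix(NA_real_, np, nf)
    for (i in seq_len(np)) {
        c0 <- round(pts@centroids[i, "x"] / stack@pixelSize)
        r0 <- round(pts@centroids[i, "y"] / stack@pixelSize)
        rs <- max(1L, r0 - rpx):min(nr, r0 + rpx)
        cs <- max(1L, c0 - rpx):min(nc, c0 + rpx)
        grid <- expand.grid(r = rs, c = cs)
        disk <- grid[(grid$r - r0)^2 + (grid$c - c0)^2 <= rpx^2, ]
        idx <- disk$r + (disk$c - 1L) * nr
        traces[i, ] <- colMeans(frMat[idx, , drop = FALSE])
    }

    events <- list()
    for (i in seq_len(np)) {
        v <- traces[i, ]
        u <- rev(v)
        d <- diff(u)
        ## reversed-frame mask: diff j touches reversed frames j, j+1,
        ## i.e. forward frames nf-j+1, nf-j
        dMask <- jump[nf - seq_along(d) + 1L] | jump[nf - seq_along(d)]
        dStat <- d[!dMask]
        if (length(dStat) > 4L) {
            drop2 <- order(abs(dStat), decreasing = TRUE)[1:2]
            dStat <- dStat[-drop2]
        }
        thr <- mean(dStat) + k * stats::sd(dStat)
        cands <- which(d > thr & !dMask)
        if (!length(cands)) next

        ## punctum elevation above its darkest level: the scale a genuine
        ## disappearance must be commensurate with
        elev <- stats::median(v[seq_len(min(5L, nf))]) - min(v)

        best <- NULL
        for (j in cands[order(d[cands], decreasing = TRUE)]) {
            jEnd <- min(j + maxRiseFrames, nf)
            before <- u[max(1L, j - 4L):j]
            after <- u[jEnd:min(jEnd + 4L, nf)]
            total <- stats::median(after) - stats::median(before)
            if (total <= 0) next
            if (total < minDeltaFrac * elev) next
            riseWithin <- max(u[(j + 1L):jEnd]) - u[j]
            if (riseWithin < completenessFrac * total) next
            best <- list(j = j, delta = total)
            break
        }
        if (is.null(best)) next

        fwdFrame <- nf - best$j + 1L      # first frame with fluorescence lost
        preLevel <- stats::median(u[min(best$j + maxRiseFrames, nf):
                                    min(best$j + maxRiseFrames + 4L, nf)])
        postLevel <- stats::median(u[max(1L, best$j - 4L):best$j])
        span <- preLevel - min(v)
        partial <- span > 0 && (best$delta / span) < 0.7
        events[[length(events) + 1L]] <- data.frame(
            t_s = times[fwdFrame],
            x_um = pts@centroids[i, "x"],
            y_um = pts@centroids[i, "y"],
            punctum_id = i,
            delta_intensity = best$delta,
            partial = partial)
    }
    ev <- if (length(events)) do.call(rbind, events) else emptyEv
    ev <- ev[order(ev$t_s), , drop = FALSE]
    rownames(ev) <- NULL

    if (hasMask) {
        counts <- tabulate(findInterval(ev$t_s, times), nbins = nf)
        rate <- counts / dt / cellArea
        inWin <- ev$t_s >= stimulusS & ev$t_s <= stimulusS + windowS
        cum <- cumsum(counts * as.numeric(times >= stimulusS &
                                          times <= stimulusS + windowS)) /
               cellArea
    } else {
        rate <- numeric(); cum <- numeric()
    }

    new("VesicleKinetics", density = density, events = ev,
        rateTimecourse = rate, cumulative = cum, windowS = windowS,
        cellArea = cellArea)
}

#' Fraction of the basal vesicular pool released
#'
#' @param cumulative cumulative release density, vesicles/um^2.
#' @param basalDensity basal vesicular density, vesicles/um^2 (> 0).
#' @return Percentage of the pool released. A value above 100 indicates an
#'   upstream tracking error and is returned with a warning.
#' @examples
#' percentPoolReleased(5e-3, 70e-3)  # ~7.1%
#' @export
percentPoolReleased <- function(cumulative, basalDensity) {
    if (any(basalDensity <= 0)) stop("'basalDensity' must be > 0")
    if (any(cumulative > basalDensity))
        warning("cumulative release exceeds the basal pool; upstream ",
                "tracking error likely")
    100 * cumulative / basalDensity
}
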