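## Synthetic-data generators with embedded ground truth. Every generator is a
## pure function of (parameters, seed): the caller's RNG state is untouched
## and regeneration with the same arguments is bit-identical.

## Noise-free transient shape shared by the generators: flat baseline, a
## raised-cosine ("sigmoidal") rise of duration riseDur starting at onsetS,
## then exponential decay with constant tau from the peak. The 10-90% rise
## time of a raised cosine is 0.59032 * riseDur.
.RISE_FRACTION <- (acos(-0.8) - acos(0.8)) / pi   # 10-90% fraction ~0.59032

.transientSignal <- function(t, baseline, amplitude, riseDur, tau, onsetS) {
    s <- numeric(length(t))
    rising <- t >= onsetS & t < onsetS + riseDur
    s[rising] <- amplitude * (1 - cos(pi * (t[rising] - onsetS) / riseDur)) / 2
    decaying <- t >= onsetS + riseDur
    s[decaying] <- amplitude * exp(-(t[decaying] - onsetS - riseDur) / tau)
    baseline + s
}

#' Simulate a single-cell calcium transient
#'
#' Generates a uniformly sampled ratio trace: flat baseline, a sigmoidal
#' (raised-cosine) rise whose 10--90\% time is `tAct`, then exponential decay
#' with constant `tau`, plus Gaussian noise with SD `amplitude / snr`. The
#' rise duration is snapped to the sampling grid so the true peak falls on a
#' sample; the ground-truth sidecar reports the actually generated `tAct`
#' (which may differ slightly from the request) along with every other
#' generating value.
#'
#' @param baseline baseline ratio (default 1).
#' @param amplitude response amplitude above baseline (default 0.5).
#' @param tAct requested 10--90\% rise time, s (default 2).
#' @param tau decay constant, s (default 20).
#' @param snr amplitude-to-noise-SD ratio; `Inf` for noise-free (default 20).
#' @param rateHz sampling rate (default 2, the acquisition standard).
#' @param durationS recording length, s (default 120).
#' @param stimulusS stimulus time, s (default 10, i.e. a 10 s baseline).
#' @param roiId identifier for the trace (default "sim").
#' @param seed RNG seed.
#' @return list with elements `trace` ([FluorescenceTrace-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' sim <- simulateTransient(seed = 7)
#' characterizeTransient(sim$trace, estimateBaseline(sim$trace))
#' @export
simulateTransient <- function(baseline = 1, amplitude = 0.5, tAct = 2,
                              tau = 20, snr = 20, rateHz = 2,
                              durationS = 120, stimulusS = 10,
                              roiId = "sim", seed = 1) {
    if (snr <= 0) stop("'snr' must be > 0 (use Inf for noise-free)")
    if (durationS <= stimulusS + tAct)
        stop("'durationS' must cover the stimulus plus the rise and decay")
    dt <- 1 / rateHz
    riseDur <- max(dt, round(tAct / .RISE_FRACTION / dt) * dt)
    tActTrue <- riseDur * .RISE_FRACTION
    t <- seq(0, durationS, by = dt)
    sig <- .transientSignal(t, baseline, amplitude, riseDur, tau, stimulusS)
    noiseSd <- if (is.finite(snr)) amplitude / snr else 0
    v <- withSeed(seed, sig + stats::rnorm(length(t), 0, noiseSd))
    trace <- FluorescenceTrace(roiId, times = t, values = v,
                               samplingRate = rateHz,
                               stimulusTime = stimulusS)
    truth <- new("GroundTruth", kind = "transient",
                 parameters = list(baseline = baseline,
                                   amplitude = amplitude,
                                   tAct = tActTrue, tau = tau,
                                   tPeak = stimulusS + riseDur,
                                   snr = snr, noiseSd = noiseSd,
                                   rateHz = rateHz,
                                   stimulusS = stimulusS),
                 seed = as.integer(seed))
    list(trace = trace, truth = truth)
}

#' Simulate a multi-cell field recording
#'
#' A stimulated primary cell plus `nNeighbors` neighboring cells at random
#' positions 20--80 um away. Each neighbor responds with probability
#' `responderProb`; responders show a delayed transient of amplitude
#' `effectSdMultiple` baseline-noise SDs, with onset delay growing with
#' distance (`delayBaseS + delayPerUm * distance`); non-responders show
#' baseline noise only. The ground truth records the responder labels,
#' delays and positions.
#'
#' @param nNeighbors number of neighbors (>= 1, default 10).
#' @param responderProb per-neighbor response probability (default 0.5).
#' @param effectSdMultiple responder amplitude in baseline-noise SD units
#'   (default 8).
#' @param baselineNoiseSd baseline noise SD, ratio units (default 0.02).
#' @param delayBaseS,delayPerUm delay model intercept (s) and slope (s/um)
#'   (defaults 1 and 0.05).
#' @param rateHz,durationS,stimulusS acquisition parameters as in
#'   [simulateTransient()].
#' @param seed RNG seed.
#' @return list with `field` ([FieldRecording-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
simulateFieldRecording <- function(nNeighbors = 10, responderProb = 0.5,
                                   effectSdMultiple = 8,
                                   baselineNoiseSd = 0.02,
                                   delayBaseS = 1, delayPerUm = 0.05,
                                   rateHz = 2, durationS = 120,
                                   stimulusS = 10, seed = 1) {
    stopifnot(nNeighbors >= 1)
    dt <- 1 / rateHz
    t <- seq(0, durationS, by = dt)
    out <- withSeed(seed, {
        ang <- stats::runif(nNeighbors, 0, 2 * pi)
        rad <- stats::runif(nNeighbors, 20, 80)
        pos <- rbind(c(0, 0), cbind(rad * cos(ang), rad * sin(ang)))
        rownames(pos) <- c("primary", paste0("n", seq_len(nNeighbors)))
        colnames(pos) <- c("x", "y")
        responder <- stats::runif(nNeighbors) < responderProb
        delays <- delayBaseS + delayPerUm * rad

        primSig <- .transientSignal(t, 1, 0.5, 2 / .RISE_FRACTION, 20,
                                    stimulusS)
        traces <- vector("list", nNeighbors + 1L)
        traces[[1L]] <- FluorescenceTrace("primary", times = t,
            values = primSig + stats::rnorm(length(t), 0, baselineNoiseSd),
            samplingRate = rateHz, stimulusTime = stimulusS)
        amp <- effectSdMultiple * baselineNoiseSd
        for (i in seq_len(nNeighbors)) {
            sig <- if (responder[i])
                .transientSignal(t, 1, amp, 2 / .RISE_FRACTION, 20,
                                 stimulusS + delays[i])
            else rep(1, length(t))
            traces[[i + 1L]] <- FluorescenceTrace(paste0("n", i), times = t,
                values = sig + stats::rnorm(length(t), 0, baselineNoiseSd),
                samplingRate = rateHz, stimulusTime = stimulusS)
        }
        list(pos = pos, responder = responder, delays = delays,
             traces = traces)
    })
    field <- FieldRecording(out$traces, out$pos, "primary")
    truth <- new("GroundTruth", kind = "field",
                 parameters = list(responder = stats::setNames(
                                       out$responder,
                                       paste0("n", seq_len(nNeighbors))),
                                   delays = out$delays,
                                   responderProb = responderProb,
                                   effectSdMultiple = effectSdMultiple,
                                   baselineNoiseSd = baselineNoiseSd,
                                   positions = out$pos),
                 seed = as.integer(seed))
    list(field = field, truth = truth)
}

#' Simulate pericellular concentration profiles
#'
#' Generates `n` observation sets from the instantaneous plane-source law at
#' areal strength `sigma`, multiplied by lognormal noise with coefficient of
#' variation `noiseCv` (mean 1, so the estimator is unbiased in
#' expectation). The default grids sample the pericellular region (< 15 um)
#' at several early times.
#'
#' @param sigma true areal source strength, amol/um^2 (default 0.05).
#' @param D diffusion coefficient, um^2/s (default [DEFAULT_D_ATP]).
#' @param xGrid distances, um (default 0-12.5 um in 2.5 um steps).
#' @param tGrid times, s (default 0.5, 1, 2, 4).
#' @param noiseCv coefficient of variation of the multiplicative noise
#'   (default 0.05; 0 for noise-free).
#' @param n number of profiles (default 1).
#' @param seed RNG seed.
#' @return list with `profiles` (list of [ConcentrationProfile-class]) and
#'   `truth` ([GroundTruth-class]).
#' @export
simulateSourceProfiles <- function(sigma = 0.05, D = DEFAULT_D_ATP,
                                   xGrid = seq(0, 12.5, by = 2.5),
                                   tGrid = c(0.5, 1, 2, 4),
                                   noiseCv = 0.05, n = 1, seed = 1) {
    stopifnot(noiseCv >= 0, all(tGrid > 0), all(xGrid >= 0), n >= 1)
    grid <- expand.grid(x = xGrid, t = tGrid)
    clean <- planeSourceConcentration(sigma, D, grid$x, grid$t)
    sdlog <- sqrt(log(1 + noiseCv^2))
    profiles <- withSeed(seed, {
        lapply(seq_len(n), function(i) {
            noise <- if (noiseCv > 0)
                stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2,
                              sdlog = sdlog)
            else rep(1, nrow(grid))
            ConcentrationProfile(grid$x, grid$t, clean * noise,
                                 regionLimit = 15)
        })
    })
    truth <- new("GroundTruth", kind = "profile",
                 parameters = list(sigma = sigma, D = D, noiseCv = noiseCv,
                                   xGrid = xGrid, tGrid = tGrid, n = n),
                 seed = as.integer(seed))
    list(profiles = profiles, truth = truth)
}

## Bilinear upsampling of a coarse grid to (nr, nc): smooth background texture.
.smoothField <- function(coarse, nr, nc) {
    cr <- nrow(coarse); ccn <- ncol(coarse)
    ri <- seq(1, cr, length.out = nr)
    ci <- seq(1, ccn, length.out = nc)
    r0 <- pmin(floor(ri), cr - 1L); c0 <- pmin(floor(ci), ccn - 1L)
    fr <- ri - r0; fc <- ci - c0
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) {
        a <- coarse[r0[i], ] * (1 - fr[i]) + coarse[r0[i] + 1L, ] * fr[i]
        out[i, ] <- a[c0] * (1 - fc) + a[c0 + 1L] * fc
    }
    out
}

#' Simulate a quinacrine vesicle time-lapse stack
#'
#' Renders Gaussian puncta on a smooth textured background inside a circular
#' cell mask, over `durationS` at `rateHz`. The first `nEvents` puncta
#' disappear abruptly (within one frame) at random post-stimulus times --
#' the exocytosis ground truth. The next `nFades` puncta fade linearly over
#' `fadeFrames` frames (focus-drift confounders that must not be called as
#' events). The whole field bleaches exponentially with constant
#' `bleachTau`, and Poisson-Gaussian noise is added such that the total
#' noise SD at a punctum peak equals `amplitude / snr`.
#'
#' Puncta are placed with a minimum mutual distance of `minSeparationUm`
#' inside the mask (away from its boundary); if placement fails after many
#' rejections the field is overcrowded and an error is raised.
#'
#' @param nPuncta total puncta (default 20).
#' @param nEvents abrupt disappearances (default 10; <= nPuncta).
#' @param nFades gradual fades (default 5; nEvents + nFades <= nPuncta).
#' @param snr punctum-amplitude-to-noise-SD ratio (default 5).
#' @param bleachTau global bleaching time constant, s (default 200).
#' @param geometry list: `width`, `height` (px), `pixelSizeUm`,
#'   `maskRadiusUm`.
#' @param amplitude punctum peak amplitude, arbitrary units (default 1).
#' @param punctumSigmaUm punctum Gaussian width (default 0.5).
#' @param rateHz frame rate (default 2).
#' @param durationS recording length, s (default 120, i.e. 2 min).
#' @param stimulusS stimulus time (default 10); events occur in
#'   (stimulusS + 2, stimulusS + 95).
#' @param fadeFrames frames over which a fade completes (default 24,
#'   >= 20).
#' @param minSeparationUm minimum punctum spacing (default 2).
#' @param seed RNG seed.
#' @return list with `stack` ([ImageStack-class]) and `truth`
#'   ([GroundTruth-class]); the truth records punctum positions, event
#'   punctum indices and times, and fade punctum indices.
#' @export
simulateVesicleStack <- function(nPuncta = 20, nEvents = 10, nFades = 5,
                                 snr = 5, bleachTau = 200,
                                 geometry = list(width = 64, height = 64,
                                                 pixelSizeUm = 0.4,
                                                 maskRadiusUm = 9.5),
                                 amplitude = 1, punctumSigmaUm = 0.5,
                                 rateHz = 2, durationS = 120,
                                 stimulusS = 10, fadeFrames = 24L,
                                 minSeparationUm = 2, seed = 1) {
    if (nEvents + nFades > nPuncta)
        stop("'nEvents' + 'nFades' must not exceed 'nPuncta'")
    if (snr <= 0) stop("'snr' must be > 0")
    if (fadeFrames < 20L) stop("'fadeFrames' must be >= 20 (gradual fade)")
    nr <- geometry$height; nc <- geometry$width
    px <- geometry$pixelSizeUm
    nf <- as.integer(round(durationS * rateHz))
    dt <- 1 / rateHz
    cx <- (nc + 1) / 2 * px; cy <- (nr + 1) / 2 * px
    maskR <- geometry$maskRadiusUm

    colUm <- (seq_len(nc) - 0.5) * px
    rowUm <- (seq_len(nr) - 0.5) * px
    distC <- sqrt(outer(rowUm - cy, colUm - cx, function(a, b) a^2 + b^2))
    mask <- distC <= maskR

    out <- withSeed(seed, {
        ## punctum positions: inside the mask, 1.5 um off the boundary
        posR <- maskR - 1.5
        pts <- matrix(NA_real_, nPuncta, 2L)
        placed <- 0L; tries <- 0L
        while (placed < nPuncta) {
            tries <- tries + 1L
            if (tries > 20000L)
                stop("overcrowded field: cannot place ", nPuncta,
                     " puncta at ", minSeparationUm, " um spacing")
            a <- stats::runif(1, 0, 2 * pi)
            r <- posR * sqrt(stats::runif(1))
            p <- c(cx + r * cos(a), cy + r * sin(a))
            if (placed > 0L) {
                d2 <- (pts[seq_len(placed), 1L] - p[1L])^2 +
                      (pts[seq_len(placed), 2L] - p[2L])^2
                if (any(d2 < minSeparationUm^2)) next
            }
            placed <- placed + 1L
            pts[placed, ] <- p
        }
        colnames(pts) <- c("x", "y")

        eventFrames <- if (nEvents > 0)
            sort(sample(seq(as.integer((stimulusS + 2) * rateHz),
                            as.integer(min(stimulusS + 95, durationS - 5) *
                                       rateHz)), nEvents))
        else integer()
        fadeStarts <- if (nFades > 0)
            sample(seq(as.integer((stimulusS + 2) * rateHz),
                       nf - fadeFrames - 5L), nFades)
        else integer()

        bgCoarse <- matrix(stats::runif(64, 0.15, 0.25), 8L, 8L)
        bg <- .smoothField(bgCoarse, nr, nc)

        ## per-punctum Gaussian footprints (precomputed)
        sigPx <- punctumSigmaUm / px
        foot <- lapply(seq_len(nPuncta), function(i) {
            r0 <- pts[i, "y"] / px; c0 <- pts[i, "x"] / px
            rs <- max(1L, floor(r0 - 4 * sigPx)):min(nr, ceiling(r0 + 4 * sigPx))
            cs <- max(1L, floor(c0 - 4 * sigPx)):min(nc, ceiling(c0 + 4 * sigPx))
            g <- outer(rs - r0, cs - c0,
                       function(a, b) exp(-(a^2 + b^2) / (2 * sigPx^2)))
            list(rs = rs, cs = cs, g = g)
        })

        ## amplitude of punctum i at frame k
        ampAt <- function(i, k) {
            ev <- match(i, seq_len(nEvents))
            if (!is.na(ev) && nEvents > 0 && k >= eventFrames[ev]) return(0)
            fd <- match(i, nEvents + seq_len(nFades))
            if (!is.na(fd) && nFades > 0) {
                s <- fadeStarts[fd]
                if (k >= s + fadeFrames) return(0)
                if (k >= s) return(amplitude * (1 - (k - s) / fadeFrames))
            }
            amplitude
        }

        ## noise model: Gaussian read noise + Poisson shot noise scaled so
        ## that total SD at an unbleached punctum peak is amplitude/snr
        readSd <- amplitude / (2 * snr)
        peakLevel <- max(bg) + amplitude
        photonScale <- peakLevel / (0.75 * (amplitude / snr)^2)

        frames <- array(0, dim = c(nr, nc, nf))
        for (k in seq_len(nf)) {
            img <- bg
            for (i in seq_len(nPuncta)) {
                a <- ampAt(i, k)
                if (a > 0) {
                    f <- foot[[i]]
                    img[f$rs, f$cs] <- img[f$rs, f$cs] + a * f$g
                }
            }
            img <- img * exp(-((k - 1L) * dt) / bleachTau)
            shot <- matrix(stats::rpois(nr * nc, img * photonScale),
                           nr, nc) / photonScale
            frames[, , k] <- shot + stats::rnorm(nr * nc, 0, readSd)
        }
        list(pts = pts, eventFrames = eventFrames, fadeStarts = fadeStarts,
             frames = frames)
    })

    stack <- new("ImageStack", frames = out$frames, pixelSize = px,
                 frameInterval = dt, cellMask = mask * 1)
    truth <- new("GroundTruth", kind = "stack",
                 parameters = list(
                     positions = out$pts,
                     eventPuncta = seq_len(nEvents),
                     eventFrames = out$eventFrames,
                     eventTimes = (out$eventFrames - 1L) * dt,
                     fadePuncta = nEvents + seq_len(nFades),
                     fadeStarts = out$fadeStarts,
                     nPuncta = nPuncta, snr = snr, bleachTau = bleachTau,
                     amplitude = amplitude,
                     punctumSigmaUm = punctumSigmaUm,
                     maskAreaUm2 = sum(mask) * px^2,
                     stimulusS = stimulusS),
                 seed = as.integer(seed))
    list(stack = stack, truth = truth)
}

#' Simulate a cohort of dye-leakage injury traces
#'
#' Per cell, a class (mIn/iIn/sIn) is drawn with the given probabilities; the
#' trace holds its baseline until the stimulus, then relaxes exponentially
#' (time constant `dropTau`) to a class-specific retained plateau, with
#' additive Gaussian noise. Class means closer than `2 * noiseSd` are not
#' separable and trigger a warning.
#'
#' @param fractions class probabilities `c(mIn, iIn, sIn)`, summing to 1
#'   (default c(0.45, 0.35, 0.20)).
#' @param retainedMeans class retained fractions, ordered mIn > iIn > sIn
#'   (default c(0.95, 0.5, 0.02)).
#' @param noiseSd additive noise SD in intensity units (default 0.03).
#' @param n cohort size (default 100).
#' @param baseline,floorLevel baseline intensity and background floor
#'   (defaults 1 and 0).
#' @param dropTau post-stimulus relaxation time constant, s (default 5).
#' @param rateHz,durationS,stimulusS acquisition parameters (defaults 2 Hz,
#'   60 s, 10 s).
#' @param seed RNG seed.
#' @return list with `traces` (list of [FluorescenceTrace-class]) and
#'   `truth` ([GroundTruth-class] carrying the class labels).
#' @export
simulateInjuryCohort <- function(fractions = c(0.45, 0.35, 0.20),
                                 retainedMeans = c(0.95, 0.5, 0.02),
                                 noiseSd = 0.03, n = 100, baseline = 1,
                                 floorLevel = 0, dropTau = 5, rateHz = 2,
                                 durationS = 60, stimulusS = 10, seed = 1) {
    if (abs(sum(fractions) - 1) > 1e-9)
        stop("'fractions' must sum to 1")
    if (is.unsorted(rev(retainedMeans), strictly = TRUE))
        stop("'retainedMeans' must be ordered mIn > iIn > sIn")
    if (min(abs(diff(retainedMeans))) < 2 * noiseSd)
        warning("class retained-fraction means are closer than 2 * noiseSd; ",
                "classes may not be separable")
    classes <- c("mIn", "iIn", "sIn")
    dt <- 1 / rateHz
    t <- seq(0, durationS, by = dt)
    out <- withSeed(seed, {
        lab <- sample(classes, n, replace = TRUE, prob = fractions)
        traces <- lapply(seq_len(n), function(i) {
            retained <- retainedMeans[match(lab[i], classes)]
            plateau <- floorLevel + retained * (baseline - floorLevel)
            sig <- ifelse(t < stimulusS, baseline,
                          plateau + (baseline - plateau) *
                              exp(-(t - stimulusS) / dropTau))
            FluorescenceTrace(paste0("cell", i), times = t,
                              values = sig + stats::rnorm(length(t), 0,
                                                          noiseSd),
                              samplingRate = rateHz,
                              stimulusTime = stimulusS)
        })
        list(lab = lab, traces = traces)
    })
    truth <- new("GroundTruth", kind = "injury",
                 parameters = list(labels = out$lab, fractions = fractions,
                                   retainedMeans = retainedMeans,
                                   noiseSd = noiseSd, baseline = baseline,
                                   floorLevel = floorLevel),
                 seed = as.integer(seed))
    list(traces = out$traces, truth = truth)
}

#' Simulate a saturating dose-response data set
#'
#' Responses follow `y = a x / (b + x)` times lognormal noise with CV
#' `noiseCv` (mean 1). Doses default to 1..10 media displacements, matching
#' the turbulent-shear protocol in which 50\% of the medium is displaced `n`
#' times.
#'
#' @param a asymptote (default 400, amol/cell scale).
#' @param b half-saturation dose (default 3).
#' @param doses dose vector (default 1:10).
#' @param noiseCv multiplicative noise CV (default 0.1; 0 = noise-free).
#' @param seed RNG seed.
#' @return list with `data` (data.frame `dose`, `response`) and `truth`
#'   ([GroundTruth-class]).
#' @export
simulateDoseResponse <- function(a = 400, b = 3, doses = 1:10,
                                 noiseCv = 0.1, seed = 1) {
    stopifnot(a > 0, b > 0, noiseCv >= 0)
    clean <- a * doses / (b + doses)
    sdlog <- sqrt(log(1 + noiseCv^2))
    y <- withSeed(seed, {
        if (noiseCv > 0)
            clean * stats::rlnorm(length(doses), -sdlog^2 / 2, sdlog)
        else clean
    })
    truth <- new("GroundTruth", kind = "dose",
                 parameters = list(a = a, b = b, doses = doses,
                                   noiseCv = noiseCv),
                 seed = as.integer(seed))
    list(data = data.frame(dose = doses, response = y), truth = truth)
}
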