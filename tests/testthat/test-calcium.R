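test_that("baseline is the median of the pre-stimulus window", {
    tr <- makeTrace(rep(1, 41))
    expect_identical(estimateBaseline(tr), 1)

    # 10 s window at 2 Hz spans exactly 20 samples (t = 0 .. 9.5 s)
    v <- c(rep(2, 20), rep(9, 21))
    tr2 <- makeTrace(v)
    idx <- which(tr2@times >= 0 & tr2@times < 10)
    expect_length(idx, 20L)
    expect_identical(estimateBaseline(tr2), 2)

    # noisy flat trace: matches an independently computed median
    set.seed(42)
    v3 <- 1 + rnorm(41, 0, 0.01)
    tr3 <- makeTrace(v3)
    expect_equal(estimateBaseline(tr3), median(v3[tr3@times < 10]))
    expect_lt(abs(estimateBaseline(tr3) - 1), 0.01)

    # window with too few samples errors
    tr4 <- FluorescenceTrace("x", values = rep(1, 30), samplingRate = 2,
                             stimulusTime = 1)
    expect_error(estimateBaseline(tr4), "baseline")
})

test_that("characterizeTransient recovers ideal-shape parameters exactly", {
    # ideal step to baseline+A followed by exponential decay with tau = 5
    t <- seq(-10, 60, by = 0.5)
    A <- 0.8
    v <- ifelse(t < 0, 1, 1 + A * exp(-t / 5))
    tr <- FluorescenceTrace("s", times = t, values = v, samplingRate = 2,
                            stimulusTime = 0)
    p <- characterizeTransient(tr, 1)
    expect_equal(amplitude(p), A, tolerance = 1e-9)
    expect_equal(tauDecay(p), 5, tolerance = 1e-6)

    # linear ramp over T s then plateau: tAct = 0.8 T by definition of 10-90%
    T <- 8
    t2 <- seq(-10, 40, by = 0.5)
    v2 <- ifelse(t2 < 0, 1, ifelse(t2 < T, 1 + 0.5 * t2 / T, 1.5))
    tr2 <- FluorescenceTrace("r", times = t2, values = v2, samplingRate = 2,
                             stimulusTime = 0)
    p2 <- characterizeTransient(tr2, 1)
    expect_equal(tAct(p2), 0.8 * T, tolerance = 1e-9)
    expect_equal(activationRate(p2), 0.5 / (0.8 * T), tolerance = 1e-9)
})

test_that("characterization is invariant to baseline shift and rescales with time", {
    sim <- simulateTransient(seed = 3, snr = Inf)
    tr <- sim$trace
    p <- characterizeTransient(tr, estimateBaseline(tr))

    # additive shift moves the baseline only
    shifted <- FluorescenceTrace(tr@roiId, times = tr@times,
                                 values = tr@values + 2.5,
                                 samplingRate = tr@samplingRate,
                                 stimulusTime = tr@stimulusTime)
    ps <- characterizeTransient(shifted, estimateBaseline(shifted))
    expect_equal(ps@baseline, p@baseline + 2.5, tolerance = 1e-9)
    expect_equal(amplitude(ps), amplitude(p), tolerance = 1e-9)
    expect_equal(tAct(ps), tAct(p), tolerance = 1e-9)
    expect_equal(tauDecay(ps), tauDecay(p), tolerance = 1e-6)

    # compressing the time axis by s divides tAct and tau by s
    s <- 2
    comp <- FluorescenceTrace(tr@roiId, times = tr@times / s,
                              values = tr@values,
                              samplingRate = tr@samplingRate * s,
                              stimulusTime = tr@stimulusTime / s)
    pc <- characterizeTransient(comp, estimateBaseline(comp, 10 / s))
    expect_equal(tAct(pc), tAct(p) / s, tolerance = 1e-6)
    expect_equal(tauDecay(pc), tauDecay(p) / s, tolerance = 1e-4)
    expect_equal(activationRate(pc), activationRate(p) * s,
                 tolerance = 1e-6)
})

test_that("noiseless synthetic transients round-trip to generator truth", {
    for (seed in 1:5) {
        sim <- simulateTransient(seed = seed, snr = Inf, tAct = 1 + seed / 2,
                                 tau = 10 + 2 * seed)
        tru <- sim$truth@parameters
        p <- characterizeTransient(sim$trace, estimateBaseline(sim$trace))
        expect_lt(abs(amplitude(p) - tru$amplitude) / tru$amplitude, 1e-6)
        expect_lt(abs(tAct(p) - tru$tAct), 0.5)          # one sample interval
        expect_lt(abs(tauDecay(p) - tru$tau) / tru$tau, 1e-3)
    }
})

test_that("flat traces are flagged as non-responses and the rate errors", {
    tr <- makeTrace(rep(1, 41))
    p <- characterizeTransient(tr, 1)
    expect_identical(amplitude(p), 0)
    expect_true("no_response" %in% p@flags)
    expect_true(is.na(tAct(p)))
    expect_error(activationRate(p), "undefined|no measurable")
})

test_that("secondary responder detection counts and labels correctly", {
    # constructed field: 4 of 10 neighbors carry a 10-SD response
    sd0 <- 0.02
    t <- seq(0, 60, by = 0.5)
    set.seed(7)
    mk <- function(id, responds) {
        sig <- if (responds)
            ifelse(t < 12, 1, 1 + 10 * sd0 * exp(-(t - 12) / 10)) else
            rep(1, length(t))
        FluorescenceTrace(id, times = t, values = sig + rnorm(length(t), 0, sd0),
                          samplingRate = 2, stimulusTime = 10)
    }
    traces <- c(list(mk("primary", TRUE)),
                lapply(1:10, function(i) mk(paste0("n", i), i <= 4)))
    pos <- cbind(x = c(0, cos(1:10)), y = c(0, sin(1:10))) * 30
    rownames(pos) <- c("primary", paste0("n", 1:10))
    field <- FieldRecording(traces, pos, "primary")
    s <- detectSecondaryResponders(field)
    expect_identical(s@nNeighbors, 10L)
    expect_identical(s@nResponders, 4L)
    expect_equal(percentResponders(s), 40)
    expect_true(all(perNeighbor(s)$responded[1:4]))
    expect_true(all(perNeighbor(s)$delay_s[perNeighbor(s)$responded] >= 0))

    # permutation invariance of the percentage
    field2 <- FieldRecording(traces[c(1, sample(2:11))], pos, "primary")
    expect_equal(percentResponders(detectSecondaryResponders(field2)), 40)
})

test_that("all-flat fields give 0% and zero-variance neighbors do not divide by zero", {
    t <- seq(0, 30, by = 0.5)
    mkFlat <- function(id) FluorescenceTrace(id, times = t,
        values = rep(1, length(t)), samplingRate = 2, stimulusTime = 10)
    traces <- lapply(c("primary", "n1", "n2"), mkFlat)
    pos <- cbind(x = c(0, 10, 20), y = 0)
    rownames(pos) <- c("primary", "n1", "n2")
    s <- detectSecondaryResponders(FieldRecording(traces, pos, "primary"))
    expect_equal(percentResponders(s), 0)

    # no neighbors at all errors
    solo <- FieldRecording(list(mkFlat("primary")),
                           {m <- cbind(x = 0, y = 0)
                            rownames(m) <- "primary"; m}, "primary")
    expect_error(detectSecondaryResponders(solo), "neighbor")
})

test_that("mean difference curves subtract pointwise with quadrature SEM", {
    t <- seq(0, 10, by = 0.5)
    mk <- function(v) FluorescenceTrace("g", times = t, values = v,
                                        samplingRate = 2, stimulusTime = 5)
    gA <- lapply(1:4, function(i) mk(rep(1 + 0.1 * (i - 2.5), length(t))))
    gB <- lapply(1:4, function(i) mk(rep(0.6 + 0.1 * (i - 2.5), length(t))))

    # identical groups cancel exactly
    d0 <- meanDifferenceCurve(gA, gA)
    expect_true(all(abs(d0$mean_diff) < 1e-12))

    # constant offset appears as a flat difference
    d1 <- meanDifferenceCurve(gA, gB)
    expect_equal(d1$mean_diff, rep(0.4, length(t)), tolerance = 1e-12)

    # quadrature: SEM_A = SEM_B = 0.1 gives sqrt(0.02) ~ 0.1414
    # construct groups of 4 with per-group SEM exactly 0.1 (sd = 0.2)
    offs <- c(-0.3, -0.1, 0.1, 0.3)
    offs <- offs / sd(offs) * 0.2
    gC <- lapply(offs, function(o) mk(rep(1 + o, length(t))))
    gD <- lapply(offs, function(o) mk(rep(2 + o, length(t))))
    d2 <- meanDifferenceCurve(gC, gD)
    expect_equal(d2$sem_diff[1], sqrt(0.1^2 + 0.1^2), tolerance = 1e-9)
    expect_equal(d2$sem_diff[1], 0.1414, tolerance = 1e-3)

    # mismatched grids must instruct resampling
    tOther <- seq(0, 10, by = 1)
    gE <- list(FluorescenceTrace("g", times = tOther,
                                 values = rep(1, length(tOther)),
                                 samplingRate = 1, stimulusTime = 5))
    expect_error(meanDifferenceCurve(gA, gE), "resampl")
})
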