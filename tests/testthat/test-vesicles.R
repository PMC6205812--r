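test_that("preprocessing flattens bleaching and preserves punctum positions", {
    sim <- simulateVesicleStack(nPuncta = 10, nEvents = 0, nFades = 0,
                                snr = 10, bleachTau = 200, durationS = 60,
                                seed = 5)
    # detrend only: whole-frame median varies < 2% across frames
    st <- preprocessStack(sim$stack, backgroundSubtract = FALSE,
                          normalize = FALSE)
    meds <- apply(st@frames, 3L, median)
    expect_lt((max(meds) - min(meds)) / meds[1L], 0.02)

    # full preprocessing: detected centroids shift < 1 pixel
    full <- preprocessStack(sim$stack)
    ref <- apply(full@frames[, , 1:5], c(1, 2), mean)
    pts <- detectPuncta(ref, full@pixelSize)
    tru <- sim$truth@parameters$positions
    shifts <- vapply(seq_len(nrow(pts@centroids)), function(i)
        min(sqrt((tru[, 1] - pts@centroids[i, 1])^2 +
                 (tru[, 2] - pts@centroids[i, 2])^2)), numeric(1))
    expect_lt(max(shifts), full@pixelSize)

    # constant stacks pass through as constants; all-zero stacks error
    const <- ImageStack(array(2, dim = c(16, 16, 4)), 0.4, 0.5)
    out <- preprocessStack(const)
    expect_lt(diff(range(out@frames)), 1e-12)
    zero <- ImageStack(array(0, dim = c(16, 16, 4)), 0.4, 0.5)
    expect_error(preprocessStack(zero), "zero")
})

test_that("LoG punctum detection counts well-separated puncta exactly", {
    # blank frame: nothing detected
    blank <- matrix(0.2, 64, 64)
    expect_identical(nrow(detectPuncta(blank, 0.4)@centroids), 0L)

    # 35 non-overlapping puncta at SNR 10: all found, none invented
    geom <- list(width = 96, height = 96, pixelSizeUm = 0.4,
                 maskRadiusUm = 15)
    sim <- simulateVesicleStack(nPuncta = 35, nEvents = 0, nFades = 0,
                                snr = 10, geometry = geom, durationS = 10,
                                seed = 11)
    st <- preprocessStack(sim$stack)
    ref <- apply(st@frames[, , 1:5], c(1, 2), mean)
    pts <- detectPuncta(ref, st@pixelSize)
    expect_identical(nrow(pts@centroids), 35L)

    # two puncta closer than the exclusion radius merge into one detection
    f <- matrix(0, 64, 64)
    g <- function(r0, c0) outer(1:64, 1:64, function(r, c)
        exp(-((r - r0)^2 + (c - c0)^2) / (2 * 1.25^2)))
    f <- f + g(32, 32) + g(32, 33)              # 0.4 um apart at 0.4 um/px
    expect_identical(nrow(detectPuncta(f, 0.4)@centroids), 1L)
})

test_that("vesicular density is count over area", {
    geom <- list(width = 96, height = 96, pixelSizeUm = 0.4,
                 maskRadiusUm = 15)
    sim <- simulateVesicleStack(nPuncta = 35, nEvents = 0, nFades = 0,
                                snr = 10, geometry = geom, durationS = 10,
                                seed = 11)
    st <- preprocessStack(sim$stack)
    ref <- apply(st@frames[, , 1:5], c(1, 2), mean)
    pts <- detectPuncta(ref, st@pixelSize)
    expect_equal(vesicularDensity(pts, 500), 0.07)
    empty <- detectPuncta(matrix(0, 32, 32), 0.4)
    expect_identical(vesicularDensity(empty, 500), 0)
    expect_error(vesicularDensity(pts, 0), "> 0")
})

test_that("release events are called on the benchmark with F1 >= 0.9", {
    sim <- simulateVesicleStack(nPuncta = 20, nEvents = 10, nFades = 5,
                                snr = 5, seed = 1234)
    kin <- detectReleaseEvents(sim$stack)
    tru <- sim$truth@parameters
    m <- matchEvents(eventTable(kin), tru)
    expect_gte(f1FromCounts(m), 0.9)
    expect_lte(fadesMiscalled(eventTable(kin), tru), 1L)

    # kinetics bookkeeping: density matches truth; cumulative is bounded by
    # the basal pool and the rate integrates back to it
    expect_equal(basalDensity(kin), tru$nPuncta / tru$maskAreaUm2,
                 tolerance = 1e-9)
    cum <- cumulativeRelease(kin)
    expect_true(all(diff(cum) >= 0))
    expect_lte(max(cum), basalDensity(kin))
    expect_equal(sum(kin@rateTimecourse * sim$stack@frameInterval),
                 nrow(eventTable(kin)) / kin@cellArea, tolerance = 1e-9)
})

test_that("event calling is scale-invariant and ignores appearances", {
    sim <- simulateVesicleStack(nPuncta = 12, nEvents = 6, nFades = 2,
                                snr = 5, seed = 2)
    kin1 <- detectReleaseEvents(sim$stack)
    scaled <- ImageStack(sim$stack@frames * 10, sim$stack@pixelSize,
                         sim$stack@frameInterval, sim$stack@cellMask)
    kin2 <- detectReleaseEvents(scaled)
    expect_equal(eventTable(kin1)$t_s, eventTable(kin2)$t_s)
    expect_equal(eventTable(kin1)$punctum_id, eventTable(kin2)$punctum_id)

    # an abrupt appearance (reversed-time disappearance) is never an event
    app <- simulateVesicleStack(nPuncta = 8, nEvents = 0, nFades = 0,
                                snr = 20, durationS = 60, seed = 3)
    fr <- app$stack@frames
    # inject a punctum that appears abruptly at frame 60 in the field center
    g <- outer(seq_len(dim(fr)[1]), seq_len(dim(fr)[2]), function(r, c)
        exp(-((r - 32)^2 + (c - 32)^2) / (2 * 1.25^2)))
    for (k in 60:dim(fr)[3]) fr[, , k] <- fr[, , k] + g
    appStack <- ImageStack(fr, app$stack@pixelSize,
                           app$stack@frameInterval, app$stack@cellMask)
    kinApp <- detectReleaseEvents(appStack)
    expect_identical(nrow(eventTable(kinApp)), 0L)
})

test_that("constant and pure-noise stacks produce no events", {
    const <- ImageStack(array(1, dim = c(32, 32, 20)), 0.4, 0.5,
                        cellMask = matrix(1, 32, 32))
    expect_identical(nrow(eventTable(detectReleaseEvents(const))), 0L)

    for (s in 1:2) {
        noise <- simulateVesicleStack(nPuncta = 0, nEvents = 0, nFades = 0,
                                      snr = 5, durationS = 60, seed = s)
        expect_identical(nrow(eventTable(detectReleaseEvents(noise$stack))),
                         0L)
    }
})

test_that("pool-fraction arithmetic matches the printed densities", {
    expect_equal(percentPoolReleased(5e-3, 70e-3), 100 * 5 / 70,
                 tolerance = 1e-12)
    expect_identical(percentPoolReleased(0, 70e-3), 0)
    expect_equal(percentPoolReleased(70e-3, 70e-3), 100)
    expect_warning(percentPoolReleased(80e-3, 70e-3), "exceeds")
    expect_error(percentPoolReleased(1e-3, 0), "> 0")
})
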