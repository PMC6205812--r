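test_that("plane-source concentration matches an independent PDE solution", {
    # closed form at the reference point
    expect_equal(planeSourceConcentration(1, 330, 0, 1), 15.5288,
                 tolerance = 1e-4)

    # independent oracle: explicit finite-difference solution of c_t = D c_xx
    # from a narrow Gaussian initial condition carrying total mass sigma
    D <- 330; sigma <- 1
    dx <- 0.5
    L <- 150
    x <- seq(-L, L, by = dx)
    s0 <- 1.5                                   # narrow initial width (um)
    c0 <- sigma / (sqrt(2 * pi) * s0) * exp(-x^2 / (2 * s0^2))  # amol/um^3
    dt <- 0.4 * dx^2 / (2 * D)                  # stability margin
    nsteps <- ceiling(1 / dt)
    dt <- 1 / nsteps
    cc <- c0
    lam <- D * dt / dx^2
    for (k in seq_len(nsteps)) {
        cc <- cc + lam * (c(cc[-1], 0) - 2 * cc + c(0, cc[-length(cc)]))
    }
    # compare to the analytic solution started from the same Gaussian:
    # variance grows by 2 D t, so evaluate the plane source at an effective
    # time t_eff with 2 D t_eff = s0^2 + 2 D t
    tEff <- (s0^2 + 2 * D * 1) / (2 * D)
    numeric0 <- cc[x == 0] * 1000               # amol/um^3 -> uM
    expect_equal(numeric0, planeSourceConcentration(sigma, D, 0, tEff),
                 tolerance = 1e-3)
    # and the narrow-source correction is small: within 0.5% of t = 1
    expect_equal(numeric0, planeSourceConcentration(sigma, D, 0, 1),
                 tolerance = 5e-3)
})

test_that("plane-source limits, zero source, and t = 0 behave as the model demands", {
    expect_equal(planeSourceConcentration(1, 330, 1e4, 1), 0)
    # late times: the profile flattens and decays toward zero as 1/sqrt(t)
    expect_lt(planeSourceConcentration(1, 330, 5, 1e9),
              planeSourceConcentration(1, 330, 5, 100))
    expect_equal(planeSourceConcentration(1, 330, 5, 1e9), 0,
                 tolerance = 1e-3)
    expect_identical(planeSourceConcentration(0, 330, c(0, 5, 10), 1),
                     c(0, 0, 0))
    expect_error(planeSourceConcentration(1, 330, 0, 0), "undefined")
    expect_error(planeSourceConcentration(1, 330, 0, -1), "undefined")
})

test_that("mass is conserved and the solution is diffusion-self-similar", {
    D <- 330
    for (tt in c(0.1, 1, 10)) {
        L <- 10 * sqrt(4 * D * tt)
        x <- seq(-L, L, length.out = 4001)
        c_amol <- planeSourceConcentration(1, D, x, tt) / 1000
        integ <- pracma::trapz(x, c_amol)
        expect_lt(abs(integ - 1), 1e-3)
    }
    # rescaling D -> k D, t -> t/k leaves the profile unchanged
    k <- 7.3
    x <- seq(0, 20, by = 2.5)
    expect_equal(planeSourceConcentration(0.05, D, x, 2),
                 planeSourceConcentration(0.05, k * D, x, 2 / k),
                 tolerance = 1e-12)
})

test_that("source fitting is exact on clean profiles and matches a grid-search oracle", {
    sp <- simulateSourceProfiles(sigma = 0.05, noiseCv = 0, seed = 1)
    est <- fitSourceAmount(sp$profiles[[1]], effectiveArea = 400)
    expect_lt(abs(sourceStrength(est) - 0.05) / 0.05, 1e-9)
    expect_equal(totalAmount(est), sourceStrength(est) * 400)
    expect_equal(est@r2, 1, tolerance = 1e-9)

    # noisy profile: the closed form equals a dense grid search to 4 sig digits
    spn <- simulateSourceProfiles(sigma = 0.05, noiseCv = 0.05, seed = 2)
    p <- spn$profiles[[1]]
    estn <- fitSourceAmount(p)
    grid <- seq(0.02, 0.10, length.out = 80001)
    sse <- vapply(grid, function(s)
        sum((p@concentrations -
             planeSourceConcentration(s, 330, p@distances, p@times))^2),
        numeric(1))
    oracle <- grid[which.min(sse)]
    expect_equal(signif(sourceStrength(estn), 4), signif(oracle, 4))

    # closed-form and iterative (t0) solutions agree on clean data
    estT0 <- fitSourceAmount(sp$profiles[[1]], fitT0 = TRUE)
    expect_lt(abs(sourceStrength(estT0) - sourceStrength(est)) /
              sourceStrength(est), 1e-6)
    expect_lt(abs(estT0@t0Offset), 1e-6)
})

test_that("source recovery is accurate over an ensemble of noisy profiles", {
    sims <- simulateSourceProfiles(sigma = 0.05, noiseCv = 0.05, n = 200,
                                   seed = 42)
    errs <- vapply(sims$profiles, function(p)
        abs(sourceStrength(fitSourceAmount(p)) - 0.05) / 0.05, numeric(1))
    expect_lt(median(errs), 0.10)
    # unbiased in expectation: ensemble mean within 2% of truth
    sigmas <- vapply(sims$profiles,
                     function(p) sourceStrength(fitSourceAmount(p)),
                     numeric(1))
    expect_lt(abs(mean(sigmas) - 0.05) / 0.05, 0.02)
})

test_that("source fitting validates its inputs", {
    p <- ConcentrationProfile(c(0, 5), c(1, 1), c(1, 0.5))
    expect_error(fitSourceAmount(p), "at least 3")
    expect_error(ConcentrationProfile(c(0, 5, 10), c(0, 1, 1), c(1, 1, 1)),
                 "> 0")
})

test_that("time to peak is recovered at sample resolution and truncation is flagged", {
    # a peak placed 1.5 s after the stimulus
    t <- seq(0, 30, by = 0.5)
    v <- exp(-abs(t - 11.5))
    tr <- FluorescenceTrace("p", times = t, values = v, samplingRate = 2,
                            stimulusTime = 10)
    ttp <- timeToPeak(tr)
    expect_equal(as.numeric(ttp), 1.5)
    expect_false(attr(ttp, "truncated"))

    # monotone rising trace: peak on the final sample, flagged truncated
    tr2 <- FluorescenceTrace("m", times = t, values = t, samplingRate = 2,
                             stimulusTime = 10)
    expect_true(attr(timeToPeak(tr2), "truncated"))

    # generator peaks drawn in (1, 2) s recovered at sample resolution
    set.seed(5)
    for (i in 1:5) {
        pk <- runif(1, 1, 2)
        v3 <- exp(-((t - 10 - pk) / 2)^2)
        tr3 <- FluorescenceTrace("g", times = t, values = v3,
                                 samplingRate = 2, stimulusTime = 10)
        expect_lt(abs(as.numeric(timeToPeak(tr3)) - pk), 0.25 + 1e-9)
    }
})
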