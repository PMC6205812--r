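mkInjuryTrace <- function(retained, noise = 0, seed = 1, baseline = 1,
                          floorLevel = 0) {
    t <- seq(0, 60, by = 0.5)
    plateau <- floorLevel + retained * (baseline - floorLevel)
    sig <- ifelse(t < 10, baseline,
                  plateau + (baseline - plateau) * exp(-(t - 10) / 5))
    set.seed(seed)
    FluorescenceTrace("c", times = t, values = sig + rnorm(length(t), 0, noise),
                      samplingRate = 2, stimulusTime = 10)
}

test_that("injury classes follow the retained-fraction taxonomy", {
    expect_identical(injuryClass(classifyInjuryTrace(mkInjuryTrace(1))),
                     "mIn")
    expect_identical(injuryClass(classifyInjuryTrace(mkInjuryTrace(0))),
                     "sIn")
    expect_identical(injuryClass(classifyInjuryTrace(mkInjuryTrace(0.5))),
                     "iIn")
    call <- classifyInjuryTrace(mkInjuryTrace(0.5))
    expect_equal(retainedFraction(call), 0.5, tolerance = 0.02)

    # plateau window beyond the recording errors
    short <- FluorescenceTrace("s", values = rep(1, 30), samplingRate = 2,
                               stimulusTime = 13)
    expect_error(classifyInjuryTrace(short, plateauWindowS = 10),
                 "plateau")
})

test_that("classification is monotone in the post-stimulus plateau", {
    sev <- c(sIn = 1, iIn = 2, mIn = 3)
    lastSev <- Inf
    for (retained in c(0.98, 0.7, 0.4, 0.15, 0.02)) {
        k <- injuryClass(classifyInjuryTrace(mkInjuryTrace(retained)))
        expect_lte(sev[[k]], lastSev)
        lastSev <- sev[[k]]
    }
})

test_that("cohort classification agrees with generator labels and degrades with noise", {
    co <- simulateInjuryCohort(n = 200, noiseSd = 0.03, seed = 8)
    calls <- vapply(co$traces,
                    function(tr) injuryClass(classifyInjuryTrace(tr)),
                    character(1))
    expect_gte(mean(calls == co$truth@parameters$labels), 0.95)

    accAt <- function(sd) {
        co <- suppressWarnings(
            simulateInjuryCohort(n = 300, noiseSd = sd, seed = 9))
        calls <- vapply(co$traces,
                        function(tr) injuryClass(classifyInjuryTrace(tr)),
                        character(1))
        mean(calls == co$truth@parameters$labels)
    }
    accs <- vapply(c(0.05, 0.2, 0.4), accAt, numeric(1))
    expect_true(all(diff(accs) <= 0))
    expect_lt(accs[3L], accs[1L])
})

test_that("injury frequencies are percentages that sum to 100", {
    f <- injuryFrequencies(c("mIn", "mIn", "iIn", "sIn"))
    expect_equal(unname(f), c(50, 25, 25))
    expect_equal(sum(f), 100, tolerance = 1e-9)
    expect_equal(unname(injuryFrequencies("iIn")), c(0, 100, 0))
    expect_error(injuryFrequencies(character()), "no injury")
    expect_error(injuryFrequencies(c("mIn", "bogus")), "unknown")

    # frequencies from InjuryCall objects work the same way
    calls <- lapply(c(1, 0.5, 0), function(r)
        classifyInjuryTrace(mkInjuryTrace(r)))
    expect_equal(sum(injuryFrequencies(calls)), 100)
})

test_that("Fura-2 leakage equals the sIn frequency", {
    kl <- c("sIn", "sIn", rep("mIn", 5), rep("iIn", 3))
    expect_equal(fura2LeakagePercent(kl), 20)
    expect_equal(fura2LeakagePercent(kl),
                 unname(injuryFrequencies(kl)["sIn"]))
    expect_equal(fura2LeakagePercent(rep("mIn", 4)), 0)
})

test_that("dye uptake and LDH leakage ratios behave", {
    expect_equal(dyeUptakeFraction(18, 100), 18)
    expect_equal(dyeUptakeFraction(0, 50), 0)
    expect_error(dyeUptakeFraction(5, 4), "total")
    expect_error(dyeUptakeFraction(5, 0), "> 0")

    expect_equal(as.numeric(ldhLeakagePercent(0.2, 2.0)), 10)
    expect_equal(as.numeric(ldhLeakagePercent(2.0, 2.0)), 100)
    clamped <- ldhLeakagePercent(0.05, 2.0, blank = 0.1)
    expect_equal(as.numeric(clamped), 0)
    expect_true(attr(clamped, "clamped"))
    expect_error(ldhLeakagePercent(1, 0.05, blank = 0.1), "blank")
})

test_that("molecular radii follow the cube-root mass law", {
    # hand-evaluated oracle values: 0.066 * MW^(1/3)
    expect_equal(molecularRadius(507), 0.5263, tolerance = 1e-4)
    expect_equal(molecularRadius(140000), 3.427, tolerance = 1e-3)
    expect_equal(molecularRadius(8 * 900), 2 * molecularRadius(900),
                 tolerance = 1e-12)
    mws <- c(507, 832, 900, 1e4, 1.4e5)
    expect_true(all(diff(molecularRadius(mws)) > 0))
    expect_error(molecularRadius(0), "> 0")
})

test_that("the lesion bracket spans permeant and excluded tracer radii", {
    br <- lesionRadiusBracket(defaultDyeTable())
    expect_equal(br@lowerNm, 0.066 * 900^(1 / 3), tolerance = 1e-12)
    expect_equal(br@upperNm, 0.066 * 10000^(1 / 3), tolerance = 1e-12)
    expect_equal(br@lowerNm, 0.637, tolerance = 1e-3)
    expect_equal(br@upperNm, 1.422, tolerance = 1e-3)
    # ATP passes: its radius sits below the lower bound
    expect_lt(molecularRadius(507), br@lowerNm)

    # every tracer permeant: the upper bound is unbounded
    all_in <- defaultDyeTable()
    all_in$permeant <- TRUE
    expect_identical(lesionRadiusBracket(all_in)@upperNm, Inf)

    # lower bound grows monotonically as larger permeant dyes are added
    d1 <- data.frame(name = "a", mw_da = 500, radius_nm = NA, permeant = TRUE)
    d2 <- rbind(d1, data.frame(name = "b", mw_da = 2000, radius_nm = NA,
                               permeant = TRUE))
    expect_gt(lesionRadiusBracket(d2)@lowerNm,
              lesionRadiusBracket(d1)@lowerNm)

    # inconsistent pattern errors and names the offending pair
    bad <- data.frame(name = c("big", "small"), mw_da = c(1e5, 500),
                      radius_nm = NA, permeant = c(TRUE, FALSE))
    expect_error(lesionRadiusBracket(bad), "big.*small|inconsistent")
})
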