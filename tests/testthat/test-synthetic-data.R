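test_that("generated curves have Baranyi shape: saturation, slope, grid", {
    ## default schedule: 15-min steps for 24 h = 97 samples
    expect_length(simulateGrowthCurve(visibleKin())@od, 97)
    ## saturation limit: log fold-change converges to the amplitude
    kin <- KineticParams(mu = 0.8, lag = 2, y0 = log(1e3),
                         amplitude = log(150))
    cur <- simulateGrowthCurve(kin, schedule = seq(0, 36, by = 0.25),
                               noise = NoiseSpec(odSigma = 0, blankOd = 0),
                               odPerDensity = 1e-5)
    n <- length(cur@od)
    expect_lt(abs(log(cur@od[n] / cur@od[1]) - log(150)), 1e-6)
    ## exponential-region derivative ~ mu on a curve with a long
    ## exponential phase (realistic ~12.4 ln fold change)
    kin2 <- KineticParams(mu = 0.8, lag = 2, y0 = log(1e3),
                          amplitude = 12.4)
    sch <- seq(0, 24, by = 0.25)
    cur2 <- simulateGrowthCurve(kin2, schedule = sch,
                                noise = NoiseSpec(odSigma = 0, blankOd = 0),
                                odPerDensity = 1e-5)
    y <- log(cur2@od)
    d <- (y[-(1:2)] - y[seq_len(length(y) - 2)]) / 0.5
    expect_rel(max(d), 0.8, 0.01)
})

test_that("curve generation is deterministic given the seed and validates input", {
    kin <- visibleKin()
    a <- simulateGrowthCurve(kin, noise = NoiseSpec(seed = 42L))
    b <- simulateGrowthCurve(kin, noise = NoiseSpec(seed = 42L))
    expect_identical(a@od, b@od)
    c <- simulateGrowthCurve(kin, noise = NoiseSpec(seed = 43L))
    expect_false(identical(a@od, c@od))
    expect_error(simulateGrowthCurve(kin, schedule = c(0, 1, 1, 2)),
                 "strictly increasing")
    expect_error(simulateGrowthCurve(kin, schedule = c(1, 2, 3)),
                 "start at 0")
    expect_error(simulateGrowthCurve(kin, odPerDensity = -1), "positive")
})

test_that("dilution series shifts y0 by -ln(factor) at fixed capacity", {
    kin <- costKin()
    plate <- simulateDilutionSeries(kin, baseT0 = 2e7,
                                    dilutionFactors = c(1e2, 1e4, 1e6),
                                    noise = noiseless(), nReplicates = 1)
    md <- wellMetadata(plate)
    expect_equal(nrow(md), 3)
    expect_equal(md$true_T0_cfu / 2e7, c(1e-2, 1e-4, 1e-6))
    ## identity dilution leaves y0 unshifted
    p1 <- simulateDilutionSeries(kin, baseT0 = 2e7, dilutionFactors = 1,
                                 noise = noiseless(), nReplicates = 1)
    ref <- simulateGrowthCurve(kin, noise = noiseless())
    expect_equal(getCurve(p1, wellMetadata(p1)$well[1])@od, ref@od)
    expect_error(simulateDilutionSeries(kin, dilutionFactors = 0.5),
                 ">= 1")
})

test_that("noiseless dilution-series crossing times are linear in ln T0", {
    kin <- costKin()
    plate <- simulateDilutionSeries(kin, baseT0 = 2e7,
                                    dilutionFactors = 10^(0:6),
                                    noise = noiseless(), nReplicates = 1)
    md <- wellMetadata(plate)
    thr <- selectThreshold(plate, blank = 0.04)
    ts <- vapply(md$well, function(w)
        timeToThreshold(preprocessCurve(getCurve(plate, w), 0.04), thr),
        numeric(1))
    ## equally spaced in ln T0 with spacing ln(10)/mu (the undiluted well
    ## crosses while still exiting lag, so its gap is excluded)
    gaps <- diff(ts)[-1]
    expect_true(all(abs(gaps - log(10) / 0.8) / (log(10) / 0.8) < 0.01))
})

test_that("de novo effects act on rate and lag exactly as specified", {
    kin <- costKin()
    thr <- 0.1
    base <- simulateDeNovoWells(kin, 1, 0, trueT0 = 2000, nWells = 1,
                                noise = noiseless())
    t0 <- timeToThreshold(
        preprocessCurve(getCurve(base, "A1"), 0.04), thr)
    ## pure extra lag shifts the crossing by exactly that lag
    lagged <- simulateDeNovoWells(kin, 1, 1.5, trueT0 = 2000, nWells = 1,
                                  noise = noiseless())
    t1 <- timeToThreshold(
        preprocessCurve(getCurve(lagged, "A1"), 0.04), thr)
    expect_lt(abs((t1 - t0) - 1.5), 1e-4)
    ## null effect reproduces adapted kinetics exactly
    expect_equal(getCurve(base, "A1")@od,
                 simulateGrowthCurve(
                     KineticParams(0.8, 2, log(2000),
                                   kin@y0 + kin@amplitude - log(2000)),
                     noise = noiseless())@od)
    expect_error(simulateDeNovoWells(kin, muScale = 0), "muScale")
    expect_error(simulateDeNovoWells(kin, extraLag = -1), "extraLag")
})

test_that("halved growth rate in de novo wells is recovered by refitting", {
    kin <- visibleKin()
    dn <- simulateDeNovoWells(kin, muScale = 0.5, extraLag = 0,
                              trueT0 = 2e7, nWells = 1,
                              schedule = seq(0, 36, 0.25),
                              noise = noiseless())
    fit <- fitGrowthCurve(
        preprocessCurve(getCurve(dn, "A1"), 0.04), "baranyi")
    expect_rel(growthRate(fit), 0.4, 0.01)
})

test_that("CFU sampler matches Poisson moments and edge cases", {
    expect_identical(sampleCfu(0, seed = 1L), 0L)
    n <- 1e4
    draws <- sampleCfu(1e5, volume = 0.01, dilutionFactor = 1,
                       seed = 7L, n = n)
    se <- sqrt(1000 / n)
    expect_lt(abs(mean(draws) - 1000), 3 * se)
    expect_lt(abs(var(draws) - 1000) / 1000, 0.05)
    expect_identical(sampleCfu(1e5, seed = 3L),
                     sampleCfu(1e5, seed = 3L))
    expect_error(sampleCfu(-1), "density")
    ## default plating volume is a 10 ul spot
    expect_equal(formals(sampleCfu)$volume, 0.01)
})

test_that("competition series wraps serial transfer and adds CFU noise", {
    p <- ModelParams(mu = 0.8, alpha = 1, rho = 1, beta = 0.01,
                     eta = 0, kappa = 0)
    cs <- simulateCompetitionSeries(p, days = 14, dilutionPerDay = 1e4)
    expect_equal(nrow(cs), 14)
    expect_equal(cs$fraction_observed, cs$fraction_true)
    expect_true(all(abs(cs$fraction_true - 0.5) < 1e-6))
    ## noiseless output equals the model output exactly
    st <- serialTransfer(p, days = 14, dilutionPerDay = 1e4)
    expect_equal(cs$fraction_true, plasmidFraction(st))
    ## CFU sampling perturbs but tracks the truth
    noisy <- simulateCompetitionSeries(p, days = 5,
                                       cfuNoise = NoiseSpec(seed = 5L))
    expect_false(identical(noisy$fraction_observed, noisy$fraction_true))
    expect_true(all(abs(noisy$fraction_observed - 0.5) < 0.05))
})

test_that("plates are bit-identical under one seed and wells independent of layout", {
    kin <- costKin()
    ns <- NoiseSpec(seed = 11L)
    a <- simulateDilutionSeries(kin, dilutionFactors = c(1e2, 1e4),
                                noise = ns, nReplicates = 2)
    b <- simulateDilutionSeries(kin, dilutionFactors = c(1e2, 1e4),
                                noise = ns, nReplicates = 2)
    expect_identical(odMatrix(a), odMatrix(b))
})
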