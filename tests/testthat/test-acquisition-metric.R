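test_that("the threshold is half the experiment-wide maximum density", {
    plate <- simulateDilutionSeries(costKin(), baseT0 = 2e7,
                                    dilutionFactors = c(1e2, 1e4),
                                    noise = noiseless(), nReplicates = 1,
                                    nBlanks = 1)
    thr <- selectThreshold(plate, blank = 0.04)
    maxOd <- max(odMatrix(plate)[, 1:2] - 0.04)
    expect_equal(thr, 0.5 * maxOd)
    ## per-experiment, not per-well: adding a taller condition moves it
    tall <- simulateDilutionSeries(adaptedKinetics(t0 = 2e7,
                                                   saturationOd = 0.8),
                                   baseT0 = 2e7, dilutionFactors = 1e2,
                                   noise = noiseless(), nReplicates = 1)
    thr2 <- selectThreshold(combinePlates(plate, tall), blank = 0.04)
    expect_gt(thr2, thr)
    ## all-blank plate has no signal
    blanks <- simulateDilutionSeries(costKin(), baseT0 = 2e7,
                                     dilutionFactors = 1e2,
                                     noise = noiseless(), nReplicates = 1,
                                     nBlanks = 2)
    onlyBlank <- blanks[, wellMetadata(blanks)$role == "blank"]
    expect_error(selectThreshold(new("PlateExperiment", onlyBlank), 0),
                 "non-blank")
})

test_that("threshold crossing interpolates exactly and guards against spikes", {
    tt <- seq(0, 24, by = 0.25)
    t0 <- 1e-5
    cur <- GrowthCurve(time = tt, od = t0 * exp(0.8 * tt),
                       backgroundSubtracted = TRUE)
    thr <- 0.1
    expect_equal(timeToThreshold(cur, thr), log(thr / t0) / 0.8,
                 tolerance = 1e-3)
    ## never reaching the threshold is an error
    expect_error(timeToThreshold(cur, 1e9), "no crossing")
    ## starting above the threshold is an error
    high <- GrowthCurve(time = tt, od = 0.5 + 0.01 * tt,
                        backgroundSubtracted = TRUE)
    expect_error(timeToThreshold(high, 0.1), "pre-saturated")
    ## a single-sample spike does not count as a crossing
    od <- t0 * exp(0.8 * tt)
    spikeAt <- 20
    od[spikeAt] <- thr * 1.5
    spiky <- GrowthCurve(time = tt, od = od, backgroundSubtracted = TRUE)
    expect_equal(timeToThreshold(spiky, thr), log(thr / t0) / 0.8,
                 tolerance = 1e-3)
    expect_error(timeToThreshold(GrowthCurve(time = tt, od = od), thr),
                 "background-subtracted")
})

test_that("the standard curve has slope -1/mu and near-perfect linearity", {
    plate <- simulateDilutionSeries(costKin(), baseT0 = 2e7,
                                    dilutionFactors = 10^(1:6),
                                    noise = noiseless(), nReplicates = 1)
    thr <- selectThreshold(plate, blank = 0.04)
    md <- wellMetadata(plate)
    ts <- vapply(md$well, function(w)
        timeToThreshold(preprocessCurve(getCurve(plate, w), 0.04), thr),
        numeric(1))
    std <- buildStandardCurve(ts, md$true_T0_cfu, thr)
    expect_rel(std@slope, -1 / 0.8, 0.005)
    expect_gt(std@r2, 0.999)
    ## degenerate designs are rejected
    expect_error(buildStandardCurve(c(1, 2), c(1000, 1000), thr),
                 "degenerate")
    expect_error(buildStandardCurve(1, 1000, thr), "at least 2")
})

test_that("density prediction inverts the standard curve", {
    std <- new("StandardCurve", slope = -1.25, intercept = 25,
               thresholdOd = 0.25, r2 = 1, nPoints = 6L,
               t0Range = c(20, 2e6))
    ## exact inversion identity
    expect_equal(predictInitialDensity(std, 25 - 1.25 * log(1000)), 1000)
    ## extrapolation warns but returns
    expect_warning(out <- predictInitialDensity(std, 25), "extrapolation")
    expect_equal(out, 1)
})

test_that("held-out adapted wells predict their own inoculum", {
    plate <- simulateDilutionSeries(costKin(), baseT0 = 2e7,
                                    dilutionFactors = c(1e2, 1e4, 1e6),
                                    noise = noiseless(), nReplicates = 1)
    thr <- selectThreshold(plate, blank = 0.04)
    md <- wellMetadata(plate)
    ts <- vapply(md$well, function(w)
        timeToThreshold(preprocessCurve(getCurve(plate, w), 0.04), thr),
        numeric(1))
    std <- buildStandardCurve(ts, md$true_T0_cfu, thr)
    held <- simulateDilutionSeries(costKin(), baseT0 = 2e7,
                                   dilutionFactors = 1e3,
                                   noise = noiseless(), nReplicates = 1)
    tsH <- timeToThreshold(
        preprocessCurve(getCurve(held, wellMetadata(held)$well[1]), 0.04),
        thr)
    expect_rel(predictInitialDensity(std, tsH), 2e4, 0.02)
})

test_that("acquisition cost detects lag and rate effects, not the null", {
    kin <- costKin()
    ## null: de novo identical to adapted
    nullPlate <- simulateCostPlate(kin, 1, 0, noise = noiseless(), t0Cv = 0)
    r0 <- acquisitionCostFromPlate(nullPlate, blank = 0.04)
    expect_rel(costRatio(r0$cost), 1, 0.02)
    expect_false(r0$cost@significant)
    ## pure extra lag: ratio = exp(-mu * dLag)
    lagPlate <- simulateCostPlate(kin, 1, 1,
                                  noise = NoiseSpec(odSigma = 0.003,
                                                    seed = 5L))
    r1 <- acquisitionCostFromPlate(lagPlate, blank = 0.04)
    expect_rel(costRatio(r1$cost), exp(-0.8), 0.1)
    expect_true(r1$cost@significant)
    ## slower growth also yields a significant cost (36 h to saturation)
    slowPlate <- simulateCostPlate(kin, 0.6, 0, hours = 36,
                                   noise = NoiseSpec(odSigma = 0.003,
                                                     seed = 6L))
    r2 <- acquisitionCostFromPlate(slowPlate, blank = 0.04)
    expect_lt(costRatio(r2$cost), 0.5)
    expect_true(r2$cost@significant)
})

test_that("cost ratio responds monotonically to both effect axes", {
    kin <- costKin()
    ratios <- vapply(c(0, 0.5, 1, 2), function(dl) {
        pl <- simulateCostPlate(kin, 1, dl, noise = noiseless(), t0Cv = 0,
                                hours = 30)
        costRatio(acquisitionCostFromPlate(pl, blank = 0.04)$cost)
    }, numeric(1))
    expect_true(all(diff(ratios) < 0))
    ratios2 <- vapply(c(1, 0.9, 0.8, 0.7), function(ms) {
        pl <- simulateCostPlate(kin, ms, 0, noise = noiseless(), t0Cv = 0,
                                hours = 36)
        costRatio(acquisitionCostFromPlate(pl, blank = 0.04)$cost)
    }, numeric(1))
    expect_true(all(diff(ratios2) < 0))
})

test_that("wells that never cross are excluded with a warning", {
    std <- new("StandardCurve", slope = -1.25, intercept = 25,
               thresholdOd = 0.25, r2 = 1, nPoints = 6L,
               t0Range = c(20, 2e6))
    expect_warning(res <- acquisitionCost(std, c(15, NA, 16), 2000),
                   "excluded")
    expect_length(res@tPred, 2)
    expect_error(suppressWarnings(acquisitionCost(std, c(NA, NA), 2000)),
                 "all wells failed")
})

test_that("lag normalization multiplies by T0 and divides by the adapted mean", {
    expect_equal(normalizedLag(2, 1, adaptedLags = c(2, 2)), 1)
    ## doubling T0 doubles the value
    expect_equal(normalizedLag(2, 2, adaptedLags = c(2, 2)), 2)
    ## adapted wells normalized against themselves average to mean(T0)
    lags <- c(1.8, 2.0, 2.2)
    t0s <- c(900, 1000, 1100)
    vals <- normalizedLag(lags, t0s, lags)
    expect_equal(mean(vals), sum(lags * t0s) / (3 * mean(lags)))
    expect_error(normalizedLag(1, 1, numeric(0)), "empty")
})

test_that("group comparison runs ANOVA with Bonferroni-corrected pairs", {
    ## identical groups: no signal, adjusted p = 1
    x <- c(1, 2, 3, 1, 2, 3)
    g <- rep(c("a", "b"), each = 3)
    res <- compareGroups(x, g)
    expect_equal(res$omnibusP, 1)
    expect_equal(unname(res$pairwise["b", "a"]), 1)
    ## clearly separated groups are detected in nearly every seed
    hits <- vapply(1:100, function(s) {
        set.seed(s)
        v <- c(rnorm(10, 0), rnorm(10, 5))
        compareGroups(v, rep(c("a", "b"), each = 10))$omnibusP < 0.05
    }, logical(1))
    expect_gte(sum(hits), 99)
    ## Bonferroni factor equals the number of pairwise comparisons
    set.seed(1)
    v <- rnorm(30)
    g3 <- rep(c("a", "b", "c"), each = 10)
    adj <- compareGroups(v, g3)$pairwise
    raw <- pairwise.t.test(v, g3, p.adjust.method = "none",
                           pool.sd = FALSE)$p.value
    expect_equal(adj, pmin(raw * 3, 1))
    expect_error(compareGroups(1:4, c("a", "a", "a", "b")), "at least 2")
})

test_that("standard curves at different entry dilutions are parallel", {
    ## emulates building the curve after 150x vs 5000x dilution into wells:
    ## slopes depend only on mu, so the lines are parallel
    slopes <- vapply(c(150, 5000), function(entry) {
        plate <- simulateDilutionSeries(
            adaptedKinetics(t0 = 3e9 / entry), baseT0 = 3e9 / entry,
            dilutionFactors = c(1e1, 1e2, 1e3),
            noise = noiseless(), nReplicates = 1)
        thr <- selectThreshold(plate, blank = 0.04)
        md <- wellMetadata(plate)
        ts <- vapply(md$well, function(w)
            timeToThreshold(preprocessCurve(getCurve(plate, w), 0.04),
                            thr), numeric(1))
        buildStandardCurve(ts, md$true_T0_cfu, thr)@slope
    }, numeric(1))
    expect_rel(slopes[1], slopes[2], 0.02)
})
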