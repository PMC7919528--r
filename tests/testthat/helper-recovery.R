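## Growth-fit recovery experiment shared by the benchmark tests: random
## (mu, lag) draws on the plate-visible design (inoculum OD 0.02,
## stationary OD 2), sigma_od noise, 15-min/24-h sampling.
recoveryErrors <- function(nCurves = 100, odSigma = 0.005,
                           seedOffset = 0L) {
    res <- vapply(seq_len(nCurves), function(s) {
        set.seed(s + seedOffset)
        mu <- runif(1, 0.4, 1.2)
        lag <- runif(1, 0.5, 3)
        kin <- adaptedKinetics(t0 = 2e7, mu = mu, lag = lag,
                               saturationOd = 2)
        cur <- simulateGrowthCurve(kin, noise = NoiseSpec(
            odSigma = odSigma, seed = s + seedOffset))
        pp <- preprocessCurve(cur, blank = 0.04)
        out <- numeric(0)
        for (m in c("baranyi", "gompertz", "logistic")) {
            f <- fitGrowthCurve(pp, m)
            out <- c(out, (f@mu - mu) / mu, (f@lag - lag) / lag)
        }
        pr <- tryCatch(maxSlopeRate(pp),
                       error = function(e) list(mu = NA, tMax = NA))
        lg <- tryCatch(
            suppressWarnings(geometricLag(pp, pr$mu, pr$tMax)),
            error = function(e) NA_real_)
        c(out, (pr$mu - mu) / mu, (lg - lag) / lag)
    }, numeric(8))
    rownames(res) <- c("baranyi.mu", "baranyi.lag", "gompertz.mu",
                       "gompertz.lag", "logistic.mu", "logistic.lag",
                       "maxslope.mu", "geometric.lag")
    res
}

## standard-curve + de novo cost experiment at the plate study conditions
costExperiment <- function(muScale = 1, extraLag = 0, seed = 1L,
                           odSigma = 0.003, t0Cv = 0.1, hours = 24,
                           factors = 10^(0:6)) {
    kin <- adaptedKinetics(t0 = 2e7, mu = 0.8, lag = 2, saturationOd = 0.5)
    plate <- simulateCostPlate(kin, muScale = muScale, extraLag = extraLag,
                               dilutionFactors = factors, t0Cv = t0Cv,
                               hours = hours,
                               noise = NoiseSpec(odSigma = odSigma,
                                                 seed = seed))
    suppressWarnings(acquisitionCostFromPlate(plate, blank = 0.04))
}
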