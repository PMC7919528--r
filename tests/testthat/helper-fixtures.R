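## Shared fixtures: all synthetic, built in code.

## adapted kinetics at plate-visible scale: inoculum OD 0.02, stationary
## OD 2 (used by parameter-recovery checks, where the full curve must be
## above the detection limit)
visibleKin <- function(mu = 0.8, lag = 2) {
    adaptedKinetics(t0 = 2e7, mu = mu, lag = lag, saturationOd = 2)
}

## adapted kinetics at the plate conditions the cost metric is designed
## for: ~2e7 cells undiluted, stationary OD 0.5
costKin <- function(mu = 0.8, lag = 2) {
    adaptedKinetics(t0 = 2e7, mu = mu, lag = lag, saturationOd = 0.5)
}

noiseless <- function(seed = 1L) NoiseSpec(odSigma = 0, seed = seed)

## preprocessed noiseless curve for fitting tests
cleanCurve <- function(kin = visibleKin(), hours = 24) {
    cur <- simulateGrowthCurve(kin, schedule = seq(0, hours, by = 0.25),
                               noise = noiseless())
    preprocessCurve(cur, blank = 0.04)
}

## a log-space curve with a long exponential phase (fold change typical of
## a full bacterial outgrowth), bypassing the OD detection limit
logSpaceCurve <- function(mu = 0.8, lag = 2, amplitude = 12.4,
                          hours = 24) {
    tt <- seq(0, hours, by = 0.25)
    GrowthCurve(time = tt, logFold = baranyiY(tt, mu, lag, 0, amplitude),
                backgroundSubtracted = TRUE)
}

expect_rel <- function(actual, expected, tol) {
    expect_lt(abs(actual - expected) / abs(expected), tol)
}
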