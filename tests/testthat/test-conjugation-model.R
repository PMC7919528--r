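test_that("derivatives vanish at extinction and conserve exchanged mass", {
    p <- ModelParams(mu = 0.8, alpha = 1.2, rho = 0.3, beta = 0.05,
                     eta = 0.2, kappa = 0.01, dilution = 0.05)
    expect_equal(conjugationDerivatives(c(0, 0, 0), p), c(0, 0, 0))
    ## exchange terms (eta, beta, kappa) move mass, never create it: the
    ## total derivative equals growth minus dilution for random states
    set.seed(9)
    for (i in 1:50) {
        s <- runif(3, 0, 0.3)
        d <- conjugationDerivatives(s, p)
        free <- 1 - sum(s)
        growth <- p@mu * free * (p@alpha * s[1] + p@rho * s[2] + s[3])
        expect_equal(sum(d), growth - p@dilution * sum(s),
                     tolerance = 1e-12)
    }
    ## without exchange or dilution, sd = 0 stays 0 and the others are
    ## decoupled logistic terms
    p2 <- ModelParams(mu = 0.8, alpha = 1.2, rho = 0.5, beta = 0.1)
    d2 <- conjugationDerivatives(c(0.1, 0, 0.2), p2)
    expect_equal(d2[2], 0)
    expect_equal(d2[1], 1.2 * 0.8 * 0.1 * 0.7)
    expect_equal(d2[3], 0.8 * 0.2 * 0.7)
})

test_that("pure adapted growth follows the logistic closed form", {
    p <- ModelParams(mu = 0.8, alpha = 1, rho = 0, beta = 0,
                     eta = 0, kappa = 0)
    tt <- seq(0, 24, by = 0.25)
    tr <- simulateConjugation(p, c(0, 0, 0.01), tt)
    closed <- 0.01 * exp(0.8 * tt) / (1 - 0.01 + 0.01 * exp(0.8 * tt))
    expect_lt(max(abs(tr@sa - closed)), 1e-6)
    expect_error(simulateConjugation(p, c(-0.1, 0, 0.1), tt),
                 "nonnegative")
    expect_error(simulateConjugation(p, c(0.8, 0.3, 0.2), tt), "<= 1")
})

test_that("expanded model converges to the two-population model as beta grows", {
    tt <- seq(0, 48, by = 0.25)
    po <- ModelParams(mu = 0.8, alpha = 1.2, eta = 0.1)
    orig <- simulateOriginalModel(po, c(0.05, 0.05), tt)
    errs <- vapply(c(10, 100, 1000), function(b) {
        pe <- ModelParams(mu = 0.8, alpha = 1.2, rho = 0, beta = b,
                          eta = 0.1)
        tr <- simulateConjugation(pe, c(0.05, 0, 0.05), tt)
        max(abs(tr@sd + tr@sa - orig$s1))
    }, numeric(1))
    expect_lt(errs[3], 1e-3)
    expect_true(all(diff(errs) < 0))
})

test_that("two-population model: neutral ratio is constant, costly declines", {
    tt <- seq(0, 48, by = 0.5)
    pn <- ModelParams(mu = 0.8, alpha = 1, eta = 0, kappa = 0)
    n <- simulateOriginalModel(pn, c(0.02, 0.01), tt)
    expect_lt(max(abs(n$s0 / n$s1 - 2)), 1e-5)
    pc <- ModelParams(mu = 0.8, alpha = 1.2, eta = 0, kappa = 0)
    c2 <- simulateOriginalModel(pc, c(0.01, 0.01), tt)
    frac <- c2$s1 / (c2$s0 + c2$s1)
    ## strictly declining until saturation, never increasing beyond
    ## integrator noise
    expect_true(all(diff(frac) < 1e-10))
    expect_lt(frac[20], frac[1])
})

test_that("observed growth rate is the abundance-weighted mean", {
    p <- ModelParams(mu = 0.8, rho = 0.3, beta = 0.01)
    mk <- function(sd, sa) new("Trajectory", times = 0, s0 = 0, sd = sd,
                               sa = sa, params = p)
    ## adapted-only pool grows at mu
    expect_equal(observedGrowthRate(mk(0, 0.2)), 0.8)
    ## rho = 1 collapses to mu regardless of composition
    p1 <- ModelParams(mu = 0.8, rho = 1, beta = 0.01)
    tr <- mk(0.13, 0.05); tr@params <- p1
    expect_equal(observedGrowthRate(tr), 0.8)
    ## equal pools give the midpoint mu (1 + rho) / 2
    expect_equal(observedGrowthRate(mk(0.1, 0.1)), 0.8 * (1 + 0.3) / 2)
    ## empty pool is an error; zero timepoints are NA
    expect_error(observedGrowthRate(mk(0, 0)), "zero")
})

test_that("steady-state growth deficit appears when conjugation outpaces adaptation", {
    ## eta >> beta: de novo cells accumulate and depress mu_obs
    pFast <- ModelParams(mu = 0.8, rho = 0.3, beta = 1e-3, eta = 1,
                         kappa = 0.005, dilution = 0.1)
    pSlow <- ModelParams(mu = 0.8, rho = 0.3, beta = 1, eta = 1e-3,
                         kappa = 0.005, dilution = 0.1)
    ssF <- steadyStateGrowthRate(pFast)
    ssS <- steadyStateGrowthRate(pSlow)
    expect_false(ssF$extinct)
    expect_lt(ssF$muObs, ssS$muObs)
    ## rho = 1: no deficit regardless of beta and eta
    pRho1 <- ModelParams(mu = 0.8, rho = 1, beta = 1e-3, eta = 1,
                         kappa = 0.005, dilution = 0.1)
    expect_equal(steadyStateGrowthRate(pRho1)$muObs, 0.8, tolerance = 1e-9)
    ## very fast adaptation: mu_obs indistinguishable from mu
    pBig <- ModelParams(mu = 0.8, rho = 0, beta = 1000, eta = 1,
                        kappa = 0.005, dilution = 0.1)
    expect_gt(steadyStateGrowthRate(pBig)$ratio, 0.999)
    expect_error(steadyStateGrowthRate(ModelParams(dilution = 0)),
                 "dilution")
})

test_that("mu_obs stays within [rho mu, mu] along trajectories", {
    set.seed(31)
    for (i in 1:20) {
        p <- ModelParams(mu = runif(1, 0.4, 1.2), alpha = runif(1, 0.8, 1.5),
                         rho = runif(1), beta = 10^runif(1, -3, 0),
                         eta = 10^runif(1, -3, 0), kappa = runif(1, 0, 0.01))
        tr <- simulateConjugation(p, c(0.04, 0.01, 0.05), seq(0, 48, 1))
        mo <- observedGrowthRate(tr)
        mo <- mo[is.finite(mo)]
        expect_true(all(mo >= p@rho * p@mu - 1e-9 & mo <= p@mu + 1e-9))
    }
})

test_that("de novo cells accumulate transiently within the first day", {
    p <- ModelParams(mu = 0.8, alpha = 1.2, rho = 0, beta = 0.2, eta = 1)
    tr <- simulateConjugation(p, c(0.05, 0, 0.05), seq(0, 24, 0.1))
    peak <- which.max(tr@sd)
    expect_gt(peak, 1)
    expect_lt(peak, length(tr@times))
    expect_gt(tr@sd[peak], tr@sd[1])
    expect_gt(tr@sd[peak], tail(tr@sd, 1))
})

test_that("serial transfer is symmetric when neutral and declines when costly", {
    pn <- ModelParams(mu = 0.8, alpha = 1, rho = 1, beta = 0.01,
                      eta = 0, kappa = 0)
    st <- serialTransfer(pn, initFractionPlasmid = 0.5, days = 14,
                         dilutionPerDay = 1e4)
    expect_length(plasmidFraction(st), 14)
    expect_true(all(abs(plasmidFraction(st) - 0.5) < 1e-6))
    pc <- ModelParams(mu = 0.8, alpha = 1.2, rho = 1, beta = 0.01,
                      eta = 0, kappa = 0)
    stc <- serialTransfer(pc, days = 14)
    expect_true(all(diff(plasmidFraction(stc)) < 0))
    expect_error(serialTransfer(pn, dilutionPerDay = 1),
                 "dilutionPerDay")
    expect_error(serialTransfer(ModelParams(dilution = 0.1)), "dilution")
    df <- as.data.frame(stc)
    expect_named(df, c("day", "plasmid_fraction", "s0", "sd", "sa"))
})

test_that("random valid systems stay nonnegative and bounded by capacity", {
    set.seed(77)
    ok <- TRUE
    for (i in 1:30) {
        p <- ModelParams(mu = runif(1, 0.2, 1.5), alpha = runif(1, 0.5, 2),
                         rho = runif(1), beta = 10^runif(1, -4, 1),
                         eta = 10^runif(1, -4, 0.5),
                         kappa = runif(1, 0, 0.02), dilution = 0)
        init <- runif(3, 0, 0.3)
        tr <- simulateConjugation(p, init, seq(0, 72, 0.5))
        tot <- tr@s0 + tr@sd + tr@sa
        ok <- ok && min(tr@s0, tr@sd, tr@sa) >= -1e-9 &&
            max(tot) <= 1 + 1e-6
    }
    expect_true(ok)
})
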