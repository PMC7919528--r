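## Fitting the de novo -> adapted transition rate to transconjugant
## out-growth, and mapping where the acquisition cost matters at steady
## state.

#' Fit the transition rate beta to a transconjugant out-growth curve
#'
#' Minimizes the sum of squared residuals between the model's total
#' transconjugant density \eqn{S^1(t) = S^D + S^A} (simulation initiated
#' with 100% de novo cells at the observed inoculum) and the observed
#' series, by Nelder-Mead simplex search on log(beta) (and, optionally,
#' logit(rho)). Three perturbed starts are run and the best kept. The
#' default initial beta guess is the geometric lag time of the observed
#' curve, overridable via \code{initBeta}.
#'
#' @param time observation times (h).
#' @param observed observed S1 densities (normalized to carrying capacity).
#' @param params a \linkS4class{ModelParams}; beta (and rho when
#'   \code{fitRho}) are replaced by the fitted values, all other rates are
#'   held fixed.
#' @param initT0 initial de novo density (normalized); defaults to the
#'   first observation.
#' @param fitRho also fit rho (default FALSE: rho fixed at
#'   \code{params@rho}).
#' @param initBeta initial beta guess (1/h); NULL uses the geometric lag.
#' @param logResiduals compute residuals on the log density scale instead
#'   of the linear scale (default FALSE, matching raw-curve fitting).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return a \linkS4class{FitResult}.
#' @examples
#' p <- ModelParams(mu = 0.8, rho = 0, beta = 0.05)
#' tt <- seq(0, 48, 0.5)
#' s1 <- as.data.frame(simulateConjugation(p, c(0, 4e-6, 0), tt))$s1
#' fitTransitionRate(tt, s1, p)
#' @export
fitTransitionRate <- function(time, observed, params, initT0 = observed[1],
                              fitRho = FALSE, initBeta = NULL,
                              logResiduals = FALSE, maxit = 500) {
    stopifnot(length(time) == length(observed), length(time) >= 5)
    if (initT0 <= 0) stop("initT0 must be positive")
    init <- c(0, initT0, 0)

    if (is.null(initBeta)) {
        initBeta <- tryCatch({
            y <- log(pmax(observed, 1e-12) / max(observed[1], 1e-12))
            cur <- GrowthCurve(time = time, logFold = y,
                               backgroundSubtracted = TRUE)
            suppressWarnings(geometricLag(cur))
        }, error = function(e) 0.1)
        if (!is.finite(initBeta) || initBeta <= 0) initBeta <- 0.1
    }

    obj <- function(theta) {
        beta <- exp(theta[1])
        rho <- if (fitRho) stats::plogis(theta[2]) else params@rho
        p <- ModelParams(mu = params@mu, alpha = params@alpha, rho = rho,
                         beta = beta, eta = params@eta,
                         kappa = params@kappa, dilution = params@dilution)
        s1 <- tryCatch({
            tr <- simulateConjugation(p, init, time)
            tr@sd + tr@sa
        }, error = function(e) NULL)
        if (is.null(s1)) return(1e12)
        r <- if (logResiduals) log(pmax(s1, 1e-12)) -
                 log(pmax(observed, 1e-12)) else s1 - observed
        v <- sum(r^2)
        if (!is.finite(v)) 1e12 else v
    }

    theta0 <- if (fitRho) c(log(initBeta), stats::qlogis(
        min(max(params@rho, 0.05), 0.95))) else log(initBeta)
    perturb <- list(0, log(1 / 3), log(3))
    best <- NULL
    for (dp in perturb) {
        th <- theta0
        th[1] <- th[1] + dp
        opt <- optim(th, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-12,
                                    warn.1d.NelderMead = FALSE))
        if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (!is.finite(best$value)) stop("non-finite objective at the optimum")
    betaHat <- exp(best$par[1])
    rhoHat <- if (fitRho) stats::plogis(best$par[2]) else params@rho
    ig <- c(beta = initBeta)
    if (fitRho) ig <- c(ig, rho = params@rho)
    new("FitResult", betaHat = betaHat, rhoHat = rhoHat,
        objective = best$value, converged = best$convergence == 0,
        initGuess = ig)
}

#' Observable growth rate and lag implied by fitted dynamics
#'
#' Simulates the model at the fitted parameters from 100% de novo cells and
#' extracts, from \eqn{\ln S^1(t)}, the growth rate and geometric lag an
#' experimenter fitting the out-growth curve would report (Baranyi fit for
#' mu, tangent construction for the lag).
#'
#' @param fit a converged \linkS4class{FitResult}.
#' @param params base \linkS4class{ModelParams} (beta/rho are taken from
#'   the fit).
#' @param initT0 initial de novo density (normalized).
#' @param times simulation grid (h).
#' @return named numeric: \code{mu} (1/h) and \code{lag} (h).
#' @export
predictedGrowthSummary <- function(fit, params, initT0,
                                   times = seq(0, 48, by = 0.25)) {
    if (!fit@converged) stop("fit did not converge")
    p <- ModelParams(mu = params@mu, alpha = params@alpha,
                     rho = fit@rhoHat, beta = fit@betaHat,
                     eta = params@eta, kappa = params@kappa,
                     dilution = params@dilution)
    tr <- simulateConjugation(p, c(0, initT0, 0), times)
    s1 <- tr@sd + tr@sa
    y <- log(pmax(s1, 1e-15) / s1[1])
    cur <- GrowthCurve(time = times, logFold = y,
                       backgroundSubtracted = TRUE)
    gf <- fitGrowthCurve(cur, "baranyi")
    lag <- suppressWarnings(geometricLag(cur))
    c(mu = gf@mu, lag = lag)
}

#' Map where the acquisition cost alters steady-state growth
#'
#' For every (alpha, beta) grid cell, runs the model to steady state under
#' continuous dilution from a 1:1 plasmid-free : adapted start and
#' classifies whether \eqn{\mu_{obs}/\mu} falls below the threshold
#' (default 0.98). Cells where the plasmid washes out are marked extinct
#' and excluded from the classification.
#'
#' @param alphaGrid fitness-cost grid (default 25 points over [0.8, 1.5]).
#' @param betaGrid transition-rate grid (default 25 log-spaced points over
#'   [1e-4, 1]).
#' @param eta conjugation efficiency for this map.
#' @param params base \linkS4class{ModelParams} (alpha, beta, eta are
#'   overridden per cell/map). Defaults use continuous dilution D = 0.1/h
#'   (a steady state needs turnover) and segregation kappa = 0.005/h (a
#'   plasmid-free subpopulation must be regenerated for conjugation to
#'   keep producing de novo cells at steady state; see the vignette).
#' @param init initial state (s0, sd, sa); default 1:1 at total 0.1.
#' @param threshold classification threshold in (0, 1).
#' @return a \linkS4class{BoundaryMap}.
#' @export
boundaryMap <- function(alphaGrid = seq(0.8, 1.5, length.out = 25),
                        betaGrid = 10^seq(-4, 0, length.out = 25),
                        eta = 1,
                        params = ModelParams(mu = 0.8, rho = 0,
                                             kappa = 0.005,
                                             dilution = 0.1),
                        init = c(0.05, 0, 0.05), threshold = 0.98) {
    if (length(alphaGrid) == 0 || length(betaGrid) == 0)
        stop("grids must be nonempty")
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must be strictly inside (0, 1)")
    ratio <- matrix(NA_real_, length(alphaGrid), length(betaGrid),
                    dimnames = list(signif(alphaGrid, 4),
                                    signif(betaGrid, 4)))
    extinct <- matrix(FALSE, length(alphaGrid), length(betaGrid))
    for (i in seq_along(alphaGrid)) {
        for (j in seq_along(betaGrid)) {
            p <- ModelParams(mu = params@mu, alpha = alphaGrid[i],
                             rho = params@rho, beta = betaGrid[j],
                             eta = eta, kappa = params@kappa,
                             dilution = params@dilution)
            ss <- steadyStateGrowthRate(p, init)
            if (ss$extinct) {
                extinct[i, j] <- TRUE
            } else {
                ratio[i, j] <- ss$ratio
            }
        }
    }
    below <- !is.na(ratio) & ratio < threshold
    new("BoundaryMap", alphaGrid = alphaGrid, betaGrid = betaGrid,
        eta = eta, threshold = threshold, ratio = ratio,
        belowThreshold = below, extinct = extinct)
}

#' Boundary-map sensitivity to the classification threshold
#'
#' Computes the steady-state ratio grid once and re-classifies it at each
#' requested threshold; reports pairwise Jaccard overlaps between the
#' below-threshold sets. Thresholds must lie strictly inside (0, 1).
#'
#' @inheritParams boundaryMap
#' @param thresholds numeric vector of thresholds in (0, 1).
#' @return list with \code{maps} (one \linkS4class{BoundaryMap} per
#'   threshold) and \code{jaccard} (overlap matrix).
#' @export
thresholdSensitivity <- function(alphaGrid = seq(0.8, 1.5, length.out = 25),
                                 betaGrid = 10^seq(-4, 0, length.out = 25),
                                 eta = 1,
                                 params = ModelParams(mu = 0.8, rho = 0,
                                                      kappa = 0.005,
                                                      dilution = 0.1),
                                 init = c(0.05, 0, 0.05),
                                 thresholds = c(0.95, 0.98, 0.99)) {
    if (any(thresholds <= 0 | thresholds >= 1))
        stop("thresholds must be strictly inside (0, 1)")
    base <- boundaryMap(alphaGrid, betaGrid, eta, params, init,
                        threshold = thresholds[1])
    maps <- lapply(thresholds, function(th) {
        below <- !is.na(base@ratio) & base@ratio < th
        new("BoundaryMap", alphaGrid = alphaGrid, betaGrid = betaGrid,
            eta = eta, threshold = th, ratio = base@ratio,
            belowThreshold = below, extinct = base@extinct)
    })
    names(maps) <- as.character(thresholds)
    k <- length(maps)
    jac <- matrix(NA_real_, k, k, dimnames = list(names(maps), names(maps)))
    for (a in seq_len(k)) for (b in seq_len(k)) {
        A <- maps[[a]]@belowThreshold
        B <- maps[[b]]@belowThreshold
        u <- sum(A | B)
        jac[a, b] <- if (u == 0) 1 else sum(A & B) / u
    }
    list(maps = maps, jaccard = jac)
}
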