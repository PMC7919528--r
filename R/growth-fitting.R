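## Growth-curve model functions and parameter estimation.
##
## All fits operate on the log fold-change series y(t) = ln(OD'(t)/OD'(0)),
## which makes the estimates invariant to the OD-to-density conversion and to
## any positive rescaling of the background-subtracted signal.

#' Baranyi-Roberts growth model in log space
#'
#' \deqn{y(t) = y_0 + \mu A(t) - \ln\!\left(1 +
#'   \frac{e^{\mu A(t)} - 1}{e^{\mathrm{amplitude}}}\right)}
#' with the lag-adjustment
#' \deqn{A(t) = t + \frac{1}{\mu}\ln\!\left(e^{-\mu t} + e^{-\mu\lambda}
#'   - e^{-\mu(t+\lambda)}\right).}
#' At \eqn{\lambda = 0}, \eqn{A(t) = t}; as \eqn{t \to \infty},
#' \eqn{y \to y_0 + \mathrm{amplitude}}.
#'
#' @param t time, hours (vectorized).
#' @param mu maximum specific growth rate, 1/h (> 0).
#' @param lag lag time, h (>= 0).
#' @param y0 value of y at t = 0 (0 for a fold-change series).
#' @param amplitude ln fold-change from y0 to saturation.
#' @return numeric vector of y values.
#' @examples
#' baranyiY(seq(0, 24, 0.25), mu = 0.8, lag = 2, amplitude = log(150))
#' @export
baranyiY <- function(t, mu, lag, y0 = 0, amplitude) {
    stopifnot(mu > 0, lag >= 0)
    ## A(t) = t + (1/mu) log(exp(-mu t) (1 - exp(-mu lag)) + exp(-mu lag))
    A <- t + log(exp(-mu * t) * (1 - exp(-mu * lag)) + exp(-mu * lag)) / mu
    m <- mu * A
    ## saturation correction, numerically stable for large m
    corr <- ifelse(m - amplitude > 35, m - amplitude,
                   log1p(expm1(pmin(m, 700)) * exp(-amplitude)))
    y0 + m - corr
}

#' Modified Gompertz growth model (Zwietering form)
#'
#' \deqn{y = A \exp\left(-\exp\left(\frac{\mu e}{A}(\lambda - t) + 1\right)\right)}
#'
#' @inheritParams baranyiY
#' @param A ln fold-change amplitude.
#' @export
gompertzY <- function(t, mu, lag, A, y0 = 0) {
    y0 + A * exp(-exp((mu * exp(1) / A) * (lag - t) + 1))
}

#' Modified Logistic growth model (Zwietering form)
#'
#' \deqn{y = \frac{A}{1 + \exp\left(\frac{4\mu}{A}(\lambda - t) + 2\right)}}
#'
#' @inheritParams gompertzY
#' @export
logisticY <- function(t, mu, lag, A, y0 = 0) {
    y0 + A / (1 + exp((4 * mu / A) * (lag - t) + 2))
}

#' Background-subtract a curve and compute its log fold-change series
#'
#' Subtracts the blank (a scalar OD, or the median OD of a blank-well
#' \linkS4class{GrowthCurve}), floors the result at the detection limit,
#' and computes \eqn{y(t) = \ln(\mathrm{OD}'(t)/\overline{\mathrm{OD}'(0)})}
#' where the reference is the mean of the first \code{nBaseline} floored
#' readings.
#'
#' @param curve a \linkS4class{GrowthCurve} with raw OD readings.
#' @param blank scalar background OD (>= 0) or a blank-well GrowthCurve.
#' @param floor detection limit applied after subtraction (OD units).
#' @param nBaseline number of initial readings averaged for the reference.
#' @return the curve with background-subtracted \code{od}, \code{logFold}
#'   filled in, and \code{backgroundSubtracted = TRUE}.
#' @examples
#' cur <- GrowthCurve(time = 0:20, od = 0.04 + 0.01 * exp(0.3 * (0:20)))
#' pp <- preprocessCurve(cur, blank = 0.04)
#' head(pp@logFold)
#' @export
preprocessCurve <- function(curve, blank = 0, floor = 1e-3, nBaseline = 3) {
    if (is(blank, "GrowthCurve")) blank <- median(blank@od)
    stopifnot(is.numeric(blank), length(blank) == 1L, blank >= 0)
    if (length(curve@od) == 0)
        stop("curve has no OD readings")
    if (max(curve@od) <= blank)
        stop("no signal: all readings are at or below the blank")
    odc <- pmax(curve@od - blank, floor)
    ref <- mean(odc[seq_len(min(nBaseline, length(odc)))])
    GrowthCurve(time = curve@time, od = odc, logFold = log(odc / ref),
                wellId = curve@wellId, backgroundSubtracted = TRUE)
}

## centered moving average with shrinking windows at the ends, so the
## smoothed series has no NA padding
.smooth <- function(y, window) {
    n <- length(y)
    h <- window %/% 2L
    vapply(seq_len(n), function(i) {
        lo <- max(1L, i - h); hi <- min(n, i + h)
        mean(y[lo:hi])
    }, numeric(1))
}

#' Maximum growth rate by curve smoothing and numerical differentiation
#'
#' Smooths the log fold-change series with a centered moving average, locates
#' the timepoint of maximum discrete derivative within the exponential region
#' (smoothed y between 10% and 90% of its maximum; earliest index on ties),
#' and estimates the rate as the slope of the secant through the samples two
#' points above and below that timepoint:
#' \deqn{\mu = \frac{y_{i+2} - y_{i-2}}{t_{i+2} - t_{i-2}}.}
#'
#' @param curve a preprocessed \linkS4class{GrowthCurve} (or one constructed
#'   directly with a \code{logFold} series).
#' @param smoothWindow moving-average window in samples (default 5, i.e.
#'   1.25 h at 15-min sampling).
#' @return list with \code{mu} (1/h) and \code{tMax} (h, the maximum-rate
#'   timepoint).
#' @export
maxSlopeRate <- function(curve, smoothWindow = 5) {
    y <- .logFoldOf(curve)
    t <- curve@time
    n <- length(y)
    if (n < 5) stop("need at least 5 samples")
    ys <- .smooth(y, smoothWindow)
    ymax <- max(ys)
    if (ymax <= 0) stop("no growth signal: log fold-change never positive")
    region <- which(ys >= 0.1 * ymax & ys <= 0.9 * ymax)
    region <- region[region >= 2L & region <= n - 1L]
    if (length(region) == 0) stop("exponential region is empty")
    d <- (ys[region + 1L] - ys[region - 1L]) / (t[region + 1L] - t[region - 1L])
    i <- region[which.max(d)]          # which.max takes the earliest tie
    if (i <= 2L || i >= n - 1L) stop("max-rate at boundary of the series")
    mu <- (ys[i + 2L] - ys[i - 2L]) / (t[i + 2L] - t[i - 2L])
    list(mu = mu, tMax = t[i])
}

.logFoldOf <- function(curve) {
    if (length(curve@logFold) == 0)
        stop("curve has no log fold-change series; run preprocessCurve() first")
    curve@logFold
}

#' Geometric lag time
#'
#' The x-intercept of the tangent to the log-growth curve at the
#' maximum-rate point: \eqn{\lambda = t_{max} - y(t_{max})/\mu}. Negative
#' values (tangent crossing left of the origin) are clamped to 0 with a
#' warning.
#'
#' @inheritParams maxSlopeRate
#' @param mu maximum growth rate (1/h); estimated with
#'   \code{\link{maxSlopeRate}} when missing.
#' @param tMax time of the maximum-rate point (h); ditto.
#' @return lag time in hours.
#' @export
geometricLag <- function(curve, mu = NULL, tMax = NULL, smoothWindow = 5) {
    if (is.null(mu) || is.null(tMax)) {
        pr <- maxSlopeRate(curve, smoothWindow)
        if (is.null(mu)) mu <- pr$mu
        if (is.null(tMax)) tMax <- pr$tMax
    }
    stopifnot(mu > 0)
    yAt <- approx(curve@time, .logFoldOf(curve), xout = tMax)$y
    lag <- tMax - yAt / mu
    if (lag < 0) {
        warning("negative geometric lag clamped to 0")
        lag <- 0
    }
    lag
}

## model function dispatch for the parametric fits
.modelFun <- function(method) {
    switch(method,
        baranyi  = function(t, mu, lag, A, y0) baranyiY(t, mu, lag, y0, A),
        gompertz = function(t, mu, lag, A, y0) gompertzY(t, mu, lag, A, y0),
        logistic = function(t, mu, lag, A, y0) logisticY(t, mu, lag, A, y0),
        stop("unknown method: ", method))
}

#' Fit a parametric growth model to one curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the Baranyi,
#' modified Gompertz or modified Logistic model to the log fold-change
#' series. Residuals are inverse-variance weighted for additive OD noise
#' with a relative-error floor:
#' \eqn{w_i = 1/(c^2 + (\hat\sigma/\mathrm{OD}_i)^2)} with
#' \eqn{\hat\sigma = \mathrm{mad}(\Delta \mathrm{OD})/\sqrt{2}} estimated
#' from first differences (log-transforming additive OD noise otherwise
#' lets the noise-amplified low-density points dominate the fit). Curves
#' built directly from a log fold-change series are fitted unweighted.
#' Starting values come from \code{\link{maxSlopeRate}} and
#' \code{\link{geometricLag}}; the fit is retried from three
#' deterministically jittered starts and the best kept. A curve with no
#' discernible growth returns \code{converged = FALSE} rather than raising.
#'
#' @param curve a preprocessed \linkS4class{GrowthCurve} (>= 8 samples).
#' @param method one of \code{"baranyi"}, \code{"gompertz"},
#'   \code{"logistic"}.
#' @param smoothWindow passed to the starting-value heuristics.
#' @param relSigma relative-error floor c of the weighting scheme
#'   (default 0.1).
#' @return a \linkS4class{GrowthFit}.
#' @examples
#' kin <- adaptedKinetics(t0 = 2e7, saturationOd = 2)
#' cur <- simulateGrowthCurve(kin, noise = NoiseSpec(odSigma = 0))
#' fitGrowthCurve(preprocessCurve(cur, blank = 0.04), "baranyi")
#' @export
fitGrowthCurve <- function(curve,
                           method = c("baranyi", "gompertz", "logistic"),
                           smoothWindow = 5, relSigma = 0.1) {
    method <- match.arg(method)
    y <- .logFoldOf(curve)
    t <- curve@time
    if (length(y) < 8) stop("need at least 8 samples for a parametric fit")
    w <- rep(1, length(y))
    if (length(curve@od) == length(y)) {
        sig <- stats::mad(diff(curve@od)) / sqrt(2)
        w <- 1 / (relSigma^2 + (sig / curve@od)^2)
        w <- w / mean(w)
    }

    failFit <- function() GrowthFit(NA_real_, NA_real_, NA_real_, NA_real_,
                                    method, sum(y^2), FALSE)
    if (max(y) < 0.1) return(failFit())   # flat curve: nothing to fit

    start <- tryCatch({
        pr <- maxSlopeRate(curve, smoothWindow)
        lag0 <- tryCatch(geometricLag(curve, pr$mu, pr$tMax),
                         warning = function(w) 0)
        c(mu = max(pr$mu, 1e-3), lag = max(lag0, 0), A = max(y), y0 = 0)
    }, error = function(e)
        c(mu = max(max(y) / max(t), 1e-3), lag = 0, A = max(y), y0 = 0))

    f <- .modelFun(method)
    lower <- c(mu = 1e-4, lag = 0, A = 1e-3, y0 = -2)
    upper <- c(mu = 20, lag = max(t), A = 60, y0 = 2)
    sw <- sqrt(w)
    resid <- function(par) sw * (f(t, par[1], par[2], par[3], par[4]) - y)
    jitters <- list(c(1, 1, 1, 1), c(0.7, 0.5, 1.2, 1),
                    c(1.4, 1.5, 0.9, 1), c(0.5, 2, 1.5, 1))
    best <- NULL
    for (j in jitters) {
        st <- pmin(pmax(start * j, lower + 1e-9), upper - 1e-9)
        fit <- tryCatch(
            minpack.lm::nls.lm(
                par = st, lower = lower, upper = upper, fn = resid,
                control = minpack.lm::nls.lm.control(
                    ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
            error = function(e) NULL)
        if (!is.null(fit)) {
            cf <- fit$par
            rss <- sum((f(t, cf[1], cf[2], cf[3], cf[4]) - y)^2)
            if (is.null(best) || rss < best$rss)
                best <- list(fit = fit, rss = rss)
            if (rss < 1e-12 * length(y)) break
        }
    }
    if (is.null(best)) return(failFit())
    cf <- best$fit$par
    GrowthFit(mu = cf[["mu"]], lag = max(cf[["lag"]], 0), y0 = cf[["y0"]],
              amplitude = cf[["A"]], method = method, rss = best$rss,
              converged = best$fit$info %in% 1:4)
}

#' Fit growth parameters for every non-blank well of a plate
#'
#' Convenience wrapper: preprocesses each well against the blank and applies
#' the requested estimation methods. The \code{"maxslope"} method reports the
#' numerical-derivative rate with the geometric lag.
#'
#' @param plate a \linkS4class{PlateExperiment}.
#' @param blank scalar blank OD, a blank-well GrowthCurve, or \code{NULL} to
#'   use the median OD of the plate's blank wells (0 when there are none).
#' @param methods character vector from
#'   \code{c("baranyi", "gompertz", "logistic", "maxslope")}.
#' @param smoothWindow passed through.
#' @return data.frame with columns well, method, mu, lag, y0, amplitude,
#'   rss, converged.
#' @export
fitGrowthPlate <- function(plate, blank = NULL,
                           methods = "baranyi", smoothWindow = 5) {
    methods <- match.arg(methods,
        c("baranyi", "gompertz", "logistic", "maxslope"), several.ok = TRUE)
    blank <- .resolveBlank(plate, blank)
    md <- wellMetadata(plate)
    wells <- md$well[is.na(md$role) | md$role != "blank"]
    rows <- list()
    for (w in wells) {
        pp <- tryCatch(preprocessCurve(getCurve(plate, w), blank),
                       error = function(e) NULL)
        if (is.null(pp)) next
        for (m in methods) {
            if (m == "maxslope") {
                est <- tryCatch({
                    pr <- maxSlopeRate(pp, smoothWindow)
                    lg <- suppressWarnings(geometricLag(pp, pr$mu, pr$tMax))
                    list(mu = pr$mu, lag = lg, conv = TRUE)
                }, error = function(e) list(mu = NA, lag = NA, conv = FALSE))
                rows[[length(rows) + 1L]] <- data.frame(
                    well = w, method = m, mu = est$mu, lag = est$lag,
                    y0 = NA_real_, amplitude = max(pp@logFold),
                    rss = NA_real_, converged = est$conv)
            } else {
                ft <- fitGrowthCurve(pp, m, smoothWindow)
                rows[[length(rows) + 1L]] <- data.frame(
                    well = w, method = m, mu = ft@mu, lag = ft@lag,
                    y0 = ft@y0, amplitude = ft@amplitude, rss = ft@rss,
                    converged = ft@converged)
            }
        }
    }
    do.call(rbind, rows)
}

## blank resolution shared by plate-level operations: explicit value wins,
## otherwise the median OD over the plate's blank wells, otherwise 0
.resolveBlank <- function(plate, blank) {
    if (!is.null(blank)) {
        if (is(blank, "GrowthCurve")) return(median(blank@od))
        return(blank)
    }
    md <- wellMetadata(plate)
    bw <- md$well[!is.na(md$role) & md$role == "blank"]
    if (length(bw) == 0) return(0)
    median(odMatrix(plate)[, bw, drop = FALSE])
}
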