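#' @import methods
#' @importFrom stats approx coef lm median optim pairwise.t.test
#'   rnorm rpois t.test aov var residuals
#' @importFrom utils read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData "colData<-"
#' @importFrom S4Vectors DataFrame
NULL

.VALID_ROLES <- c("adapted", "de_novo", "blank")

## ---------------------------------------------------------------------------
## KineticParams
## ---------------------------------------------------------------------------

#' Kinetic parameters of a single growth curve
#'
#' Container for the Baranyi parameterization of batch growth: the maximum
#' specific growth rate \eqn{\mu} (1/h), the lag time \eqn{\lambda} (h), the
#' natural-log initial density \eqn{y_0} (ln CFU-per-well equivalents), and
#' the natural-log fold increase from \eqn{y_0} to saturation (the amplitude,
#' dimensionless). The saturation density is \eqn{\exp(y_0 + \mathrm{amplitude})}.
#'
#' @slot mu numeric(1), maximum specific growth rate, 1/h; must be > 0.
#' @slot lag numeric(1), lag time, h; must be >= 0.
#' @slot y0 numeric(1), natural log of the initial density.
#' @slot amplitude numeric(1), ln fold-change from y0 to saturation; > 0.
#'
#' @examples
#' kp <- KineticParams(mu = 0.8, lag = 2, y0 = log(2000), amplitude = log(2.5e5))
#' growthRate(kp)
#' @export
setClass("KineticParams",
    representation(mu = "numeric", lag = "numeric",
                   y0 = "numeric", amplitude = "numeric"))

setValidity("KineticParams", function(object) {
    msg <- NULL
    for (s in c("mu", "lag", "y0", "amplitude")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v))
            msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    }
    if (is.null(msg)) {
        if (object@mu <= 0) msg <- c(msg, "'mu' must be > 0")
        if (object@lag < 0) msg <- c(msg, "'lag' must be >= 0")
        if (object@amplitude <= 0) msg <- c(msg, "'amplitude' must be > 0")
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname KineticParams-class
#' @param mu,lag,y0,amplitude see slots.
#' @export
KineticParams <- function(mu, lag, y0, amplitude) {
    new("KineticParams", mu = as.numeric(mu), lag = as.numeric(lag),
        y0 = as.numeric(y0), amplitude = as.numeric(amplitude))
}

## ---------------------------------------------------------------------------
## NoiseSpec
## ---------------------------------------------------------------------------

#' Measurement-noise specification for the synthetic plate generator
#'
#' @slot odSigma numeric(1), standard deviation of additive Gaussian OD noise
#'   (OD units); >= 0.
#' @slot blankOd numeric(1), constant background offset added to every
#'   reading (OD units); >= 0.
#' @slot cfuPlatingVolume numeric(1), volume plated per CFU spot (ml);
#'   default 0.01 ml (a 10 ul spot).
#' @slot seed integer(1), RNG seed; identical seeds give bit-identical output.
#'
#' @examples
#' NoiseSpec(odSigma = 0.003, blankOd = 0.04, seed = 11L)
#' @export
setClass("NoiseSpec",
    representation(odSigma = "numeric", blankOd = "numeric",
                   cfuPlatingVolume = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
    msg <- NULL
    if (object@odSigma < 0) msg <- c(msg, "'odSigma' must be >= 0")
    if (object@blankOd < 0) msg <- c(msg, "'blankOd' must be >= 0")
    if (object@cfuPlatingVolume <= 0)
        msg <- c(msg, "'cfuPlatingVolume' must be > 0")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "'seed' must be a single integer")
    if (is.null(msg)) TRUE else msg
})

#' @rdname NoiseSpec-class
#' @param odSigma,blankOd,cfuPlatingVolume,seed see slots.
#' @export
NoiseSpec <- function(odSigma = 0.003, blankOd = 0.04,
                      cfuPlatingVolume = 0.01, seed = 1L) {
    new("NoiseSpec", odSigma = as.numeric(odSigma),
        blankOd = as.numeric(blankOd),
        cfuPlatingVolume = as.numeric(cfuPlatingVolume),
        seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## GrowthCurve
## ---------------------------------------------------------------------------

#' A single well's OD600 time series
#'
#' Holds raw or background-subtracted optical density over time for one well,
#' and (after \code{\link{preprocessCurve}}) the log fold-change series
#' \eqn{y(t) = \ln(\mathrm{OD}'(t)/\mathrm{OD}'(0))} that all growth fits
#' operate on.
#'
#' @slot time numeric, hours, strictly increasing, time[1] >= 0.
#' @slot od numeric, OD600 readings (same length as time).
#' @slot logFold numeric, log fold-change series; length 0 until computed.
#' @slot wellId character(1) well label.
#' @slot backgroundSubtracted logical(1).
#' @export
setClass("GrowthCurve",
    representation(time = "numeric", od = "numeric", logFold = "numeric",
                   wellId = "character", backgroundSubtracted = "logical"))

setValidity("GrowthCurve", function(object) {
    msg <- NULL
    n <- length(object@time)
    if (n > 0 && length(object@od) > 0 && length(object@od) != n)
        msg <- c(msg, "'time' and 'od' must have equal length")
    if (length(object@logFold) > 0 && length(object@logFold) != n)
        msg <- c(msg, "'logFold' must match 'time' in length")
    if (n > 0 && object@time[1] < 0)
        msg <- c(msg, "time must start at >= 0")
    if (n > 1 && any(diff(object@time) <= 0))
        msg <- c(msg, "time must be strictly increasing")
    if (is.null(msg)) TRUE else msg
})

#' @rdname GrowthCurve-class
#' @param time,od,logFold,wellId,backgroundSubtracted see slots. Either
#'   \code{od} or \code{logFold} (or both) must be supplied.
#' @export
GrowthCurve <- function(time, od = numeric(0), logFold = numeric(0),
                        wellId = "well", backgroundSubtracted = FALSE) {
    if (length(od) == 0 && length(logFold) == 0)
        stop("supply 'od' and/or 'logFold'")
    new("GrowthCurve", time = as.numeric(time), od = as.numeric(od),
        logFold = as.numeric(logFold), wellId = as.character(wellId),
        backgroundSubtracted = backgroundSubtracted)
}

## ---------------------------------------------------------------------------
## PlateExperiment
## ---------------------------------------------------------------------------

#' A plate of growth curves with per-well metadata
#'
#' Thin extension of \link[SummarizedExperiment]{SummarizedExperiment}:
#' timepoints are rows (hours in \code{rowData(x)$time_h}), wells are columns,
#' and the single assay \code{"OD"} holds the raw OD600 readings. Per-well
#' metadata lives in \code{colData}: \code{role} (one of \code{"adapted"},
#' \code{"de_novo"}, \code{"blank"}, or \code{NA} before metadata are joined),
#' \code{dilution_factor}, \code{true_T0_cfu}, \code{condition},
#' \code{replicate}.
#'
#' @export
setClass("PlateExperiment", contains = "SummarizedExperiment")

setValidity("PlateExperiment", function(object) {
    msg <- NULL
    rd <- SummarizedExperiment::rowData(object)
    if (!"time_h" %in% colnames(rd))
        return("rowData must contain 'time_h'")
    tt <- rd$time_h
    if (length(tt) > 1 && any(diff(tt) <= 0))
        msg <- c(msg, "time_h must be strictly increasing")
    if (!"OD" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'OD' is required")
    cd <- SummarizedExperiment::colData(object)
    if ("role" %in% colnames(cd)) {
        bad <- setdiff(unique(cd$role[!is.na(cd$role)]), .VALID_ROLES)
        if (length(bad))
            msg <- c(msg, paste0("invalid role(s): ",
                                 paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate well ids")
    if (is.null(msg)) TRUE else msg
})

#' @rdname PlateExperiment-class
#' @param time numeric vector of hours (one per row of \code{od}).
#' @param od numeric matrix, timepoints x wells; column names are well ids.
#' @param metadata optional data.frame with columns \code{well}, \code{role},
#'   \code{dilution_factor}, \code{true_T0_cfu}, \code{condition},
#'   \code{replicate}.
#' @export
PlateExperiment <- function(time, od, metadata = NULL) {
    od <- as.matrix(od)
    if (length(time) != nrow(od))
        stop("length(time) must equal nrow(od)")
    if (is.null(colnames(od)))
        colnames(od) <- paste0("W", seq_len(ncol(od)))
    cd <- S4Vectors::DataFrame(
        role = rep(NA_character_, ncol(od)),
        dilution_factor = rep(NA_real_, ncol(od)),
        true_T0_cfu = rep(NA_real_, ncol(od)),
        condition = rep(NA_character_, ncol(od)),
        replicate = rep(NA_integer_, ncol(od)),
        row.names = colnames(od))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(OD = od),
        rowData = S4Vectors::DataFrame(time_h = as.numeric(time)),
        colData = cd)
    pe <- new("PlateExperiment", se)
    if (!is.null(metadata)) pe <- joinWellMetadata(pe, metadata)
    pe
}

## ---------------------------------------------------------------------------
## GrowthFit
## ---------------------------------------------------------------------------

#' Estimated growth parameters for one curve
#'
#' @slot mu numeric(1), maximum specific growth rate (1/h); NA when the fit
#'   did not converge.
#' @slot lag numeric(1), lag time (h), clamped at 0.
#' @slot y0 numeric(1), fitted offset of the log fold-change series at t = 0.
#' @slot amplitude numeric(1), fitted ln fold-change to saturation.
#' @slot method character(1), one of "baranyi", "gompertz", "logistic",
#'   "maxslope".
#' @slot rss numeric(1), residual sum of squares.
#' @slot converged logical(1).
#' @export
setClass("GrowthFit",
    representation(mu = "numeric", lag = "numeric", y0 = "numeric",
                   amplitude = "numeric", method = "character",
                   rss = "numeric", converged = "logical"))

setValidity("GrowthFit", function(object) {
    msg <- NULL
    if (!object@method %in% c("baranyi", "gompertz", "logistic", "maxslope"))
        msg <- c(msg, "unknown method")
    if (isTRUE(object@converged)) {
        if (!is.finite(object@mu) || object@mu <= 0)
            msg <- c(msg, "'mu' must be > 0 when converged")
        if (is.finite(object@lag) && object@lag < 0)
            msg <- c(msg, "'lag' must be >= 0")
    }
    if (is.finite(object@rss) && object@rss < 0)
        msg <- c(msg, "'rss' must be >= 0")
    if (is.null(msg)) TRUE else msg
})

GrowthFit <- function(mu, lag, y0, amplitude, method, rss, converged) {
    new("GrowthFit", mu = as.numeric(mu), lag = as.numeric(lag),
        y0 = as.numeric(y0), amplitude = as.numeric(amplitude),
        method = method, rss = as.numeric(rss), converged = converged)
}

## ---------------------------------------------------------------------------
## StandardCurve
## ---------------------------------------------------------------------------

#' Standard curve linking initial density to time-to-threshold
#'
#' Ordinary least-squares line \eqn{t^* = \mathrm{intercept} +
#' \mathrm{slope}\cdot\ln T_0} built from adapted-transconjugant dilution
#' wells at a fixed threshold density \eqn{T^*}. During exponential growth
#' \eqn{\ln T(t) = \ln T_0 + \mu(t - \lambda)}, so the slope equals
#' \eqn{-1/\mu}.
#'
#' @slot slope numeric(1), h per ln(CFU); must be negative.
#' @slot intercept numeric(1), h.
#' @slot thresholdOd numeric(1), the threshold OD T*.
#' @slot r2 numeric(1), coefficient of determination.
#' @slot nPoints integer(1).
#' @slot t0Range numeric(2), [min, max] T0 (CFU) used to build the curve.
#' @export
setClass("StandardCurve",
    representation(slope = "numeric", intercept = "numeric",
                   thresholdOd = "numeric", r2 = "numeric",
                   nPoints = "integer", t0Range = "numeric"))

setValidity("StandardCurve", function(object) {
    msg <- NULL
    if (object@slope >= 0) msg <- c(msg, "'slope' must be negative")
    if (object@r2 < 0 || object@r2 > 1) msg <- c(msg, "'r2' must be in [0,1]")
    if (object@nPoints < 2L) msg <- c(msg, "need >= 2 points")
    if (length(object@t0Range) != 2L) msg <- c(msg, "'t0Range' must be [min,max]")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## AcquisitionCostResult
## ---------------------------------------------------------------------------

#' Acquisition-cost estimate for a set of de novo wells
#'
#' @slot tPred numeric, standard-curve predicted initial CFU per replicate.
#' @slot t0True numeric, measured (CFU) initial density per replicate.
#' @slot ratio numeric(1), mean(tPred)/mean(t0True); < 1 indicates a cost.
#' @slot pOneTailed numeric(1), one-tailed Welch t-test on log10 densities,
#'   H1: tPred < t0True; NA with a single replicate.
#' @slot significant logical(1), TRUE iff p < 0.05 and ratio < 1.
#' @export
setClass("AcquisitionCostResult",
    representation(tPred = "numeric", t0True = "numeric", ratio = "numeric",
                   pOneTailed = "numeric", significant = "logical"))

setValidity("AcquisitionCostResult", function(object) {
    msg <- NULL
    if (any(object@tPred <= 0) || any(object@t0True <= 0))
        msg <- c(msg, "densities must be > 0")
    if (object@ratio <= 0) msg <- c(msg, "'ratio' must be > 0")
    if (isTRUE(object@significant) &&
        (!is.finite(object@pOneTailed) || object@pOneTailed >= 0.05 ||
         object@ratio >= 1))
        msg <- c(msg, "'significant' requires p < 0.05 and ratio < 1")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## ModelParams
## ---------------------------------------------------------------------------

#' Rate constants of the three-population conjugation model
#'
#' Populations are normalized to a shared carrying capacity (so densities are
#' dimensionless fractions of capacity): plasmid-free cells S0, de novo
#' transconjugants SD and adapted transconjugants SA. S0 grows at
#' \eqn{\alpha\mu}, SD at \eqn{\rho\mu}, SA at \eqn{\mu}. Conjugation between
#' S0 and SA creates SD at rate \eqn{\eta}; SD matures into SA at rate
#' \eqn{\beta}; SA loses the plasmid at segregation rate \eqn{\kappa}; all
#' pools wash out at the continuous dilution rate D.
#'
#' @slot mu numeric(1), adapted maximal growth rate (1/h); > 0.
#' @slot alpha numeric(1), plasmid-free growth scalar; > 1 means the plasmid
#'   is costly.
#' @slot rho numeric(1), de novo growth scalar in [0, 1].
#' @slot beta numeric(1), de novo to adapted transition rate (1/h); >= 0.
#' @slot eta numeric(1), conjugation efficiency (1/h per normalized
#'   density); >= 0.
#' @slot kappa numeric(1), segregation-loss rate (1/h); >= 0.
#' @slot dilution numeric(1), continuous dilution rate D (1/h); >= 0.
#'
#' @examples
#' ModelParams(mu = 0.8, alpha = 1.2, rho = 0, beta = 0.01, eta = 0.1)
#' @export
setClass("ModelParams",
    representation(mu = "numeric", alpha = "numeric", rho = "numeric",
                   beta = "numeric", eta = "numeric", kappa = "numeric",
                   dilution = "numeric"))

setValidity("ModelParams", function(object) {
    msg <- NULL
    if (object@mu <= 0) msg <- c(msg, "'mu' must be > 0")
    if (object@alpha <= 0) msg <- c(msg, "'alpha' must be > 0")
    if (object@rho < 0 || object@rho > 1) msg <- c(msg, "'rho' must be in [0,1]")
    for (s in c("beta", "eta", "kappa", "dilution"))
        if (slot(object, s) < 0)
            msg <- c(msg, sprintf("'%s' must be >= 0", s))
    if (is.null(msg)) TRUE else msg
})

#' @rdname ModelParams-class
#' @param mu,alpha,rho,beta,eta,kappa,dilution see slots.
#' @export
ModelParams <- function(mu = 0.8, alpha = 1, rho = 0, beta = 0.01,
                        eta = 0, kappa = 0, dilution = 0) {
    new("ModelParams", mu = as.numeric(mu), alpha = as.numeric(alpha),
        rho = as.numeric(rho), beta = as.numeric(beta),
        eta = as.numeric(eta), kappa = as.numeric(kappa),
        dilution = as.numeric(dilution))
}

## ---------------------------------------------------------------------------
## Trajectory
## ---------------------------------------------------------------------------

#' Simulated time course of the three-population model
#'
#' @slot times numeric, hours.
#' @slot s0,sd,sa numeric, normalized densities (fractions of carrying
#'   capacity) of plasmid-free, de novo and adapted pools.
#' @slot params the \linkS4class{ModelParams} used for the run.
#' @export
setClass("Trajectory",
    representation(times = "numeric", s0 = "numeric", sd = "numeric",
                   sa = "numeric", params = "ModelParams"))

setValidity("Trajectory", function(object) {
    n <- length(object@times)
    msg <- NULL
    if (length(object@s0) != n || length(object@sd) != n ||
        length(object@sa) != n)
        msg <- c(msg, "component lengths must match 'times'")
    if (n > 0 && min(object@s0, object@sd, object@sa) < -1e-9)
        msg <- c(msg, "state components must be >= -1e-9")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## SerialTransferResult
## ---------------------------------------------------------------------------

#' Daily plasmid fractions from a serial-transfer simulation
#'
#' @slot day integer vector 1..n.
#' @slot plasmidFraction numeric, S1/(S0+S1) at the end of each 24-h batch
#'   (before dilution), where S1 = SD + SA.
#' @slot endState matrix (days x 3, columns s0/sd/sa), end-of-batch states.
#' @slot truncated logical(1), TRUE when the run stopped early because the
#'   total population went extinct.
#' @export
setClass("SerialTransferResult",
    representation(day = "integer", plasmidFraction = "numeric",
                   endState = "matrix", truncated = "logical"))

setValidity("SerialTransferResult", function(object) {
    f <- object@plasmidFraction
    if (any(f < -1e-12 | f > 1 + 1e-12, na.rm = TRUE))
        return("plasmid fractions must lie in [0,1]")
    TRUE
})

## ---------------------------------------------------------------------------
## FitResult
## ---------------------------------------------------------------------------

#' Fitted transition-rate parameters
#'
#' @slot betaHat numeric(1), fitted de novo to adapted transition rate (1/h).
#' @slot rhoHat numeric(1), de novo growth scalar (fitted or fixed input).
#' @slot objective numeric(1), final sum of squared residuals.
#' @slot converged logical(1).
#' @slot initGuess named numeric, the initial parameter guesses used.
#' @export
setClass("FitResult",
    representation(betaHat = "numeric", rhoHat = "numeric",
                   objective = "numeric", converged = "logical",
                   initGuess = "numeric"))

setValidity("FitResult", function(object) {
    msg <- NULL
    if (object@betaHat < 0) msg <- c(msg, "'betaHat' must be >= 0")
    if (object@rhoHat < 0 || object@rhoHat > 1)
        msg <- c(msg, "'rhoHat' must be in [0,1]")
    if (is.finite(object@objective) && object@objective < 0)
        msg <- c(msg, "'objective' must be >= 0")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## BoundaryMap
## ---------------------------------------------------------------------------

#' Steady-state growth-deficit classification over an (alpha, beta) grid
#'
#' For each fitness cost alpha and transition rate beta the steady-state
#' observed transconjugant growth rate is compared with the adapted maximum;
#' cells with \eqn{\mu_{obs}/\mu} below the threshold are classified as
#' regions where the acquisition cost matters.
#'
#' @slot alphaGrid,betaGrid numeric grids (beta log-spaced by convention).
#' @slot eta numeric(1), conjugation efficiency used for the map.
#' @slot threshold numeric(1) in (0, 1), default 0.98.
#' @slot ratio matrix alpha x beta of mu_obs/mu; NA where the plasmid went
#'   extinct.
#' @slot belowThreshold logical matrix, TRUE iff ratio < threshold
#'   (extinct cells are FALSE and flagged in 'extinct').
#' @slot extinct logical matrix.
#' @export
setClass("BoundaryMap",
    representation(alphaGrid = "numeric", betaGrid = "numeric",
                   eta = "numeric", threshold = "numeric",
                   ratio = "matrix", belowThreshold = "matrix",
                   extinct = "matrix"))

setValidity("BoundaryMap", function(object) {
    msg <- NULL
    if (object@threshold <= 0 || object@threshold >= 1)
        msg <- c(msg, "'threshold' must be in (0,1)")
    r <- object@ratio
    if (any(r[is.finite(r)] <= 0 | r[is.finite(r)] > 1 + 1e-6))
        msg <- c(msg, "'ratio' entries must be in (0, 1]")
    ok <- is.finite(r)
    if (any(object@belowThreshold[ok] != (r[ok] < object@threshold)))
        msg <- c(msg, "'belowThreshold' inconsistent with 'ratio'")
    if (is.null(msg)) TRUE else msg
})
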