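#' @rdname accessors
#' @param x an acquicost object.
#' @export
setGeneric("growthRate", function(x) standardGeneric("growthRate"))

#' @rdname accessors
#' @export
setGeneric("lagTime", function(x) standardGeneric("lagTime"))

#' @rdname accessors
#' @export
setGeneric("plateTime", function(x) standardGeneric("plateTime"))

#' @rdname accessors
#' @export
setGeneric("odMatrix", function(x) standardGeneric("odMatrix"))

#' @rdname accessors
#' @export
setGeneric("wellMetadata", function(x) standardGeneric("wellMetadata"))

#' @rdname accessors
#' @param well character(1) well id.
#' @export
setGeneric("getCurve", function(x, well) standardGeneric("getCurve"))

#' @rdname accessors
#' @export
setGeneric("plasmidFraction", function(x) standardGeneric("plasmidFraction"))

#' @rdname accessors
#' @export
setGeneric("costRatio", function(x) standardGeneric("costRatio"))

## ---------------------------------------------------------------------------
## Accessor methods
## ---------------------------------------------------------------------------

#' Accessors for acquicost classes
#'
#' \code{growthRate} and \code{lagTime} return the estimated (or generating)
#' maximum specific growth rate (1/h) and lag time (h); \code{plateTime},
#' \code{odMatrix}, \code{wellMetadata} and \code{getCurve} access a
#' \linkS4class{PlateExperiment}; \code{plasmidFraction} returns daily
#' plasmid fractions of a \linkS4class{SerialTransferResult};
#' \code{costRatio} the T_pred/T0 ratio of an
#' \linkS4class{AcquisitionCostResult}.
#'
#' @name accessors
#' @return See individual descriptions.
NULL

#' @rdname accessors
setMethod("growthRate", "KineticParams", function(x) x@mu)
#' @rdname accessors
setMethod("growthRate", "GrowthFit", function(x) x@mu)
#' @rdname accessors
setMethod("lagTime", "KineticParams", function(x) x@lag)
#' @rdname accessors
setMethod("lagTime", "GrowthFit", function(x) x@lag)

#' @rdname accessors
setMethod("plateTime", "PlateExperiment", function(x)
    SummarizedExperiment::rowData(x)$time_h)

#' @rdname accessors
setMethod("odMatrix", "PlateExperiment", function(x)
    SummarizedExperiment::assay(x, "OD"))

#' @rdname accessors
setMethod("wellMetadata", "PlateExperiment", function(x) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cbind(well = rownames(cd), cd, row.names = NULL)
})

#' @rdname accessors
setMethod("getCurve", "PlateExperiment", function(x, well) {
    if (!well %in% colnames(x))
        stop("well '", well, "' not found on the plate")
    GrowthCurve(time = plateTime(x), od = odMatrix(x)[, well],
                wellId = well)
})

#' @rdname accessors
setMethod("plasmidFraction", "SerialTransferResult",
          function(x) x@plasmidFraction)

#' @rdname accessors
setMethod("costRatio", "AcquisitionCostResult", function(x) x@ratio)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "KineticParams", function(object) {
    cat(sprintf(
        "KineticParams: mu = %.4g /h, lag = %.4g h, y0 = %.4g, amplitude = %.4g\n",
        object@mu, object@lag, object@y0, object@amplitude))
})

setMethod("show", "GrowthFit", function(object) {
    cat(sprintf(
        "GrowthFit [%s]%s: mu = %.4g /h, lag = %.4g h, amplitude = %.4g, rss = %.3g\n",
        object@method, if (object@converged) "" else " (not converged)",
        object@mu, object@lag, object@amplitude, object@rss))
})

setMethod("show", "StandardCurve", function(object) {
    cat(sprintf(
        "StandardCurve: t* = %.4g %+.4g ln(T0)  (T* = %.4g OD, r2 = %.4f, n = %d)\n",
        object@intercept, object@slope, object@thresholdOd, object@r2,
        object@nPoints))
    cat(sprintf("  built over T0 in [%.3g, %.3g] CFU\n",
                object@t0Range[1], object@t0Range[2]))
})

setMethod("show", "AcquisitionCostResult", function(object) {
    cat(sprintf(
        "AcquisitionCostResult: T_pred/T0 = %.4g (n = %d), one-tailed p = %.4g%s\n",
        object@ratio, length(object@tPred), object@pOneTailed,
        if (isTRUE(object@significant)) " *" else ""))
})

setMethod("show", "ModelParams", function(object) {
    cat(sprintf(
        "ModelParams: mu=%.3g alpha=%.3g rho=%.3g beta=%.3g eta=%.3g kappa=%.3g D=%.3g\n",
        object@mu, object@alpha, object@rho, object@beta, object@eta,
        object@kappa, object@dilution))
})

setMethod("show", "Trajectory", function(object) {
    n <- length(object@times)
    cat(sprintf("Trajectory: %d timepoints over [%.3g, %.3g] h\n",
                n, object@times[1], object@times[n]))
    cat(sprintf("  final state: s0=%.4g sd=%.4g sa=%.4g (s1=%.4g)\n",
                object@s0[n], object@sd[n], object@sa[n],
                object@sd[n] + object@sa[n]))
})

setMethod("show", "SerialTransferResult", function(object) {
    cat(sprintf("SerialTransferResult: %d days%s\n", length(object@day),
                if (object@truncated) " (truncated: extinction)" else ""))
    cat("  plasmid fraction: ",
        paste(sprintf("%.3f", utils::head(object@plasmidFraction, 8)),
              collapse = " "),
        if (length(object@day) > 8) " ..." else "", "\n", sep = "")
})

setMethod("show", "FitResult", function(object) {
    cat(sprintf(
        "FitResult: beta = %.4g /h, rho = %.3g, SSR = %.4g%s\n",
        object@betaHat, object@rhoHat, object@objective,
        if (object@converged) "" else " (not converged)"))
})

setMethod("show", "BoundaryMap", function(object) {
    cat(sprintf(
        "BoundaryMap: %d x %d grid, eta = %.3g, threshold = %.3g\n",
        length(object@alphaGrid), length(object@betaGrid), object@eta,
        object@threshold))
    cat(sprintf("  %d cells below threshold, %d extinct\n",
                sum(object@belowThreshold, na.rm = TRUE),
                sum(object@extinct)))
})

## ---------------------------------------------------------------------------
## as.data.frame for Trajectory / SerialTransferResult
## ---------------------------------------------------------------------------

#' Coerce a Trajectory to a tidy data.frame
#'
#' Columns: time, s0, sd, sa, s1 (= sd + sa) and mu_obs, the
#' abundance-weighted transconjugant growth rate (NA where sd + sa = 0).
#'
#' @param x a \linkS4class{Trajectory}.
#' @param row.names,optional,... ignored (signature compatibility).
#' @method as.data.frame Trajectory
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
    s1 <- x@sd + x@sa
    p <- x@params
    mu_obs <- ifelse(s1 > 0, (x@sd * p@rho * p@mu + x@sa * p@mu) / s1,
                     NA_real_)
    data.frame(time = x@times, s0 = x@s0, sd = x@sd, sa = x@sa,
               s1 = s1, mu_obs = mu_obs)
}
setMethod("as.data.frame", "Trajectory", as.data.frame.Trajectory)

#' @rdname as.data.frame.Trajectory
#' @method as.data.frame SerialTransferResult
#' @export
as.data.frame.SerialTransferResult <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
    data.frame(day = x@day, plasmid_fraction = x@plasmidFraction,
               s0 = x@endState[, "s0"], sd = x@endState[, "sd"],
               sa = x@endState[, "sa"])
}
setMethod("as.data.frame", "SerialTransferResult",
          as.data.frame.SerialTransferResult)
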