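## Time-to-threshold standard curve and the acquisition-cost metric.
##
## During exponential growth ln T(t) = ln T0 + mu (t - lambda), so the time
## t* to reach a fixed threshold density T* is linear in ln T0 with slope
## -1/mu. A standard curve built from adapted-transconjugant dilution wells
## therefore predicts an unknown initial density (T_pred) from an observed
## t*; for de novo wells, T_pred/T0 < 1 quantifies the acquisition cost.

#' Experiment-wide threshold density
#'
#' Half of the maximum background-subtracted OD across all non-blank wells
#' of the experiment; one threshold per experiment, not per well, which
#' keeps t* comparisons within the shared exponential phase.
#'
#' @param plate a \linkS4class{PlateExperiment}.
#' @param blank scalar blank OD, a blank-well curve, or NULL to use the
#'   plate's blank wells (see \code{\link{fitGrowthPlate}}).
#' @param frac threshold as a fraction of the maximum (default 0.5).
#' @return threshold OD (background-subtracted scale).
#' @export
selectThreshold <- function(plate, blank = NULL, frac = 0.5) {
    blank <- .resolveBlank(plate, blank)
    md <- wellMetadata(plate)
    keep <- is.na(md$role) | md$role != "blank"
    if (!any(keep)) stop("no non-blank wells on the plate")
    m <- max(odMatrix(plate)[, md$well[keep], drop = FALSE] - blank)
    if (m <= 0) stop("no growth signal above the blank")
    frac * m
}

#' Time to reach a threshold density
#'
#' First time a background-subtracted curve reaches the threshold and stays
#' at or above it for at least two consecutive samples (a guard against
#' single-sample noise spikes), with linear interpolation between the
#' bracketing samples.
#'
#' @param curve a background-subtracted \linkS4class{GrowthCurve}.
#' @param thresholdOd threshold on the same OD scale.
#' @return t* in hours.
#' @examples
#' cur <- GrowthCurve(time = 0:24, od = 2e-6 * exp(0.8 * (0:24)),
#'                    backgroundSubtracted = TRUE)
#' timeToThreshold(cur, 0.05)
#' log(0.05 / 2e-6) / 0.8
#' @export
timeToThreshold <- function(curve, thresholdOd) {
    if (!isTRUE(curve@backgroundSubtracted))
        stop("curve must be background-subtracted")
    od <- curve@od
    t <- curve@time
    n <- length(od)
    above <- od >= thresholdOd
    runStart <- which(above[-n] & above[-1])
    if (length(runStart) == 0) stop("no crossing: curve never sustains the threshold")
    i <- runStart[1]
    ## last sub-threshold sample before the sustained run
    below <- which(od[seq_len(i)] < thresholdOd)
    if (length(below) == 0) stop("pre-saturated: curve starts above the threshold")
    j <- max(below)
    t[j] + (thresholdOd - od[j]) / (od[j + 1] - od[j]) * (t[j + 1] - t[j])
}

#' Build a standard curve from adapted dilution wells
#'
#' Ordinary least-squares regression of t* on \eqn{\ln T_0} (t* carries the
#' measurement noise; the T0s come from controlled dilutions). Inverted by
#' \code{\link{predictInitialDensity}} for prediction.
#'
#' @param tStar numeric vector of times-to-threshold (h).
#' @param trueT0 numeric vector of matching initial densities (CFU); at
#'   least two distinct values.
#' @param thresholdOd the threshold used to measure the t* values.
#' @return a \linkS4class{StandardCurve}.
#' @export
buildStandardCurve <- function(tStar, trueT0, thresholdOd) {
    ok <- is.finite(tStar) & is.finite(trueT0)
    tStar <- tStar[ok]; trueT0 <- trueT0[ok]
    if (length(tStar) < 2) stop("need at least 2 (t*, T0) pairs")
    if (length(unique(trueT0)) < 2)
        stop("degenerate design: all T0 values identical")
    fit <- lm(tStar ~ log(trueT0))
    cf <- coef(fit)
    slope <- unname(cf[2])
    if (slope >= 0)
        stop("standard curve slope must be negative (t* decreasing in T0)")
    new("StandardCurve", slope = slope, intercept = unname(cf[1]),
        thresholdOd = thresholdOd, r2 = summary(fit)$r.squared,
        nPoints = length(tStar), t0Range = range(trueT0))
}

#' Predict an initial density from a time-to-threshold
#'
#' Inverts the standard curve: \eqn{T_{pred} = \exp((t^* -
#' \mathrm{intercept})/\mathrm{slope})}. Warns (does not fail) when the
#' prediction lies outside the density range the curve was built over.
#'
#' @param std a \linkS4class{StandardCurve}.
#' @param tStar observed time(s)-to-threshold (h).
#' @return predicted initial density (CFU), vectorized over tStar.
#' @export
predictInitialDensity <- function(std, tStar) {
    tpred <- exp((tStar - std@intercept) / std@slope)
    out <- tpred < std@t0Range[1] | tpred > std@t0Range[2]
    if (any(out, na.rm = TRUE))
        warning(sum(out, na.rm = TRUE),
                " prediction(s) outside the standard curve's T0 range ",
                "(extrapolation)")
    tpred
}

#' Quantify the acquisition cost of a set of de novo wells
#'
#' Per-replicate predicted initial densities from the standard curve, the
#' cost ratio mean(T_pred)/mean(T0), and a one-tailed Welch t-test on log10
#' densities (H1: T_pred < T0). Wells whose t* is NA (e.g. excluded for
#' never crossing the threshold) are dropped with a warning.
#'
#' @param std a \linkS4class{StandardCurve}.
#' @param tStar times-to-threshold of the de novo wells (h); may contain NA.
#' @param trueT0 measured true initial densities (CFU), recycled if scalar.
#' @return an \linkS4class{AcquisitionCostResult}.
#' @export
acquisitionCost <- function(std, tStar, trueT0) {
    if (length(trueT0) == 1) trueT0 <- rep(trueT0, length(tStar))
    stopifnot(length(trueT0) == length(tStar))
    ok <- is.finite(tStar)
    if (!all(ok)) {
        warning(sum(!ok), " well(s) excluded (no threshold crossing)")
        tStar <- tStar[ok]; trueT0 <- trueT0[ok]
    }
    if (length(tStar) == 0) stop("all wells failed to cross the threshold")
    tPred <- suppressWarnings(predictInitialDensity(std, tStar))
    ratio <- mean(tPred) / mean(trueT0)
    p <- NA_real_
    if (length(tPred) >= 2) {
        p <- tryCatch(
            t.test(log10(tPred), log10(trueT0), alternative = "less",
                   var.equal = FALSE)$p.value,
            error = function(e) NA_real_)
    }
    new("AcquisitionCostResult", tPred = tPred, t0True = trueT0,
        ratio = ratio, pOneTailed = p,
        significant = isTRUE(is.finite(p) && p < 0.05 && ratio < 1))
}

#' Full acquisition-cost pipeline on a combined plate
#'
#' Preprocesses every well against the blank, selects the 50%-of-max
#' threshold, measures t* for adapted and de novo wells, builds the
#' standard curve from the adapted wells' true T0s, and quantifies the
#' de novo acquisition cost.
#'
#' @param plate a \linkS4class{PlateExperiment} containing adapted-role
#'   wells (with true_T0_cfu metadata) and de_novo-role wells.
#' @param blank scalar blank OD, blank-well curve, or NULL (plate blanks).
#' @param thresholdFrac threshold as a fraction of maximum OD.
#' @return list with elements \code{standardCurve}, \code{cost},
#'   \code{threshold}, \code{tStar} (per-well data.frame).
#' @export
acquisitionCostFromPlate <- function(plate, blank = NULL,
                                     thresholdFrac = 0.5) {
    blank <- .resolveBlank(plate, blank)
    thr <- selectThreshold(plate, blank, thresholdFrac)
    md <- wellMetadata(plate)
    tstarOf <- function(w) {
        tryCatch({
            pp <- preprocessCurve(getCurve(plate, w), blank)
            timeToThreshold(pp, thr)
        }, error = function(e) NA_real_)
    }
    md$t_star <- ifelse(!is.na(md$role) & md$role != "blank",
                        vapply(md$well, tstarOf, numeric(1)), NA_real_)
    ad <- md[!is.na(md$role) & md$role == "adapted", ]
    dn <- md[!is.na(md$role) & md$role == "de_novo", ]
    if (nrow(ad) == 0) stop("no adapted wells to build a standard curve")
    if (nrow(dn) == 0) stop("no de novo wells to evaluate")
    std <- buildStandardCurve(ad$t_star, ad$true_T0_cfu, thr)
    cost <- acquisitionCost(std, dn$t_star, dn$true_T0_cfu)
    list(standardCurve = std, cost = cost, threshold = thr, tStar = md)
}

#' Lag times normalized by inoculum and the adapted mean
#'
#' \eqn{v_i = \lambda_i T_{0,i} / \overline{\lambda}_{adapted}}: each lag is
#' multiplied by the well's true initial density and divided by the mean
#' adapted lag. The resulting unit (h CFU / h = CFU-weighted) is the
#' convention used for cross-condition lag comparisons; see the vignette
#' for discussion.
#'
#' @param lags numeric, per-replicate lag times (h).
#' @param trueT0 numeric, matching true initial densities.
#' @param adaptedLags numeric, lag times of the adapted reference group.
#' @return numeric vector of normalized values.
#' @export
normalizedLag <- function(lags, trueT0, adaptedLags) {
    if (length(adaptedLags) == 0) stop("empty adapted reference set")
    m <- mean(adaptedLags)
    if (!is.finite(m) || m <= 0) stop("mean adapted lag must be positive")
    lags * trueT0 / m
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' @param values numeric vector of measurements.
#' @param groups factor (or coercible) of group labels; at least two groups
#'   with at least two values each.
#' @return list with \code{omnibusP} (one-way ANOVA) and \code{pairwise}
#'   (matrix of Bonferroni-adjusted pairwise t-test p-values).
#' @examples
#' compareGroups(c(rnorm(5), rnorm(5, 3)), rep(c("a", "b"), each = 5))
#' @export
compareGroups <- function(values, groups) {
    groups <- factor(groups)
    if (nlevels(groups) < 2) stop("need at least 2 groups")
    if (any(table(groups) < 2)) stop("each group needs at least 2 values")
    if (all(tapply(values, groups, var) == 0) &&
        length(unique(tapply(values, groups, mean))) == 1) {
        ## degenerate all-identical case: aov would divide by zero variance
        lv <- nlevels(groups)
        pw <- matrix(1, lv - 1, lv - 1,
                     dimnames = list(levels(groups)[-1],
                                     levels(groups)[-lv]))
        pw[upper.tri(pw)] <- NA
        return(list(omnibusP = 1, pairwise = pw))
    }
    fit <- aov(values ~ groups)
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    pw <- pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                          pool.sd = FALSE)$p.value
    list(omnibusP = omnibus, pairwise = pw)
}
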