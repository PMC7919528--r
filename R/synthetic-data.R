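## Synthetic plate-data generator. Produces every input the analysis
## consumes -- OD600 plates, adapted dilution series, de novo wells, CFU spot
## counts and multi-day competition series -- with the statistical structure
## the downstream methods assume.

#' Default adapted-transconjugant kinetics
#'
#' Convenience constructor for realistic plate conditions: roughly 2,000
#' cells per well after a 1,000x dilution, growing at 0.8/h after a 2 h lag
#' to a stationary OD of ~0.5 (at the default OD-per-density conversion of
#' 1e-9 OD per CFU-per-well equivalent).
#'
#' @param t0 initial cells per well.
#' @param mu maximum specific growth rate, 1/h.
#' @param lag lag time, h.
#' @param saturationOd stationary-phase OD above background.
#' @param odPerDensity OD units per CFU-per-well equivalent.
#' @return a \linkS4class{KineticParams}.
#' @export
adaptedKinetics <- function(t0 = 2000, mu = 0.8, lag = 2,
                            saturationOd = 0.5, odPerDensity = 1e-9) {
    y0 <- log(t0)
    KineticParams(mu = mu, lag = lag, y0 = y0,
                  amplitude = log(saturationOd / odPerDensity) - y0)
}

## derived per-well seed so each well's noise stream is independent of the
## plate composition; documented derivation: seed + 7919 * index mod 2^31-1
.wellSeed <- function(seed, index) {
    as.integer((as.numeric(seed) + 7919 * index) %% 2147483647)
}

.checkSchedule <- function(schedule) {
    if (length(schedule) < 2 || any(diff(schedule) <= 0))
        stop("schedule must be strictly increasing")
    if (schedule[1] != 0)
        stop("schedule must start at 0")
}

#' Simulate one well's OD600 curve
#'
#' Baranyi-shaped growth converted to optical density:
#' \eqn{\mathrm{OD}(t) = c\,e^{y(t)} + \mathrm{blank} + \epsilon} with
#' \eqn{y(t)} the Baranyi solution for the supplied kinetics, \eqn{c} the
#' OD-per-density conversion and \eqn{\epsilon \sim N(0, \sigma_{od})}
#' i.i.d. Deterministic given the noise seed.
#'
#' @param kin a \linkS4class{KineticParams}.
#' @param schedule sampling grid in hours, strictly increasing from 0
#'   (default 15-min steps for 24 h, i.e. 97 samples).
#' @param noise a \linkS4class{NoiseSpec}.
#' @param odPerDensity OD units per CFU-per-well equivalent (> 0).
#' @param wellId label for the returned curve.
#' @return a \linkS4class{GrowthCurve} of raw (blank-containing) OD readings.
#' @examples
#' cur <- simulateGrowthCurve(adaptedKinetics(), noise = NoiseSpec(seed = 3L))
#' plot(cur@time, cur@od, type = "l")
#' @export
simulateGrowthCurve <- function(kin, schedule = seq(0, 24, by = 0.25),
                                noise = NoiseSpec(), odPerDensity = 1e-9,
                                wellId = "A1") {
    .checkSchedule(schedule)
    if (odPerDensity <= 0) stop("odPerDensity must be positive")
    y <- baranyiY(schedule, kin@mu, kin@lag, kin@y0, kin@amplitude)
    od <- odPerDensity * exp(y) + noise@blankOd
    if (noise@odSigma > 0) {
        set.seed(noise@seed)
        od <- od + rnorm(length(od), 0, noise@odSigma)
    }
    GrowthCurve(time = schedule, od = od, wellId = wellId)
}

## internal: build a PlateExperiment from a list of per-well specs
.assemblePlate <- function(schedule, specs, noise, odPerDensity) {
    nw <- length(specs)
    od <- matrix(NA_real_, nrow = length(schedule), ncol = nw)
    meta <- vector("list", nw)
    for (i in seq_len(nw)) {
        sp <- specs[[i]]
        wellNoise <- NoiseSpec(odSigma = noise@odSigma,
                               blankOd = noise@blankOd,
                               cfuPlatingVolume = noise@cfuPlatingVolume,
                               seed = .wellSeed(noise@seed, i))
        if (is.null(sp$kin)) {             # blank well: background only
            odw <- rep(noise@blankOd, length(schedule))
            if (noise@odSigma > 0) {
                set.seed(wellNoise@seed)
                odw <- odw + rnorm(length(odw), 0, noise@odSigma)
            }
        } else {
            odw <- simulateGrowthCurve(sp$kin, schedule, wellNoise,
                                       odPerDensity, sp$well)@od
        }
        od[, i] <- odw
        meta[[i]] <- data.frame(
            well = sp$well, role = sp$role,
            dilution_factor = sp$dilution_factor,
            true_T0_cfu = sp$true_T0_cfu, condition = sp$condition,
            replicate = sp$replicate)
    }
    colnames(od) <- vapply(specs, function(s) s$well, character(1))
    PlateExperiment(schedule, od, do.call(rbind, meta))
}

.wellIds <- function(n, offset = 0) {
    ids <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
    if (n + offset > length(ids))
        stop("a 96-well plate holds at most 96 wells")
    ids[(offset + 1):(offset + n)]
}

#' Simulate an adapted-transconjugant dilution series
#'
#' One (or \code{nReplicates}) adapted-role well(s) per dilution factor:
#' well \eqn{i} starts at \eqn{T_0 = \mathrm{baseT0}/f_i}, i.e. its
#' \eqn{y_0} is shifted by \eqn{-\ln f_i} while mu, lag and the saturation
#' density (carrying capacity) are shared across wells.
#'
#' @param kin adapted kinetics; \code{kin@y0} must equal \code{log(baseT0)}
#'   scaled, i.e. \code{baseT0} defaults to \code{exp(kin@y0)}.
#' @param baseT0 undiluted initial cells per well.
#' @param dilutionFactors numeric vector of factors >= 1 (e.g.
#'   \code{c(1e2, 1e4, 1e6)}).
#' @param schedule,noise,odPerDensity as in \code{\link{simulateGrowthCurve}}.
#' @param nReplicates technical replicates per factor (default 3).
#' @param condition label stored in the metadata.
#' @param nBlanks number of blank (background-only) wells appended.
#' @return a \linkS4class{PlateExperiment}.
#' @examples
#' plate <- simulateDilutionSeries(adaptedKinetics(t0 = 2e7), baseT0 = 2e7,
#'                                 dilutionFactors = c(1e2, 1e4, 1e6))
#' wellMetadata(plate)
#' @export
simulateDilutionSeries <- function(kin, baseT0 = exp(kin@y0),
                                   dilutionFactors = c(1e2, 1e4, 1e6),
                                   schedule = seq(0, 24, by = 0.25),
                                   noise = NoiseSpec(), odPerDensity = 1e-9,
                                   nReplicates = 3, condition = "standard",
                                   nBlanks = 0) {
    .checkSchedule(schedule)
    if (any(dilutionFactors < 1)) stop("dilution factors must be >= 1")
    saturation <- kin@y0 + kin@amplitude
    specs <- list()
    k <- 0
    for (i in seq_along(dilutionFactors)) {
        f <- dilutionFactors[i]
        t0 <- baseT0 / f
        y0 <- log(baseT0) - log(f)
        if (saturation - y0 <= 0)
            stop("dilution factor ", f, " dilutes below the model's capacity")
        for (r in seq_len(nReplicates)) {
            k <- k + 1
            specs[[k]] <- list(
                kin = KineticParams(kin@mu, kin@lag, y0, saturation - y0),
                well = NA, role = "adapted", dilution_factor = f,
                true_T0_cfu = t0, condition = condition, replicate = r)
        }
    }
    for (b in seq_len(nBlanks)) {
        k <- k + 1
        specs[[k]] <- list(kin = NULL, well = NA, role = "blank",
                           dilution_factor = NA_real_,
                           true_T0_cfu = NA_real_, condition = condition,
                           replicate = b)
    }
    ids <- .wellIds(length(specs))
    for (i in seq_along(specs)) specs[[i]]$well <- ids[i]
    .assemblePlate(schedule, specs, noise, odPerDensity)
}

#' Simulate de novo transconjugant wells
#'
#' De novo wells share the adapted kinetics except for the acquisition
#' effect: \eqn{\mu \leftarrow \mathrm{muScale}\cdot\mu} and
#' \eqn{\lambda \leftarrow \lambda + \mathrm{extraLag}}. The saturation
#' density is kept at the adapted carrying capacity.
#'
#' @param adaptedKin adapted \linkS4class{KineticParams} (its y0/amplitude
#'   define the shared saturation density).
#' @param muScale growth-rate scaling in (0, 1].
#' @param extraLag added lag in hours (>= 0).
#' @param trueT0 nominal initial cells per well.
#' @param nWells number of replicate wells.
#' @param schedule,noise,odPerDensity as in \code{\link{simulateGrowthCurve}}.
#' @param condition metadata label.
#' @param t0Cv coefficient of variation of the per-well inoculum (lognormal
#'   around \code{trueT0}; biological replicates are separate dilutions, so
#'   their true starting densities differ). The realized per-well value is
#'   recorded exactly in \code{true_T0_cfu} (experimentally it would be
#'   verified by CFU counts). Default 0 (identical inocula).
#' @return a \linkS4class{PlateExperiment} of de_novo-role wells.
#' @export
simulateDeNovoWells <- function(adaptedKin, muScale = 1, extraLag = 0,
                                trueT0 = 2000, nWells = 3,
                                schedule = seq(0, 24, by = 0.25),
                                noise = NoiseSpec(), odPerDensity = 1e-9,
                                condition = "de_novo", t0Cv = 0) {
    .checkSchedule(schedule)
    if (muScale <= 0 || muScale > 1) stop("muScale must be in (0, 1]")
    if (extraLag < 0) stop("extraLag must be >= 0")
    if (t0Cv < 0) stop("t0Cv must be >= 0")
    saturation <- adaptedKin@y0 + adaptedKin@amplitude
    t0s <- rep(trueT0, nWells)
    if (t0Cv > 0) {
        set.seed(.wellSeed(noise@seed, 999L))
        sdl <- sqrt(log(1 + t0Cv^2))
        t0s <- trueT0 * exp(rnorm(nWells, -sdl^2 / 2, sdl))
    }
    specs <- lapply(seq_len(nWells), function(r) {
        y0 <- log(t0s[r])
        if (saturation - y0 <= 0) stop("trueT0 exceeds the model's capacity")
        kin <- KineticParams(muScale * adaptedKin@mu,
                             adaptedKin@lag + extraLag, y0, saturation - y0)
        list(kin = kin, well = NA, role = "de_novo",
             dilution_factor = NA_real_, true_T0_cfu = t0s[r],
             condition = condition, replicate = r)
    })
    ids <- .wellIds(nWells)
    for (i in seq_along(specs)) specs[[i]]$well <- ids[i]
    .assemblePlate(schedule, specs, noise, odPerDensity)
}

#' Combine plates sharing a sampling grid into one experiment
#'
#' @param ... \linkS4class{PlateExperiment} objects with identical time
#'   grids. Well ids are made unique by suffixing when they collide.
#' @return a single \linkS4class{PlateExperiment}.
#' @export
combinePlates <- function(...) {
    plates <- list(...)
    stopifnot(length(plates) >= 1)
    tt <- plateTime(plates[[1]])
    for (p in plates[-1])
        if (!isTRUE(all.equal(plateTime(p), tt)))
            stop("plates must share one sampling grid")
    ods <- lapply(plates, odMatrix)
    mds <- lapply(plates, wellMetadata)
    od <- do.call(cbind, ods)
    md <- do.call(rbind, mds)
    if (anyDuplicated(colnames(od))) {
        colnames(od) <- make.unique(colnames(od), sep = "_")
        md$well <- colnames(od)
    }
    PlateExperiment(tt, od, md)
}

#' Simulate a complete acquisition-cost experiment on one plate
#'
#' Convenience composition of the standard-curve and de novo generators:
#' an adapted-transconjugant dilution series (default: the seven 10-fold
#' dilution factors, technical triplicates) plus a set of de novo wells
#' carrying the acquisition effect, on a shared sampling grid. Feed the
#' result to \code{\link{acquisitionCostFromPlate}}.
#'
#' @param kin adapted \linkS4class{KineticParams}; its y0 is the log of
#'   \code{baseT0}.
#' @param muScale,extraLag acquisition effect of the de novo wells.
#' @param baseT0 undiluted adapted inoculum (cells per well).
#' @param dilutionFactors standard-curve dilution factors.
#' @param deNovoT0 nominal de novo inoculum (cells per well).
#' @param nDeNovo number of de novo replicate wells.
#' @param t0Cv biological-replicate inoculum CV of the de novo wells.
#' @param hours duration of the sampling grid (15-min steps).
#' @param noise a \linkS4class{NoiseSpec}.
#' @param nStdReplicates technical replicates per dilution factor.
#' @return a combined \linkS4class{PlateExperiment}.
#' @export
simulateCostPlate <- function(kin, muScale = 1, extraLag = 0,
                              baseT0 = exp(kin@y0),
                              dilutionFactors = 10^(0:6),
                              deNovoT0 = 2000, nDeNovo = 4, t0Cv = 0.1,
                              hours = 24, noise = NoiseSpec(),
                              nStdReplicates = 3) {
    sch <- seq(0, hours, by = 0.25)
    std <- simulateDilutionSeries(kin, baseT0 = baseT0,
                                  dilutionFactors = dilutionFactors,
                                  schedule = sch, noise = noise,
                                  nReplicates = nStdReplicates)
    dn <- simulateDeNovoWells(kin, muScale = muScale, extraLag = extraLag,
                              trueT0 = deNovoT0, nWells = nDeNovo,
                              schedule = sch,
                              noise = NoiseSpec(
                                  odSigma = noise@odSigma,
                                  blankOd = noise@blankOd,
                                  cfuPlatingVolume = noise@cfuPlatingVolume,
                                  seed = .wellSeed(noise@seed, 100000L)),
                              t0Cv = t0Cv)
    combinePlates(std, dn)
}

#' Poisson CFU spot counts
#'
#' Colony counts from plating a diluted sample: draws from
#' \eqn{\mathrm{Poisson}(\mathrm{density}\cdot\mathrm{volume}/
#' \mathrm{dilutionFactor})}. The default 0.01 ml volume corresponds to a
#' 10 ul spot.
#'
#' @param density cells per ml (>= 0).
#' @param volume plated volume in ml (> 0).
#' @param dilutionFactor dilution applied before plating (>= 1).
#' @param seed integer RNG seed; identical seeds give identical counts.
#' @param n number of independent draws.
#' @return integer vector of colony counts.
#' @examples
#' sampleCfu(1e5, volume = 0.01, dilutionFactor = 1, seed = 5L)
#' @export
sampleCfu <- function(density, volume = 0.01, dilutionFactor = 1,
                      seed = 1L, n = 1L) {
    if (density < 0) stop("density must be >= 0")
    if (volume <= 0) stop("volume must be > 0")
    if (dilutionFactor < 1) stop("dilutionFactor must be >= 1")
    set.seed(as.integer(seed))
    rpois(n, density * volume / dilutionFactor)
}

#' Simulate an observed long-term competition series
#'
#' Runs \code{\link{serialTransfer}} and, when \code{cfuNoise} is supplied,
#' converts each day's plasmid-carrying and plasmid-free densities to CFU/ml,
#' Poisson-samples spot counts for both, and reports the observed plasmid
#' fraction \eqn{n_1/(n_0+n_1)}. Without \code{cfuNoise} the observed series
#' equals the model output exactly.
#'
#' @param params a \linkS4class{ModelParams} with \code{dilution = 0}
#'   (batch growth between transfers).
#' @param initFractionPlasmid starting plasmid fraction (1:1 mix = 0.5).
#' @param days number of daily transfers (>= 1).
#' @param dilutionPerDay fold dilution at each transfer (default 10,000x).
#' @param cfuNoise \code{NULL} (noiseless) or a \linkS4class{NoiseSpec}
#'   supplying the plating volume and seed.
#' @param cellsPerUnit CFU/ml corresponding to one unit of normalized
#'   density (carrying capacity), default 1e9.
#' @param cfuDilutionFactor dilution before spotting, chosen to give
#'   countable colonies.
#' @param initialTotal starting total normalized density.
#' @return data.frame with columns day, fraction_true, fraction_observed.
#' @export
simulateCompetitionSeries <- function(params, initFractionPlasmid = 0.5,
                                      days = 14, dilutionPerDay = 1e4,
                                      cfuNoise = NULL, cellsPerUnit = 1e9,
                                      cfuDilutionFactor = 1e3,
                                      initialTotal = 1e-4) {
    if (days < 1) stop("days must be >= 1")
    st <- serialTransfer(params, initFractionPlasmid, days, dilutionPerDay,
                         initialTotal = initialTotal)
    trueFrac <- st@plasmidFraction
    obs <- trueFrac
    if (!is.null(cfuNoise)) {
        vol <- cfuNoise@cfuPlatingVolume
        set.seed(cfuNoise@seed)
        s1 <- st@endState[, "sd"] + st@endState[, "sa"]
        s0 <- st@endState[, "s0"]
        n1 <- rpois(length(s1), s1 * cellsPerUnit * vol / cfuDilutionFactor)
        n0 <- rpois(length(s0), s0 * cellsPerUnit * vol / cfuDilutionFactor)
        obs <- ifelse(n0 + n1 > 0, n1 / (n0 + n1), NA_real_)
    }
    data.frame(day = st@day, fraction_true = trueFrac,
               fraction_observed = obs)
}
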