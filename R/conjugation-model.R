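## Three-population conjugation model: plasmid-free cells (s0), de novo
## transconjugants (sd) and adapted transconjugants (sa), all normalized to
## a shared carrying capacity of 1.

#' Right-hand side of the three-population conjugation model
#'
#' \deqn{\dot S^0 = \alpha\mu S^0 (1 - S^0 - S^A - S^D) - \eta S^0 S^A
#'   + \kappa S^A - D S^0}
#' \deqn{\dot S^D = \rho\mu S^D (1 - S^0 - S^A - S^D) + \eta S^0 S^A
#'   - \beta S^D - D S^D}
#' \deqn{\dot S^A = \mu S^A (1 - S^0 - S^A - S^D) + \beta S^D
#'   - \kappa S^A - D S^A}
#'
#' Conjugation and plasmid loss act on the adapted pool only (the de novo
#' pool is assumed not to conjugate or segregate); setting
#' \code{deNovoConjugates = TRUE} lets the de novo pool donate as well
#' (transfer term \eqn{\eta S^0 (S^A + S^D)}) as a robustness variant.
#'
#' @param state numeric(3): s0, sd, sa.
#' @param params a \linkS4class{ModelParams}.
#' @param deNovoConjugates logical(1), see above.
#' @return numeric(3) of derivatives (1/h).
#' @examples
#' conjugationDerivatives(c(0.4, 0.01, 0.1),
#'                        ModelParams(mu = 0.8, alpha = 1.2, eta = 0.1))
#' @export
conjugationDerivatives <- function(state, params, deNovoConjugates = FALSE) {
    s0 <- state[1]; sd <- state[2]; sa <- state[3]
    free <- 1 - s0 - sd - sa
    donors <- if (deNovoConjugates) sa + sd else sa
    conj <- params@eta * s0 * donors
    ds0 <- params@alpha * params@mu * s0 * free - conj +
        params@kappa * sa - params@dilution * s0
    dsd <- params@rho * params@mu * sd * free + conj -
        params@beta * sd - params@dilution * sd
    dsa <- params@mu * sa * free + params@beta * sd -
        params@kappa * sa - params@dilution * sa
    c(ds0, dsd, dsa)
}

.rhs <- function(t, y, parms) {
    list(conjugationDerivatives(y, parms$p, parms$dnc))
}

#' Integrate the three-population model
#'
#' Adaptive stiff-capable integration (lsoda) at rtol 1e-8 / atol 1e-10.
#' Tiny negative excursions (integrator slack) are clipped to zero post hoc.
#'
#' @param params a \linkS4class{ModelParams}.
#' @param init numeric(3) initial state (s0, sd, sa), nonnegative with
#'   total <= 1.
#' @param times output time grid in hours (first element is the start).
#' @param deNovoConjugates see \code{\link{conjugationDerivatives}}.
#' @param rtol,atol integrator tolerances.
#' @return a \linkS4class{Trajectory}.
#' @examples
#' tr <- simulateConjugation(ModelParams(mu = 0.8), c(0, 0, 0.01),
#'                           seq(0, 24, 0.5))
#' tail(as.data.frame(tr))
#' @export
simulateConjugation <- function(params, init, times,
                                deNovoConjugates = FALSE,
                                rtol = 1e-8, atol = 1e-10) {
    stopifnot(length(init) == 3)
    if (any(init < 0)) stop("initial state must be nonnegative")
    if (sum(init) > 1 + 1e-9) stop("initial total must be <= 1")
    y0 <- c(s0 = unname(init[1]), sd = unname(init[2]), sa = unname(init[3]))
    out <- deSolve::ode(y = y0, times = times, func = .rhs,
                        parms = list(p = params, dnc = deNovoConjugates),
                        method = "lsoda", rtol = rtol, atol = atol)
    if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0)
        stop("integrator failure: istate = ", attr(out, "istate")[1])
    st <- out[, c("s0", "sd", "sa"), drop = FALSE]
    st[st < 0 & st > -1e-7] <- 0
    new("Trajectory", times = out[, "time"], s0 = st[, "s0"],
        sd = st[, "sd"], sa = st[, "sa"], params = params)
}

#' Integrate the original two-population model
#'
#' The reduced model with a single plasmid-carrying pool S1:
#' \deqn{\dot S^0 = \alpha\mu S^0(1 - S^0 - S^1) - \eta S^0 S^1
#'   + \kappa S^1 - D S^0}
#' \deqn{\dot S^1 = \mu S^1(1 - S^0 - S^1) + \eta S^0 S^1
#'   - \kappa S^1 - D S^1}
#' It is the \eqn{\beta \to \infty} limit of the expanded model.
#'
#' @param params a \linkS4class{ModelParams}; rho and beta are ignored.
#' @param init numeric(2) initial (s0, s1).
#' @param times output grid in hours.
#' @param rtol,atol integrator tolerances.
#' @return data.frame with columns time, s0, s1.
#' @export
simulateOriginalModel <- function(params, init, times,
                                  rtol = 1e-8, atol = 1e-10) {
    stopifnot(length(init) == 2)
    if (any(init < 0)) stop("initial state must be nonnegative")
    rhs <- function(t, y, p) {
        s0 <- y[1]; s1 <- y[2]
        free <- 1 - s0 - s1
        conj <- p@eta * s0 * s1
        list(c(p@alpha * p@mu * s0 * free - conj + p@kappa * s1 -
                   p@dilution * s0,
               p@mu * s1 * free + conj - p@kappa * s1 - p@dilution * s1))
    }
    out <- deSolve::ode(y = c(s0 = unname(init[1]), s1 = unname(init[2])),
                        times = times, func = rhs, parms = params,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0)
        stop("integrator failure: istate = ", attr(out, "istate")[1])
    data.frame(time = out[, "time"], s0 = pmax(out[, "s0"], 0),
               s1 = pmax(out[, "s1"], 0))
}

#' Observed transconjugant growth rate
#'
#' Abundance-weighted mean growth rate of the combined transconjugant pool:
#' \deqn{\mu_{obs}(t) = \frac{S^D \rho\mu + S^A \mu}{S^D + S^A}.}
#' Timepoints with \eqn{S^D + S^A = 0} are reported as \code{NA}.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param params the \linkS4class{ModelParams}; defaults to the trajectory's
#'   own parameters.
#' @return numeric vector of mu_obs values (1/h).
#' @export
observedGrowthRate <- function(traj, params = traj@params) {
    s1 <- traj@sd + traj@sa
    if (all(s1 == 0)) stop("transconjugant pool is zero at all timepoints")
    ifelse(s1 > 0,
           (traj@sd * params@rho * params@mu + traj@sa * params@mu) / s1,
           NA_real_)
}

#' Steady-state observed growth rate under continuous dilution
#'
#' Integrates the model until the state changes by less than \code{tol} over
#' a 10 h window (or until \code{horizon}), then evaluates \eqn{\mu_{obs}}
#' at the final state. A nontrivial steady state requires turnover, so
#' \code{params@dilution} must be positive. A plasmid pool below
#' \code{extinctTol} at steady state is reported as extinct
#' (\code{muObs = NA}).
#'
#' @param params a \linkS4class{ModelParams} with \code{dilution > 0}.
#' @param init numeric(3) initial state.
#' @param tol convergence tolerance on the max state change per 10 h.
#' @param horizon maximum integration time (h).
#' @param extinctTol plasmid-extinction threshold on S1 (default 1e-8).
#' @return list with \code{muObs} (NA when extinct), \code{ratio}
#'   (muObs/mu), \code{state}, \code{extinct}, \code{converged},
#'   \code{time}.
#' @export
steadyStateGrowthRate <- function(params, init = c(0.05, 0, 0.05),
                                  tol = 1e-9, horizon = 5000,
                                  extinctTol = 1e-8) {
    if (params@dilution <= 0)
        stop("a nontrivial steady state requires dilution > 0")
    state <- c(s0 = unname(init[1]), sd = unname(init[2]),
               sa = unname(init[3]))
    tNow <- 0
    chunk <- 200
    converged <- FALSE
    while (tNow < horizon) {
        tEnd <- min(tNow + chunk, horizon)
        times <- seq(0, tEnd - tNow, by = 10)
        out <- deSolve::ode(y = state, times = times, func = .rhs,
                            parms = list(p = params, dnc = FALSE),
                            method = "lsoda", rtol = 1e-10, atol = 1e-12)
        st <- out[, c("s0", "sd", "sa"), drop = FALSE]
        dmax <- apply(abs(diff(st)), 1, max)
        hit <- which(dmax < tol)
        if (length(hit)) {
            state <- st[hit[1] + 1L, ]
            tNow <- tNow + times[hit[1] + 1L]
            converged <- TRUE
            break
        }
        state <- st[nrow(st), ]
        tNow <- tEnd
    }
    state <- pmax(state, 0)
    s1 <- state[["sd"]] + state[["sa"]]
    extinct <- s1 < extinctTol
    muObs <- if (extinct) NA_real_ else
        (state[["sd"]] * params@rho * params@mu +
         state[["sa"]] * params@mu) / s1
    list(muObs = muObs, ratio = muObs / params@mu, state = state,
         extinct = extinct, converged = converged, time = tNow)
}

#' Serial-transfer (daily batch dilution) simulation
#'
#' Repeats: integrate a 24 h batch (no continuous dilution), record the
#' plasmid fraction \eqn{S^1/(S^0+S^1)}, divide all pools by
#' \code{dilutionPerDay}, continue. The initial state is a mix of
#' plasmid-free and adapted cells (\eqn{S^D = 0}):
#' \eqn{S^A = f c}, \eqn{S^0 = (1-f) c} with \eqn{f} the initial plasmid
#' fraction and \eqn{c} the starting total.
#'
#' @param params a \linkS4class{ModelParams}; \code{dilution} must be 0
#'   (transfers are the only dilution).
#' @param initFractionPlasmid initial plasmid fraction f.
#' @param days number of daily batches (>= 1).
#' @param dilutionPerDay fold dilution between batches (> 1); default
#'   10,000x.
#' @param batchHours batch duration (default 24 h).
#' @param initialTotal starting total normalized density c (default 1e-4, a
#'   saturated culture after one 10,000x dilution).
#' @return a \linkS4class{SerialTransferResult}.
#' @examples
#' st <- serialTransfer(ModelParams(mu = 0.8, alpha = 1.2), days = 5)
#' plasmidFraction(st)
#' @export
serialTransfer <- function(params, initFractionPlasmid = 0.5, days = 14,
                           dilutionPerDay = 1e4, batchHours = 24,
                           initialTotal = 1e-4) {
    if (days < 1) stop("days must be >= 1")
    if (dilutionPerDay <= 1) stop("dilutionPerDay must be > 1")
    if (params@dilution != 0)
        stop("serial transfer assumes dilution = 0 within batches")
    f <- initFractionPlasmid
    stopifnot(f >= 0, f <= 1)
    state <- c(s0 = (1 - f) * initialTotal, sd = 0, sa = f * initialTotal)
    frac <- numeric(0)
    snap <- NULL
    truncated <- FALSE
    for (d in seq_len(days)) {
        tr <- simulateConjugation(params, state, c(0, batchHours))
        n <- length(tr@times)
        state <- c(s0 = tr@s0[n], sd = tr@sd[n], sa = tr@sa[n])
        tot <- sum(state)
        if (tot < 1e-15) { truncated <- TRUE; break }
        s1 <- state[["sd"]] + state[["sa"]]
        frac <- c(frac, s1 / tot)
        snap <- rbind(snap, state)
        state <- state / dilutionPerDay
    }
    rownames(snap) <- NULL
    colnames(snap) <- c("s0", "sd", "sa")
    new("SerialTransferResult", day = seq_along(frac),
        plasmidFraction = frac, endState = snap, truncated = truncated)
}
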