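# The inverse pipeline: raw trace -> ramps -> baselines -> folded fraction
# -> Tm -> van't Hoff regression, plus equilibrium diagnostics.

#' Split a time-ordered melting trace into monotone ramps
#'
#' Instrument traces record several consecutive temperature ramps (e.g.
#' 90-10-90-10 degC, giving cooling/heating/cooling). This splits the series
#' at direction reversals and returns one [MeltCurve-class] per monotone
#' segment. Segments shorter than `minPoints` are discarded with a warning.
#'
#' @param trace data.frame with columns `temperature` (degC) and `signal`,
#'   in recording order.
#' @param channel signal channel label attached to each curve.
#' @param meta metadata list attached to each curve.
#' @param minPoints minimum points per usable ramp (default 20).
#' @return list of [MeltCurve-class] objects in recording order.
#' @examples
#' tr <- data.frame(temperature = c(seq(50, 10, -0.5), seq(10.5, 50, 0.5)),
#'                  signal = 0)
#' length(splitRamps(tr))  # 2
#' @export
splitRamps <- function(trace, channel = "A260", meta = list(),
                       minPoints = 20L) {
    stopifnot(is.data.frame(trace),
              all(c("temperature", "signal") %in% names(trace)))
    tv <- as.numeric(trace$temperature)
    sv <- as.numeric(trace$signal)
    if (length(tv) < 2L) stop("trace has fewer than 2 points")
    d <- sign(diff(tv))
    if (all(d == 0))
        stop("temperature never changes: no monotone ramp in trace")
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    curves <- list()
    dropped <- 0L
    for (seg in seq_along(r$lengths)) {
        if (r$values[seg] == 0) { dropped <- dropped + 1L; next }
        idx <- starts[seg]:(ends[seg] + 1L)  # diffs i..j cover points i..j+1
        if (length(idx) < minPoints) { dropped <- dropped + 1L; next }
        curves[[length(curves) + 1L]] <- MeltCurve(
            tv[idx], sv[idx], channel = channel,
            direction = if (r$values[seg] > 0) "heating" else "cooling",
            meta = meta)
    }
    if (dropped > 0L)
        warning(dropped, " segment(s) discarded (non-monotone or shorter than ",
                minPoints, " points)")
    if (!length(curves))
        stop("no usable monotone ramp of at least ", minPoints, " points")
    curves
}

.evalLine <- function(line, tC) line[1L] * tC + line[2L]

#' Restrict a melting curve to a temperature interval
#'
#' Used to exclude a second, higher-melting transition (e.g. an adjacent
#' quadruplex) from duplex-only analysis: the curve is cut below the onset
#' of the second transition and analysed as a single two-state melt.
#'
#' @param curve a [MeltCurve-class].
#' @param tMin,tMax temperature bounds in degC (inclusive).
#' @return the trimmed [MeltCurve-class] (still >= 20 points).
#' @export
trimCurve <- function(curve, tMin = -Inf, tMax = Inf) {
    stopifnot(is(curve, "MeltCurve"))
    keep <- curve@temperature >= tMin & curve@temperature <= tMax
    if (sum(keep) < 20L)
        stop("trimming leaves fewer than 20 points")
    MeltCurve(curve@temperature[keep], curve@signal[keep],
              channel = curve@channel, direction = curve@direction,
              meta = curve@meta)
}

.fitLine <- function(tC, sv) {
    fit <- lm(sv ~ tC)
    c(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' Fit linear plateau baselines to a melting curve
#'
#' Ordinary least-squares lines over the lowest and highest `windowFrac`
#' fraction of the temperature span (default outer 15%), or over explicit
#' user-supplied windows. The low-temperature line is the folded (native)
#' plateau, the high-temperature line the unfolded plateau, regardless of
#' whether the channel is hyper- or hypochromic.
#'
#' @param curve a [MeltCurve-class].
#' @param windowFrac fraction of the temperature span per window, in
#'   (0, 0.4).
#' @param foldedWindow,unfoldedWindow optional explicit `c(lo, hi)`
#'   temperature windows (degC) overriding `windowFrac`.
#' @return a [BaselineFit-class].
#' @export
fitBaselines <- function(curve, windowFrac = 0.15,
                         foldedWindow = NULL, unfoldedWindow = NULL) {
    stopifnot(is(curve, "MeltCurve"))
    if (windowFrac <= 0 || windowFrac >= 0.4)
        stop("windowFrac must lie in (0, 0.4)")
    tC <- curve@temperature
    sv <- curve@signal
    lo <- min(tC); hi <- max(tC); span <- hi - lo
    if (is.null(foldedWindow)) foldedWindow <- c(lo, lo + windowFrac * span)
    if (is.null(unfoldedWindow)) unfoldedWindow <- c(hi - windowFrac * span, hi)
    iF <- tC >= foldedWindow[1L] & tC <= foldedWindow[2L]
    iU <- tC >= unfoldedWindow[1L] & tC <= unfoldedWindow[2L]
    if (sum(iF) < 3L || sum(iU) < 3L)
        stop("degenerate baseline window: fewer than 3 points")
    new("BaselineFit",
        folded = .fitLine(tC[iF], sv[iF]),
        unfolded = .fitLine(tC[iU], sv[iU]),
        foldedWindow = as.numeric(foldedWindow),
        unfoldedWindow = as.numeric(unfoldedWindow))
}

#' Folded fraction from a curve and its baselines
#'
#' \eqn{\theta(T) = (U(T) - s(T)) / (U(T) - F(T))} where F and U are the
#' folded and unfolded baselines. Because F is always the low-temperature
#' plateau, the same formula applies to hyperchromic (absorbance at 260 nm
#' rises on melting) and hypochromic channels (e.g. quadruplex melting at
#' 295 nm). Values are clipped to \[0, 1\].
#'
#' @param curve a [MeltCurve-class].
#' @param baselines a [BaselineFit-class] for that curve.
#' @return a [ThetaProfile-class].
#' @export
fractionFolded <- function(curve, baselines) {
    stopifnot(is(curve, "MeltCurve"), is(baselines, "BaselineFit"))
    tC <- curve@temperature
    U <- .evalLine(baselines@unfolded, tC)
    F0 <- .evalLine(baselines@folded, tC)
    den <- U - F0
    scale <- max(abs(curve@signal), abs(den), 1e-12)
    if (any(abs(den) < 1e-9 * scale) || !(all(den > 0) || all(den < 0)))
        stop("degenerate baselines: folded and unfolded lines coincide or cross within the curve range")
    ThetaProfile(tC, pmin(pmax((U - curve@signal) / den, 0), 1))
}

# Centered moving-window quadratic smoothing (Savitzky-Golay); identity for
# short profiles.
.smoothTheta <- function(theta, window = 11L) {
    window <- as.integer(window)
    if (window < 5L || length(theta) < window) return(theta)
    if (window %% 2L == 0L) window <- window + 1L
    pmin(pmax(signal::sgolayfilt(theta, p = 2, n = window), 0), 1)
}

#' Melting temperature from a folded-fraction profile
#'
#' `"crossing"`: linear interpolation of the first theta = 0.5 crossing in
#' the heating direction (ascending temperature), computed on the smoothed
#' profile; multiple crossings use the first, with a warning. `"derivative"`:
#' temperature of the extremum of d(theta)/dT on the smoothed profile, with
#' parabolic refinement between grid points.
#'
#' @param profile a [ThetaProfile-class].
#' @param method `"crossing"` (default) or `"derivative"`.
#' @param smoothWindow points in the centered moving quadratic smoother
#'   (default 11, suited to 0.25 degC grids); values below 5 disable
#'   smoothing.
#' @return melting temperature in degrees Celsius.
#' @export
meltingTemperature <- function(profile, method = c("crossing", "derivative"),
                               smoothWindow = 11L) {
    stopifnot(is(profile, "ThetaProfile"))
    method <- match.arg(method)
    ord <- order(profile@temperature)
    tC <- profile@temperature[ord]
    th <- .smoothTheta(profile@theta[ord], smoothWindow)
    if (identical(method, "derivative")) {
        dth <- diff(th) / diff(tC)
        tm <- (tC[-1L] + tC[-length(tC)]) / 2
        i <- which.max(abs(dth))
        if (i > 1L && i < length(dth)) {
            y <- abs(dth[(i - 1L):(i + 1L)])
            den <- y[1L] - 2 * y[2L] + y[3L]
            off <- if (abs(den) > 1e-15) 0.5 * (y[1L] - y[3L]) / den else 0
            return(tm[i] + off * (tm[i + 1L] - tm[i]))
        }
        return(tm[i])
    }
    d <- th - 0.5
    if (all(d > 0) || all(d < 0))
        stop("no melting transition: theta does not cross 0.5")
    exact <- which(d == 0)
    cross <- which(d[-length(d)] * d[-1L] < 0)
    nCross <- length(exact) + length(cross)
    if (nCross > 1L)
        warning("multiple theta = 0.5 crossings; using the first in the heating direction")
    firstExact <- if (length(exact)) exact[1L] else Inf
    firstCross <- if (length(cross)) cross[1L] else Inf
    if (firstExact <= firstCross) return(tC[firstExact])
    i <- firstCross
    tC[i] + (0.5 - th[i]) * (tC[i + 1L] - tC[i]) / (th[i + 1L] - th[i])
}

#' Van't Hoff regression on a folded-fraction profile
#'
#' Converts in-window points to association constants via
#' [equilibriumConstant()] and regresses ln K on 1/T (kelvin) by ordinary
#' least squares: \eqn{\Delta H = -R \cdot slope} (reported in kJ/mol) and
#' \eqn{\Delta S = R \cdot intercept} (J/K/mol). Points with theta outside
#' `thetaWindow` are baseline-dominated and excluded. The standard free
#' energy at 298.15 K, the observed crossing and derivative melting
#' temperatures and the regression R-squared are attached.
#'
#' @param profile a [ThetaProfile-class].
#' @param molecularity `"unimolecular"` or `"bimolecular"`.
#' @param CT total strand concentration, mol/L (bimolecular only).
#' @param thetaWindow `c(lo, hi)` folded-fraction window used for the
#'   regression (default `c(0.15, 0.85)`).
#' @param smoothWindow passed to [meltingTemperature()].
#' @return a [VantHoffFit-class].
#' @examples
#' p <- ThermoParams(-336.4, -902.0, "bimolecular", CT = 6e-6)
#' tC <- seq(10, 90, 0.25)
#' prof <- ThetaProfile(tC, thetaFromParams(p, celsiusToKelvin(tC)))
#' fit <- vantHoffFit(prof, "bimolecular", CT = 6e-6)
#' deltaH(fit)   # recovers -336.4
#' @export
vantHoffFit <- function(profile, molecularity = c("unimolecular", "bimolecular"),
                        CT = NA_real_, thetaWindow = c(0.15, 0.85),
                        smoothWindow = 11L) {
    stopifnot(is(profile, "ThetaProfile"))
    molecularity <- match.arg(molecularity)
    if (length(thetaWindow) != 2L || thetaWindow[1L] <= 0 ||
        thetaWindow[2L] >= 1 || thetaWindow[1L] >= thetaWindow[2L])
        stop("thetaWindow must be c(lo, hi) with 0 < lo < hi < 1")
    th <- profile@theta
    tK <- .C2K(profile@temperature)
    sel <- th > thetaWindow[1L] & th < thetaWindow[2L]
    if (sum(sel) < 5L)
        stop("fewer than 5 points with theta inside (", thetaWindow[1L], ", ",
             thetaWindow[2L], "); cannot run the van't Hoff regression")
    K <- equilibriumConstant(th[sel], molecularity, CT)
    lnK <- log(K)
    if (any(!is.finite(lnK))) stop("non-finite ln K inside the theta window")
    x <- 1 / tK[sel]
    fit <- lm(lnK ~ x)
    dH <- -unname(coef(fit)[2L]) * .RGAS / 1000
    dS <- unname(coef(fit)[1L]) * .RGAS
    ssres <- sum(fit$residuals^2)
    sstot <- sum((lnK - mean(lnK))^2)
    r2 <- if (sstot > 0) max(0, min(1, 1 - ssres / sstot)) else 1
    params <- ThermoParams(dH, dS, molecularity, CT)
    notes <- character()
    tmObs <- withCallingHandlers(
        tryCatch(meltingTemperature(profile, "crossing", smoothWindow),
                 error = function(e) { NA_real_ }),
        warning = function(w) {
            notes <<- c(notes, conditionMessage(w)); invokeRestart("muffleWarning")
        })
    if (is.na(tmObs)) notes <- c(notes, "no theta = 0.5 crossing in profile")
    tmDer <- tryCatch(meltingTemperature(profile, "derivative", smoothWindow),
                      error = function(e) NA_real_)
    new("VantHoffFit", params = params, TmObs = tmObs, TmDeriv = tmDer,
        deltaG = freeEnergy(params), rSquared = r2,
        thetaWindow = as.numeric(thetaWindow),
        nPoints = as.integer(sum(sel)), notes = notes)
}

#' Direct nonlinear least-squares fit of the complete two-state curve
#'
#' Fits the raw signal to the full two-state model
#' \eqn{s(T) = \theta(T)\,F(T) + (1-\theta(T))\,U(T)} with linear baselines
#' F and U and \eqn{\theta} from [thetaFromParams()], refining all six
#' parameters (\eqn{\Delta H}, \eqn{\Delta S}, two baseline slopes, two
#' intercepts) simultaneously by Levenberg-Marquardt least squares. Starting
#' values come from the window-based baselines and the linear van't Hoff
#' regression, so this is a polish step: it removes the bias the two-stage
#' analysis inherits from plateau contamination of the baseline windows.
#'
#' @inheritParams analyzeCurve
#' @param init optional [VantHoffFit-class] supplying starting values
#'   (default: an internal [vantHoffFit()] pass).
#' @return a [VantHoffFit-class]; melting temperatures and R-squared are
#'   recomputed from the refined baselines.
#' @examples
#' p <- ThermoParams(-336.4, -902.0, "bimolecular", CT = 6e-6)
#' fit <- fitTwoState(simulateCurve(p), "bimolecular", CT = 6e-6)
#' deltaH(fit)
#' @export
fitTwoState <- function(curve, molecularity = c("unimolecular", "bimolecular"),
                        CT = NA_real_, windowFrac = 0.15,
                        foldedWindow = NULL, unfoldedWindow = NULL,
                        thetaWindow = c(0.15, 0.85), smoothWindow = 11L,
                        init = NULL) {
    stopifnot(is(curve, "MeltCurve"))
    molecularity <- match.arg(molecularity)
    bl <- fitBaselines(curve, windowFrac, foldedWindow, unfoldedWindow)
    if (is.null(init))
        init <- vantHoffFit(fractionFolded(curve, bl), molecularity, CT,
                            thetaWindow, smoothWindow)
    tC <- curve@temperature
    tK <- .C2K(tC)
    sv <- curve@signal
    model <- function(dH, dS, fs, fi, us, ui) {
        th <- thetaFromParams(ThermoParams(dH, dS, molecularity, CT), tK)
        th * (fs * tC + fi) + (1 - th) * (us * tC + ui)
    }
    start <- list(dH = unname(init@params@deltaH),
                  dS = unname(init@params@deltaS),
                  fs = unname(bl@folded[1L]), fi = unname(bl@folded[2L]),
                  us = unname(bl@unfolded[1L]), ui = unname(bl@unfolded[2L]))
    nfit <- minpack.lm::nlsLM(sv ~ model(dH, dS, fs, fi, us, ui),
                              start = start,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- coef(nfit)
    params <- ThermoParams(co[["dH"]], co[["dS"]], molecularity, CT)
    blRef <- new("BaselineFit",
                 folded = c(co[["fs"]], co[["fi"]]),
                 unfolded = c(co[["us"]], co[["ui"]]),
                 foldedWindow = bl@foldedWindow,
                 unfoldedWindow = bl@unfoldedWindow)
    prof <- fractionFolded(curve, blRef)
    out <- vantHoffFit(prof, molecularity, CT, thetaWindow, smoothWindow)
    # keep the refined parameters; the profile supplies Tm and diagnostics
    new("VantHoffFit", params = params, TmObs = out@TmObs,
        TmDeriv = out@TmDeriv, deltaG = freeEnergy(params),
        rSquared = out@rSquared, thetaWindow = out@thetaWindow,
        nPoints = out@nPoints, notes = out@notes)
}

#' Heating/cooling hysteresis diagnostic
#'
#' Equilibrium (slow-ramp) melting gives coinciding heating and cooling
#' transitions; a Tm discrepancy beyond `tol` flags non-equilibrium melting,
#' under which van't Hoff parameters are not meaningful.
#'
#' @param heating,cooling [VantHoffFit-class] objects for the two ramp
#'   directions.
#' @param tol flag threshold in degC (default 1).
#' @return list with `deltaTm` (absolute difference, degC) and
#'   `nonEquilibrium` (logical flag).
#' @export
hysteresis <- function(heating, cooling, tol = 1.0) {
    stopifnot(is(heating, "VantHoffFit"), is(cooling, "VantHoffFit"))
    d <- abs(heating@TmObs - cooling@TmObs)
    list(deltaTm = d, nonEquilibrium = is.finite(d) && d > tol)
}

.tmOf <- function(x) {
    if (is(x, "VantHoffFit")) x@TmObs else as.numeric(x)
}

#' Duplex/quadruplex transition separation diagnostic
#'
#' Duplex-only van't Hoff analysis requires the four-stranded transition to
#' melt well above the duplex; the conventional requirement is a separation
#' of at least 25 degC between the two melting temperatures.
#'
#' @param duplexFit,quadFit [VantHoffFit-class] objects or melting
#'   temperatures in degC.
#' @param minSep minimum acceptable separation, degC (default 25).
#' @return list with `separation` (degC, quadruplex minus duplex) and `pass`.
#' @examples
#' transitionSeparation(51.4, 80)$pass   # TRUE (28.6 degC)
#' @export
transitionSeparation <- function(duplexFit, quadFit, minSep = 25) {
    sep <- .tmOf(quadFit) - .tmOf(duplexFit)
    list(separation = sep, pass = is.finite(sep) && sep >= minSep)
}

#' Molecularity from the concentration dependence of Tm
#'
#' For a bimolecular duplex, \eqn{1/T_m} is linear in \eqn{\ln C_T} with
#' slope \eqn{R/\Delta H}; a unimolecular transition has
#' concentration-independent Tm (slope 0). The fitted slope is compared
#' against the slope expected from the supplied van't Hoff enthalpy:
#' magnitudes below half the expectation classify as unimolecular.
#'
#' @param CT total strand concentrations, mol/L (>= 3 distinct values).
#' @param TmK melting temperatures in kelvin, same length.
#' @param deltaH van't Hoff association enthalpy in kJ/mol (from the curve
#'   fits) used to compute the expected bimolecular slope.
#' @return list with `classification`, `slope` (K^-1 per ln-unit),
#'   `expectedSlope` and the underlying `fit`.
#' @export
molecularityTest <- function(CT, TmK, deltaH) {
    if (length(CT) != length(TmK)) stop("CT and TmK lengths differ")
    if (length(unique(CT)) < 3L)
        stop("molecularity test needs at least 3 distinct concentrations")
    if (!is.finite(deltaH) || deltaH == 0)
        stop("deltaH (kJ/mol) is required to compute the expected slope")
    x <- log(CT)
    y <- 1 / TmK
    fit <- lm(y ~ x)
    slope <- unname(coef(fit)[2L])
    expected <- .RGAS / (deltaH * 1000)
    cls <- if (abs(slope) < abs(expected) / 2) "unimolecular" else "bimolecular"
    list(classification = cls, slope = slope, expectedSlope = expected,
         fit = fit)
}

#' One-shot analysis of a single melting curve
#'
#' The per-curve pipeline: baseline fitting over the outer temperature
#' windows, folded-fraction computation, the linear van't Hoff regression,
#' and (by default) a final [fitTwoState()] polish that refits the complete
#' curve by nonlinear least squares to remove residual baseline bias.
#'
#' @param curve a [MeltCurve-class].
#' @param molecularity,CT,thetaWindow,smoothWindow passed to [vantHoffFit()].
#' @param windowFrac,foldedWindow,unfoldedWindow passed to [fitBaselines()].
#' @param refine run the direct two-state refinement (default `TRUE`); set
#'   `FALSE` for the plain two-stage van't Hoff analysis.
#' @return a [VantHoffFit-class].
#' @export
analyzeCurve <- function(curve, molecularity, CT = NA_real_,
                         windowFrac = 0.15, foldedWindow = NULL,
                         unfoldedWindow = NULL, thetaWindow = c(0.15, 0.85),
                         smoothWindow = 11L, refine = TRUE) {
    bl <- fitBaselines(curve, windowFrac, foldedWindow, unfoldedWindow)
    prof <- fractionFolded(curve, bl)
    fit <- vantHoffFit(prof, molecularity, CT, thetaWindow, smoothWindow)
    if (!refine) return(fit)
    fitTwoState(curve, molecularity, CT, windowFrac, foldedWindow,
                unfoldedWindow, thetaWindow, smoothWindow, init = fit)
}
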