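# Synthetic melting-curve generator: the forward model the inverse pipeline
# is validated against. Emulates sigmoidal two-state transitions riding on
# linear sloping baselines, instrument-like 0.25 degC grids, triplicate
# cool-heat-cool ramp patterns, Gaussian signal noise and concentration
# series for molecularity tests.

.checkBaselines <- function(folded, unfolded, Trange) {
    d <- .evalLine(unfolded, Trange) - .evalLine(folded, Trange)
    if (!(all(d > 0) || all(d < 0)))
        stop("folded and unfolded baselines cross within the temperature range")
}

#' Simulate one two-state melting curve
#'
#' Forward model: \eqn{s(T) = \theta(T) F(T) + (1 - \theta(T)) U(T) +
#' N(0, \sigma)}, with the folded fraction from [thetaFromParams()] and
#' linear folded/unfolded baselines F and U given as `c(slope, intercept)`
#' in signal units per degC. Defaults mimic a 3 uM/strand duplex followed by
#' absorbance at 260 nm (folded plateau near 0.59 A, ~20% hyperchromicity,
#' gently sloping baselines) on the instrument grid 10-90 degC at 0.25 degC
#' resolution. Noise-free output (`noiseSigma = 0`) is the exact forward
#' model; with a seed the noise is reproducible.
#'
#' @param params a [ThermoParams-class] describing the transition.
#' @param Trange `c(lo, hi)` temperature range, degC.
#' @param step grid spacing, degC (> 0; default 0.25).
#' @param folded,unfolded baselines `c(slope, intercept)`; must not cross
#'   within `Trange`.
#' @param channel channel label for the output curve.
#' @param direction `"heating"` (ascending grid) or `"cooling"`.
#' @param noiseSigma Gaussian noise standard deviation in signal units
#'   (>= 0).
#' @param seed optional integer seed (sets the RNG via `set.seed`).
#' @param meta metadata list forwarded to the curve.
#' @return a [MeltCurve-class].
#' @examples
#' p <- ThermoParams(-336.4, -902.0, "bimolecular", CT = 6e-6)
#' simulateCurve(p)
#' @export
simulateCurve <- function(params, Trange = c(10, 90), step = 0.25,
                          folded = c(slope = 3e-4, intercept = 0.59),
                          unfolded = c(slope = 3e-4, intercept = 0.71),
                          channel = "A260",
                          direction = c("heating", "cooling"),
                          noiseSigma = 0, seed = NULL, meta = list()) {
    stopifnot(is(params, "ThermoParams"))
    direction <- match.arg(direction)
    if (step <= 0) stop("step must be > 0")
    if (noiseSigma < 0) stop("noiseSigma must be >= 0")
    .checkBaselines(folded, unfolded, Trange)
    tC <- seq(Trange[1L], Trange[2L], by = step)
    if (identical(direction, "cooling")) tC <- rev(tC)
    th <- thetaFromParams(params, .C2K(tC))
    sv <- th * .evalLine(folded, tC) + (1 - th) * .evalLine(unfolded, tC)
    if (noiseSigma > 0) {
        if (!is.null(seed)) set.seed(seed)
        sv <- sv + rnorm(length(sv), 0, noiseSigma)
    }
    MeltCurve(tC, sv, channel = channel, direction = direction, meta = meta)
}

#' Simulate a time-ordered multi-ramp instrument trace
#'
#' Concatenates successive ramps (default cool-heat-cool, the protocol of a
#' 90-10-90-10 degC run) into one time-ordered trace suitable for
#' [splitRamps()]. An optional `hysteresisShift` offsets the apparent Tm of
#' heating ramps to exercise the [hysteresis()] diagnostic (default 0:
#' equilibrium melting, as expected for slow ramp rates).
#'
#' @inheritParams simulateCurve
#' @param pattern character vector of ramp directions in recording order.
#' @param hysteresisShift temperature offset (degC) applied to the folded
#'   fraction of heating ramps.
#' @return data.frame with columns `temperature`, `signal`, `ramp`.
#' @export
simulateMeltTrace <- function(params, pattern = c("cooling", "heating", "cooling"),
                              Trange = c(10, 90), step = 0.25,
                              folded = c(slope = 3e-4, intercept = 0.59),
                              unfolded = c(slope = 3e-4, intercept = 0.71),
                              noiseSigma = 0, seed = NULL,
                              hysteresisShift = 0) {
    stopifnot(is(params, "ThermoParams"))
    if (!length(pattern) || !all(pattern %in% c("heating", "cooling")))
        stop("pattern must be a vector of 'heating'/'cooling'")
    .checkBaselines(folded, unfolded, Trange)
    if (!is.null(seed)) set.seed(seed)
    grid <- seq(Trange[1L], Trange[2L], by = step)
    out <- vector("list", length(pattern))
    for (i in seq_along(pattern)) {
        tC <- if (identical(pattern[i], "cooling")) rev(grid) else grid
        # successive ramps continue from the previous endpoint
        if (i > 1L) tC <- tC[-1L]
        shift <- if (identical(pattern[i], "heating")) hysteresisShift else 0
        th <- thetaFromParams(params, .C2K(tC - shift))
        sv <- th * .evalLine(folded, tC) + (1 - th) * .evalLine(unfolded, tC)
        if (noiseSigma > 0) sv <- sv + rnorm(length(sv), 0, noiseSigma)
        out[[i]] <- data.frame(temperature = tC, signal = sv, ramp = i)
    }
    do.call(rbind, out)
}

#' Simulate a double-transition experiment (duplex + quadruplex)
#'
#' Additive superposition of a bimolecular duplex transition and a
#' higher-melting unimolecular quadruplex transition, monitored on two
#' channels simultaneously: at 260 nm both transitions are hyperchromic
#' (the quadruplex contributes `quadAmp260` of extra absorbance on
#' melting); at 295 nm the signal is dominated by the quadruplex, with the
#' folding-increases-signal orientation (hypochromic upon melting).
#'
#' @param duplexParams bimolecular [ThermoParams-class] of the duplex.
#' @param quadParams unimolecular [ThermoParams-class] of the quadruplex.
#' @inheritParams simulateCurve
#' @param quadAmp260 260 nm amplitude of the quadruplex transition. The
#'   default is a minor fraction of the duplex amplitude: quadruplex melting
#'   changes 260 nm absorbance only modestly, which is why the quadruplex
#'   transition is monitored at 295 nm where it dominates.
#' @param quadAmp295 295 nm amplitude of the quadruplex transition.
#' @param base295 linear 295 nm baseline `c(slope, intercept)`.
#' @return list with [MeltCurve-class] elements `A260` and `A295`.
#' @export
simulateTwoTransition <- function(duplexParams, quadParams,
                                  Trange = c(10, 90), step = 0.25,
                                  folded = c(slope = 3e-4, intercept = 0.59),
                                  unfolded = c(slope = 3e-4, intercept = 0.71),
                                  quadAmp260 = 0.02, quadAmp295 = 0.10,
                                  base295 = c(slope = 0, intercept = 0.05),
                                  noiseSigma = 0, seed = NULL) {
    stopifnot(is(duplexParams, "ThermoParams"), is(quadParams, "ThermoParams"))
    if (quadAmp260 < 0 || quadAmp295 < 0) stop("amplitudes must be >= 0")
    .checkBaselines(folded, unfolded, Trange)
    if (!is.null(seed)) set.seed(seed)
    tC <- seq(Trange[1L], Trange[2L], by = step)
    tK <- .C2K(tC)
    thD <- thetaFromParams(duplexParams, tK)
    thQ <- thetaFromParams(quadParams, tK)
    a260 <- thD * .evalLine(folded, tC) + (1 - thD) * .evalLine(unfolded, tC) +
        quadAmp260 * (1 - thQ)
    a295 <- .evalLine(base295, tC) + quadAmp295 * thQ
    if (noiseSigma > 0) {
        a260 <- a260 + rnorm(length(tC), 0, noiseSigma)
        a295 <- a295 + rnorm(length(tC), 0, noiseSigma)
    }
    list(A260 = MeltCurve(tC, a260, channel = "A260"),
         A295 = MeltCurve(tC, a295, channel = "A295"))
}

#' Simulate a strand-concentration series
#'
#' Generates one melting curve per total strand concentration, holding the
#' van't Hoff parameters fixed. For a bimolecular transition the melting
#' temperature rises with concentration; a unimolecular transition is
#' concentration-invariant. Feeds [molecularityTest()].
#'
#' @inheritParams simulateCurve
#' @param concentrations total strand concentrations, mol/L (>= 2).
#' @return list with one element per concentration, each a list
#'   `(CT, curve)`.
#' @export
simulateConcentrationSeries <- function(params, concentrations,
                                        Trange = c(10, 90), step = 0.25,
                                        folded = c(slope = 3e-4, intercept = 0.59),
                                        unfolded = c(slope = 3e-4, intercept = 0.71),
                                        noiseSigma = 0, seed = NULL) {
    stopifnot(is(params, "ThermoParams"))
    if (length(concentrations) < 2L)
        stop("need at least 2 concentrations")
    if (!is.null(seed)) set.seed(seed)
    lapply(concentrations, function(ct) {
        p <- ThermoParams(params@deltaH, params@deltaS, params@molecularity,
                          CT = if (identical(params@molecularity, "bimolecular"))
                              ct else params@CT)
        list(CT = ct,
             curve = simulateCurve(p, Trange, step, folded, unfolded,
                                   noiseSigma = noiseSigma,
                                   meta = list(CT = ct)))
    })
}
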