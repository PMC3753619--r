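#' ThermoParams: two-state folding thermodynamics
#'
#' Van't Hoff association parameters of a two-state transition. Signs follow
#' the association convention: folding of a stable duplex has negative
#' \eqn{\Delta H} (kJ/mol) and \eqn{\Delta S} (J/K/mol), so
#' \eqn{\Delta G^\circ = \Delta H - T\Delta S} is negative at 298.15 K.
#'
#' `molecularity` is `"unimolecular"` (hairpin/quadruplex, concentration
#' independent) or `"bimolecular"` (non-self-complementary duplex from two
#' strands at equal concentration). For bimolecular transitions `CT` is the
#' total single-strand concentration in mol/L, i.e. twice the per-strand
#' concentration (3 uM/strand gives `CT = 6e-6`).
#'
#' @slot deltaH van't Hoff association enthalpy, kJ/mol.
#' @slot deltaS association entropy, J/K/mol.
#' @slot molecularity `"unimolecular"` or `"bimolecular"`.
#' @slot CT total strand concentration, mol/L (`NA` for unimolecular).
#' @aliases ThermoParams-class
#' @exportClass ThermoParams
setClass("ThermoParams",
    representation(deltaH = "numeric", deltaS = "numeric",
                   molecularity = "character", CT = "numeric"))

setValidity("ThermoParams", function(object) {
    msg <- character()
    if (length(object@deltaH) != 1L || !is.finite(object@deltaH))
        msg <- c(msg, "deltaH must be a single finite value (kJ/mol)")
    if (length(object@deltaS) != 1L || !is.finite(object@deltaS))
        msg <- c(msg, "deltaS must be a single finite value (J/K/mol)")
    if (length(object@molecularity) != 1L ||
        !object@molecularity %in% c("unimolecular", "bimolecular"))
        msg <- c(msg, "molecularity must be 'unimolecular' or 'bimolecular'")
    if (identical(object@molecularity, "bimolecular") &&
        (length(object@CT) != 1L || !is.finite(object@CT) || object@CT <= 0))
        msg <- c(msg, "CT (total strand concentration, mol/L) must be > 0 for bimolecular transitions")
    if (length(msg)) msg else TRUE
})

#' Construct ThermoParams
#'
#' @param deltaH association enthalpy, kJ/mol.
#' @param deltaS association entropy, J/K/mol. Note the kJ vs J distinction:
#'   it matches how melting studies tabulate these quantities.
#' @param molecularity `"unimolecular"` or `"bimolecular"`.
#' @param CT total strand concentration in mol/L (required for bimolecular;
#'   sum over both strands).
#' @return a [ThermoParams-class] object.
#' @examples
#' ThermoParams(-336.4, -902.0, "bimolecular", CT = 6e-6)
#' @export
ThermoParams <- function(deltaH, deltaS,
                         molecularity = c("unimolecular", "bimolecular"),
                         CT = NA_real_) {
    molecularity <- match.arg(molecularity)
    new("ThermoParams", deltaH = as.numeric(deltaH),
        deltaS = as.numeric(deltaS), molecularity = molecularity,
        CT = as.numeric(CT))
}

#' MeltCurve: one temperature ramp of one optical channel
#'
#' A single monotone temperature ramp of a melting experiment: temperature in
#' degrees Celsius against an optical signal (absorbance at 260/295 nm or
#' ellipticity at 280 nm). Experimental metadata (pH, strand concentration,
#' ramp rate, pair label, replicate id) travels in `meta`.
#'
#' @slot temperature numeric, degrees Celsius, strictly monotone.
#' @slot signal numeric, same length, finite.
#' @slot channel e.g. `"A260"`, `"A295"`, `"CD280"`.
#' @slot direction `"heating"` or `"cooling"`.
#' @slot meta named list of experiment metadata.
#' @aliases MeltCurve-class
#' @exportClass MeltCurve
setClass("MeltCurve",
    representation(temperature = "numeric", signal = "numeric",
                   channel = "character", direction = "character",
                   meta = "list"))

setValidity("MeltCurve", function(object) {
    msg <- character()
    n <- length(object@temperature)
    if (n < 20L)
        msg <- c(msg, "a melting curve needs at least 20 points")
    if (length(object@signal) != n)
        msg <- c(msg, "temperature and signal lengths differ")
    if (anyNA(object@temperature) || anyNA(object@signal) ||
        any(!is.finite(object@signal)))
        msg <- c(msg, "temperature and signal must be finite")
    d <- diff(object@temperature)
    if (n >= 2L && !(all(d > 0) || all(d < 0)))
        msg <- c(msg, "temperature must be strictly monotone within a ramp")
    if (!object@direction %in% c("heating", "cooling"))
        msg <- c(msg, "direction must be 'heating' or 'cooling'")
    if (length(msg)) msg else TRUE
})

#' Construct a MeltCurve
#'
#' @param temperature degrees Celsius, strictly monotone.
#' @param signal optical signal, same length.
#' @param channel signal channel label (default `"A260"`).
#' @param direction `"heating"` or `"cooling"`; inferred from the temperature
#'   grid when omitted.
#' @param meta named list of metadata (pH, CT, ramp rate, pair, replicate).
#' @return a [MeltCurve-class] object.
#' @export
MeltCurve <- function(temperature, signal, channel = "A260",
                      direction = NULL, meta = list()) {
    if (is.null(direction))
        direction <- if (temperature[length(temperature)] >= temperature[1L])
            "heating" else "cooling"
    new("MeltCurve", temperature = as.numeric(temperature),
        signal = as.numeric(signal), channel = channel,
        direction = direction, meta = meta)
}

#' BaselineFit: folded and unfolded plateau baselines
#'
#' Least-squares lines fitted to the pre- and post-transitional plateaus of a
#' melting curve. The `folded` line describes the low-temperature plateau
#' (native species), `unfolded` the high-temperature plateau. Each is stored
#' as `c(slope, intercept)` in signal units per degree Celsius / signal units.
#'
#' @slot folded,unfolded numeric `c(slope, intercept)`.
#' @slot foldedWindow,unfoldedWindow numeric `c(lo, hi)` temperature windows
#'   (degrees Celsius) the lines were fitted on; disjoint.
#' @aliases BaselineFit-class
#' @exportClass BaselineFit
setClass("BaselineFit",
    representation(folded = "numeric", unfolded = "numeric",
                   foldedWindow = "numeric", unfoldedWindow = "numeric"))

setValidity("BaselineFit", function(object) {
    msg <- character()
    if (length(object@folded) != 2L || anyNA(object@folded))
        msg <- c(msg, "folded baseline must be c(slope, intercept)")
    if (length(object@unfolded) != 2L || anyNA(object@unfolded))
        msg <- c(msg, "unfolded baseline must be c(slope, intercept)")
    if (length(object@foldedWindow) == 2L && length(object@unfoldedWindow) == 2L &&
        max(object@foldedWindow) > min(object@unfoldedWindow) &&
        max(object@unfoldedWindow) > min(object@foldedWindow))
        msg <- c(msg, "baseline windows must be disjoint")
    if (length(msg)) msg else TRUE
})

#' ThetaProfile: folded fraction against temperature
#'
#' Baseline-corrected folded fraction \eqn{\theta(T)}, clipped to \[0, 1\].
#'
#' @slot temperature degrees Celsius.
#' @slot theta folded fraction per point, in \[0, 1\].
#' @aliases ThetaProfile-class
#' @exportClass ThetaProfile
setClass("ThetaProfile",
    representation(temperature = "numeric", theta = "numeric"))

setValidity("ThetaProfile", function(object) {
    msg <- character()
    if (length(object@theta) != length(object@temperature))
        msg <- c(msg, "temperature and theta lengths differ")
    if (anyNA(object@theta) || any(object@theta < 0) || any(object@theta > 1))
        msg <- c(msg, "theta must be finite and within [0, 1]")
    if (length(msg)) msg else TRUE
})

ThetaProfile <- function(temperature, theta)
    new("ThetaProfile", temperature = as.numeric(temperature),
        theta = as.numeric(theta))

#' VantHoffFit: per-curve thermodynamic estimates
#'
#' Result of the van't Hoff regression on one melting curve: association
#' parameters, observed melting temperatures, standard free energy at
#' 298.15 K and regression diagnostics.
#'
#' @slot params fitted [ThermoParams-class].
#' @slot TmObs melting temperature from the theta = 0.5 crossing, deg C.
#' @slot TmDeriv melting temperature from the derivative extremum, deg C.
#' @slot deltaG standard free energy at 298.15 K, kJ/mol.
#' @slot rSquared coefficient of determination of ln K vs 1/T.
#' @slot thetaWindow theta range used for the regression.
#' @slot nPoints number of points used.
#' @slot notes character vector of analysis warnings.
#' @aliases VantHoffFit-class
#' @exportClass VantHoffFit
setClass("VantHoffFit",
    representation(params = "ThermoParams", TmObs = "numeric",
                   TmDeriv = "numeric", deltaG = "numeric",
                   rSquared = "numeric", thetaWindow = "numeric",
                   nPoints = "integer", notes = "character"))

setValidity("VantHoffFit", function(object) {
    msg <- character()
    if (is.finite(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1 + 1e-12))
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (length(object@thetaWindow) != 2L ||
        any(object@thetaWindow <= 0) || any(object@thetaWindow >= 1))
        msg <- c(msg, "thetaWindow must lie within (0, 1)")
    if (length(msg)) msg else TRUE
})

#' ThermoSummary: replicate mean and 1-sigma per oligonucleotide pair
#'
#' Replicate-level aggregation of van't Hoff fits for one oligonucleotide
#' pair at one pH: mean and sample standard deviation (1 sigma) of Tm (deg C),
#' delta-H (kJ/mol), delta-S (J/K/mol) and delta-G at 298.15 K (kJ/mol).
#' Per-replicate delta-G values are retained for significance testing.
#'
#' @slot pair pair label.
#' @slot pH solution pH.
#' @slot n replicate count.
#' @slot TmMean,TmSd,dHMean,dHSd,dSMean,dSSd,dGMean,dGSd means and 1-sigma.
#' @slot dGValues per-replicate delta-G values (may be empty when the summary
#'   was entered from a published table).
#' @aliases ThermoSummary-class
#' @exportClass ThermoSummary
setClass("ThermoSummary",
    representation(pair = "character", pH = "numeric", n = "integer",
                   TmMean = "numeric", TmSd = "numeric",
                   dHMean = "numeric", dHSd = "numeric",
                   dSMean = "numeric", dSSd = "numeric",
                   dGMean = "numeric", dGSd = "numeric",
                   dGValues = "numeric"))

setValidity("ThermoSummary", function(object) {
    msg <- character()
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    sds <- c(object@TmSd, object@dHSd, object@dSSd, object@dGSd)
    if (any(is.finite(sds) & sds < 0)) msg <- c(msg, "sigma must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a ThermoSummary directly from tabulated values
#'
#' Builds the replicate summary object from mean and 1-sigma values, e.g. when
#' re-analysing a published table rather than raw traces.
#'
#' @param pair pair label.
#' @param pH solution pH.
#' @param n replicate count the values were derived from.
#' @param Tm,TmSd melting temperature mean and sigma, deg C.
#' @param dH,dHSd enthalpy mean and sigma, kJ/mol.
#' @param dS,dSSd entropy mean and sigma, J/K/mol.
#' @param dG,dGSd standard free energy (298.15 K) mean and sigma, kJ/mol.
#' @param dGValues optional per-replicate delta-G values.
#' @return a [ThermoSummary-class] object.
#' @examples
#' thermoSummary("top1/bottom1", 7.4, 3, Tm = 58.6, TmSd = 0.7,
#'               dG = -67.5, dGSd = 1.7)
#' @export
thermoSummary <- function(pair, pH = NA_real_, n = 1L,
                          Tm = NA_real_, TmSd = NA_real_,
                          dH = NA_real_, dHSd = NA_real_,
                          dS = NA_real_, dSSd = NA_real_,
                          dG = NA_real_, dGSd = NA_real_,
                          dGValues = numeric()) {
    new("ThermoSummary", pair = pair, pH = as.numeric(pH), n = as.integer(n),
        TmMean = as.numeric(Tm), TmSd = as.numeric(TmSd),
        dHMean = as.numeric(dH), dHSd = as.numeric(dHSd),
        dSMean = as.numeric(dS), dSSd = as.numeric(dSSd),
        dGMean = as.numeric(dG), dGSd = as.numeric(dGSd),
        dGValues = as.numeric(dGValues))
}
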