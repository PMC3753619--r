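#' Standard free energy from van't Hoff parameters
#'
#' \eqn{\Delta G^\circ = \Delta H - T \Delta S}, with \eqn{\Delta H} in
#' kJ/mol, \eqn{\Delta S} in J/K/mol and the result in kJ/mol. The default
#' temperature is the standard 298.15 K used when tabulating duplex
#' stabilities.
#'
#' @param params a [ThermoParams-class] object.
#' @param T temperature in kelvin (> 0).
#' @return standard free energy in kJ/mol.
#' @examples
#' p <- ThermoParams(-336.4, -902.0, "bimolecular", CT = 6e-6)
#' freeEnergy(p)            # about -67.5 kJ/mol
#' @export
freeEnergy <- function(params, T = 298.15) {
    stopifnot(is(params, "ThermoParams"))
    if (any(T <= 0)) stop("temperature must be positive (kelvin)")
    params@deltaH - T * params@deltaS / 1000
}

#' Two-state association constant from the folded fraction
#'
#' Association equilibrium constants of the two-state model. Unimolecular:
#' \eqn{K = \theta / (1 - \theta)}. Bimolecular duplex from two different
#' strands at equal concentration (per-strand concentration \eqn{C_T/2}):
#' \eqn{K = \theta / ((1-\theta)^2 C_T / 2)}.
#'
#' @param theta folded fraction, strictly inside (0, 1); vectorized.
#' @param molecularity `"unimolecular"` or `"bimolecular"`.
#' @param CT total strand concentration, mol/L (bimolecular only).
#' @return association constant K (dimensionless, or 1/M for bimolecular).
#' @examples
#' equilibriumConstant(0.5, "unimolecular")            # 1
#' equilibriumConstant(0.5, "bimolecular", CT = 6e-6)  # 4 / CT
#' @export
equilibriumConstant <- function(theta,
                                molecularity = c("unimolecular", "bimolecular"),
                                CT = NA_real_) {
    molecularity <- match.arg(molecularity)
    if (any(!is.finite(theta)) || any(theta <= 0) || any(theta >= 1))
        stop("theta must lie strictly inside (0, 1); K is undefined at the endpoints")
    if (identical(molecularity, "unimolecular"))
        return(theta / (1 - theta))
    if (!is.finite(CT) || CT <= 0)
        stop("bimolecular equilibrium constants require CT > 0 (mol/L)")
    theta / ((1 - theta)^2 * (CT / 2))
}

#' Association constant of the forward model at a given temperature
#'
#' \eqn{K(T) = \exp(\Delta S / R - \Delta H / (R T))} with unit
#' reconciliation (\eqn{\Delta H} in kJ/mol, \eqn{\Delta S} in J/K/mol,
#' R = 8.314 J/K/mol).
#'
#' @inheritParams freeEnergy
#' @return K(T); may overflow to `Inf` far below the melting temperature.
#' @export
vantHoffK <- function(params, T) {
    stopifnot(is(params, "ThermoParams"))
    if (any(T <= 0)) stop("temperature must be positive (kelvin)")
    exp(params@deltaS / .RGAS - params@deltaH * 1000 / (.RGAS * T))
}

#' Folded fraction of the two-state forward model
#'
#' Inverts the mass-action law at each temperature. Unimolecular:
#' \eqn{\theta = K / (1 + K)}. Bimolecular with equal strand concentrations:
#' the root in (0, 1) of \eqn{K (C_T/2) (1-\theta)^2 = \theta}, evaluated in
#' the cancellation-free form \eqn{\theta = 2a / (2a + 1 + \sqrt{4a + 1})}
#' with \eqn{a = K C_T / 2}. Where K overflows (far below Tm for an
#' exothermic transition) theta clamps to 1.
#'
#' @inheritParams freeEnergy
#' @param T temperature(s) in kelvin; vectorized.
#' @return folded fraction(s) in (0, 1), possibly 0/1 at overflow.
#' @examples
#' p <- ThermoParams(-336.4, -902.0, "bimolecular", CT = 6e-6)
#' thetaFromParams(p, predictedTm(p))   # exactly 0.5
#' @export
thetaFromParams <- function(params, T) {
    K <- vantHoffK(params, T)
    if (identical(params@molecularity, "unimolecular")) {
        th <- ifelse(is.infinite(K), 1, K / (1 + K))
    } else {
        a <- K * params@CT / 2
        th <- ifelse(is.infinite(a), 1, 2 * a / (2 * a + 1 + sqrt(4 * a + 1)))
    }
    pmin(pmax(th, 0), 1)
}

#' Closed-form melting temperature of the two-state model
#'
#' Temperature at which the folded fraction is one half. Unimolecular:
#' \eqn{T_m = \Delta H / \Delta S} (unit-reconciled). Bimolecular duplex with
#' equal strand concentrations: \eqn{T_m = \Delta H / (\Delta S + R \ln(C_T/4))}.
#' The returned temperature satisfies `thetaFromParams(params, Tm) == 0.5`
#' to machine precision.
#'
#' @inheritParams freeEnergy
#' @param celsius return degrees Celsius instead of kelvin.
#' @return melting temperature, kelvin (default) or degrees Celsius.
#' @examples
#' p <- ThermoParams(-381.2, -1052.3, "bimolecular", CT = 6e-6)
#' predictedTm(p, celsius = TRUE)   # about 54.4 degC
#' @export
predictedTm <- function(params, celsius = FALSE) {
    stopifnot(is(params, "ThermoParams"))
    if (params@deltaH == 0) stop("Tm is undefined for deltaH = 0")
    if (identical(params@molecularity, "unimolecular")) {
        if (params@deltaS == 0) stop("unimolecular Tm is undefined for deltaS = 0")
        tm <- params@deltaH * 1000 / params@deltaS
    } else {
        den <- params@deltaS + .RGAS * log(params@CT / 4)
        if (abs(den) < .Machine$double.eps)
            stop("bimolecular Tm is undefined: deltaS + R*ln(CT/4) = 0")
        tm <- params@deltaH * 1000 / den
    }
    if (tm <= 0) stop("parameters do not yield a physical melting temperature")
    if (celsius) .K2C(tm) else tm
}
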