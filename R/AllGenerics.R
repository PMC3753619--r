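#' Accessors for duplexmelt S4 classes
#'
#' Slot access goes through these generics rather than `@`.
#'
#' @param object a duplexmelt S4 object.
#' @return the corresponding component: numeric scalars for thermodynamic
#'   quantities, numeric vectors for profiles.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("deltaH", function(object) standardGeneric("deltaH"))
#' @rdname accessors
#' @export
setGeneric("deltaS", function(object) standardGeneric("deltaS"))
#' @rdname accessors
#' @export
setGeneric("molecularity", function(object) standardGeneric("molecularity"))
#' @rdname accessors
#' @export
setGeneric("strandConc", function(object) standardGeneric("strandConc"))
#' @rdname accessors
#' @export
setGeneric("tempC", function(object) standardGeneric("tempC"))
#' @rdname accessors
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setGeneric("thetaValues", function(object) standardGeneric("thetaValues"))
#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setGeneric("tmObserved", function(object) standardGeneric("tmObserved"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("stdFreeEnergy", function(object) standardGeneric("stdFreeEnergy"))

#' @rdname accessors
setMethod("deltaH", "ThermoParams", function(object) object@deltaH)
#' @rdname accessors
setMethod("deltaS", "ThermoParams", function(object) object@deltaS)
#' @rdname accessors
setMethod("molecularity", "ThermoParams", function(object) object@molecularity)
#' @rdname accessors
setMethod("strandConc", "ThermoParams", function(object) object@CT)

#' @rdname accessors
setMethod("tempC", "MeltCurve", function(object) object@temperature)
#' @rdname accessors
setMethod("signalValues", "MeltCurve", function(object) object@signal)
#' @rdname accessors
setMethod("tempC", "ThetaProfile", function(object) object@temperature)
#' @rdname accessors
setMethod("thetaValues", "ThetaProfile", function(object) object@theta)

#' @rdname accessors
setMethod("fitParams", "VantHoffFit", function(object) object@params)
#' @rdname accessors
setMethod("deltaH", "VantHoffFit", function(object) object@params@deltaH)
#' @rdname accessors
setMethod("deltaS", "VantHoffFit", function(object) object@params@deltaS)
#' @rdname accessors
setMethod("tmObserved", "VantHoffFit", function(object) object@TmObs)
#' @rdname accessors
setMethod("rSquared", "VantHoffFit", function(object) object@rSquared)
#' @rdname accessors
setMethod("stdFreeEnergy", "VantHoffFit", function(object) object@deltaG)

setMethod("show", "ThermoParams", function(object) {
    cat(sprintf("ThermoParams (%s%s)\n", object@molecularity,
        if (identical(object@molecularity, "bimolecular"))
            sprintf(", CT = %.3g M", object@CT) else ""))
    cat(sprintf("  deltaH = %.1f kJ/mol, deltaS = %.1f J/K/mol\n",
        object@deltaH, object@deltaS))
    invisible(NULL)
})

setMethod("show", "MeltCurve", function(object) {
    cat(sprintf("MeltCurve [%s, %s]: %d points, %.2f to %.2f degC\n",
        object@channel, object@direction, length(object@temperature),
        object@temperature[1L],
        object@temperature[length(object@temperature)]))
    invisible(NULL)
})

setMethod("show", "BaselineFit", function(object) {
    cat(sprintf("BaselineFit\n  folded:   slope %.4g, intercept %.4g (window %.1f-%.1f degC)\n",
        object@folded[1L], object@folded[2L],
        object@foldedWindow[1L], object@foldedWindow[2L]))
    cat(sprintf("  unfolded: slope %.4g, intercept %.4g (window %.1f-%.1f degC)\n",
        object@unfolded[1L], object@unfolded[2L],
        object@unfoldedWindow[1L], object@unfoldedWindow[2L]))
    invisible(NULL)
})

setMethod("show", "ThetaProfile", function(object) {
    cat(sprintf("ThetaProfile: %d points, theta %.3f to %.3f\n",
        length(object@theta), min(object@theta), max(object@theta)))
    invisible(NULL)
})

setMethod("show", "VantHoffFit", function(object) {
    p <- object@params
    cat(sprintf("VantHoffFit (%s): deltaH = %.1f kJ/mol, deltaS = %.1f J/K/mol\n",
        p@molecularity, p@deltaH, p@deltaS))
    cat(sprintf("  Tm(obs) = %.2f degC, deltaG(298.15 K) = %.2f kJ/mol, R2 = %.5f\n",
        object@TmObs, object@deltaG, object@rSquared))
    if (length(object@notes))
        cat("  notes:", paste(object@notes, collapse = "; "), "\n")
    invisible(NULL)
})

setMethod("show", "ThermoSummary", function(object) {
    cat(sprintf("ThermoSummary %s (pH %.1f, n = %d)\n",
        object@pair, object@pH, object@n))
    cat(sprintf("  Tm = %.1f +/- %.1f degC, dG(298.15 K) = %.1f +/- %.1f kJ/mol\n",
        object@TmMean, object@TmSd, object@dGMean, object@dGSd))
    invisible(NULL)
})
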