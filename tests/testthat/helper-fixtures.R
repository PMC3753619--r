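# Shared fixture builders and independent test-side oracles.

RGAS <- 8.314

# Bimolecular ThermoParams with a prescribed melting temperature (degC) at
# total strand concentration CT.
paramsForTm <- function(deltaH, tmC, CT = 6e-6) {
    dS <- deltaH * 1000 / celsiusToKelvin(tmC) - RGAS * log(CT / 4)
    ThermoParams(deltaH, dS, "bimolecular", CT = CT)
}

# Random parameter draw over deltaH in [-450, -150] kJ/mol, Tm in [35, 65]
# degC, accepted only when both plateaus lie inside the 10-90 degC
# instrument range: the true folded fraction must sit within 0.002 of its
# asymptote across the outer 15% baseline windows (plateau contamination
# below the 0.2%-of-amplitude noise level of the generator).
drawScreenedParams <- function(CT = 6e-6) {
    repeat {
        p <- paramsForTm(runif(1, -450, -150), runif(1, 35, 65), CT)
        th <- thetaFromParams(p, celsiusToKelvin(c(22, 78)))
        if (th[1] >= 0.998 && th[2] <= 0.002) return(p)
    }
}

randomDNA <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
    paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

longestRun <- function(s, base) {
    r <- rle(strsplit(s, "")[[1L]] == base)
    if (!any(r$values)) 0L else max(r$lengths[r$values])
}

# Brute-force existence oracle for the run/loop motif grammar: recursive
# enumeration of every placement of nRuns runs (length >= minRun) separated
# by loops within [loopMin, loopMax]. Independent of the package scanner.
bruteHasMotif <- function(s, base, minRun = 3L, loopMin = 1L, loopMax = 7L,
                          nRuns = 4L) {
    n <- nchar(s)
    ch <- strsplit(s, "")[[1L]]
    runFrom <- function(st) {
        len <- 0L
        while (st + len <= n && ch[st + len] == base) len <- len + 1L
        len
    }
    rec <- function(pos, left) {
        if (pos > n) return(FALSE)
        for (st in pos:n) {
            maxlen <- runFrom(st)
            if (maxlen < minRun) next
            if (left == 1L) return(TRUE)
            for (len in minRun:maxlen) {
                nxt <- st + len
                for (loop in loopMin:loopMax) {
                    if (rec(nxt + loop, left - 1L)) return(TRUE)
                }
            }
        }
        FALSE
    }
    rec(1L, nRuns)
}

# Build a VantHoffFit carrying prescribed summary quantities, for arithmetic
# tests that do not need a real regression behind the object.
syntheticFit <- function(dG, Tm = 55, dH = -300, dS = -800,
                         molecularity = "bimolecular", CT = 6e-6) {
    new("VantHoffFit",
        params = ThermoParams(dH, dS, molecularity, CT),
        TmObs = Tm, TmDeriv = Tm, deltaG = dG, rSquared = 1,
        thetaWindow = c(0.15, 0.85), nPoints = 100L, notes = character())
}
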