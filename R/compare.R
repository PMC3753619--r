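# Replicate aggregation and destabilization statistics: delta-delta-G,
# delta-Tm, relative destabilization, quadrature errors, ANOVA + Bonferroni.

#' Aggregate replicate van't Hoff fits
#'
#' Mean and sample standard deviation (1 sigma) of Tm, delta-H, delta-S and
#' delta-G over replicate curve fits of one oligonucleotide pair. Delta-G is
#' averaged over per-replicate values, not recomputed from the mean
#' delta-H/delta-S. A single replicate yields sigma = 0 with a warning.
#'
#' @param fits list of [VantHoffFit-class] objects (>= 1).
#' @param pair pair label for the summary.
#' @param pH solution pH.
#' @return a [ThermoSummary-class].
#' @export
aggregateReplicates <- function(fits, pair = "pair", pH = NA_real_) {
    if (!length(fits)) stop("no fits to aggregate")
    if (!all(vapply(fits, is, logical(1L), "VantHoffFit")))
        stop("fits must be a list of VantHoffFit objects")
    g <- function(f) c(Tm = f@TmObs, dH = f@params@deltaH,
                       dS = f@params@deltaS, dG = f@deltaG)
    m <- t(vapply(fits, g, numeric(4L)))
    n <- nrow(m)
    sds <- if (n > 1L) apply(m, 2L, sd) else {
        warning("single replicate: sigma set to 0 (n = 1)")
        c(Tm = 0, dH = 0, dS = 0, dG = 0)
    }
    mu <- colMeans(m)
    thermoSummary(pair, pH, n,
                  Tm = mu["Tm"], TmSd = sds["Tm"],
                  dH = mu["dH"], dHSd = sds["dH"],
                  dS = mu["dS"], dSSd = sds["dS"],
                  dG = mu["dG"], dGSd = sds["dG"],
                  dGValues = m[, "dG"])
}

.quadrature <- function(a, b) sqrt(a^2 + b^2)

#' Destabilization free energy between a construct and its reference
#'
#' \eqn{\Delta\Delta G^\circ = \Delta G^\circ(construct) -
#' \Delta G^\circ(reference)}; positive values mean the construct is
#' destabilized. The 1-sigma error is the quadrature sum of the two
#' replicate sigmas. Comparing summaries at different pH triggers a warning.
#'
#' @param reference,construct [ThermoSummary-class] objects.
#' @return list with `value` and `sd`, both kJ/mol.
#' @examples
#' ref <- thermoSummary("ref", 7.4, 3, dG = -67.5, dGSd = 1.7)
#' con <- thermoSummary("gq",  7.4, 3, dG = -52.7, dGSd = 3.4)
#' deltaDeltaG(ref, con)   # 14.8 +/- 3.8
#' @export
deltaDeltaG <- function(reference, construct) {
    stopifnot(is(reference, "ThermoSummary"), is(construct, "ThermoSummary"))
    if (is.finite(reference@pH) && is.finite(construct@pH) &&
        reference@pH != construct@pH)
        warning("comparing summaries measured at different pH (",
                reference@pH, " vs ", construct@pH, ")")
    list(value = construct@dGMean - reference@dGMean,
         sd = .quadrature(reference@dGSd, construct@dGSd))
}

#' Melting-temperature depression between a construct and its reference
#'
#' \eqn{\Delta T_m = T_m(reference) - T_m(construct)}; positive values mean
#' the construct melts lower. Quadrature 1-sigma error.
#'
#' @param reference,construct [ThermoSummary-class] objects.
#' @return list with `value` and `sd`, degrees Celsius.
#' @export
deltaTm <- function(reference, construct) {
    stopifnot(is(reference, "ThermoSummary"), is(construct, "ThermoSummary"))
    list(value = reference@TmMean - construct@TmMean,
         sd = .quadrature(reference@TmSd, construct@TmSd))
}

#' Relative destabilization (percent of reference stability)
#'
#' \eqn{100 \cdot \Delta\Delta G^\circ / |\Delta G^\circ(ref)|}, expressing
#' the destabilization as a fraction of the stability of the duplex alone --
#' useful when comparing across pH, where the reference stability itself
#' changes. The sigma follows relative quadrature:
#' \eqn{|value| \sqrt{(\sigma_{\Delta\Delta G}/\Delta\Delta G)^2 +
#' (\sigma_{ref}/\Delta G_{ref})^2}}. A zero \eqn{\Delta\Delta G} returns 0%
#' with the sigma propagated from the absolute term.
#'
#' @param ddG destabilization free energy, kJ/mol.
#' @param refDG reference (duplex-alone) free energy, kJ/mol; non-zero.
#' @param ddGSd,refDGSd 1-sigma errors of the two inputs.
#' @return list with `value` and `sd`, percent.
#' @examples
#' relativeDestabilization(15.2, -67.5, 1.4, 0.6)  # 22.52 +/- 2.08 %
#' @export
relativeDestabilization <- function(ddG, refDG, ddGSd = 0, refDGSd = 0) {
    if (!is.finite(refDG) || refDG == 0)
        stop("reference free energy must be non-zero")
    value <- 100 * ddG / abs(refDG)
    sdv <- if (ddG == 0) 100 * ddGSd / abs(refDG)
           else abs(value) * .quadrature(ddGSd / ddG, refDGSd / refDG)
    list(value = value, sd = sdv)
}

#' Significance stars from an adjusted p-value
#'
#' Step function mapping adjusted p-values to the star annotation used in
#' figure captions: `***` below 0.001, `**` below 0.01, `*` below 0.05,
#' otherwise `ns`.
#'
#' @param p (adjusted) p-value(s).
#' @param alpha decreasing significance thresholds for `*`, `**`, `***`.
#' @return character vector of `ns`/`*`/`**`/`***`.
#' @export
significanceStars <- function(p, alpha = c(0.05, 0.01, 0.001)) {
    alpha <- sort(alpha, decreasing = TRUE)
    vapply(p, function(pi) {
        if (!is.finite(pi)) return(NA_character_)
        if (pi < alpha[3L]) "***"
        else if (pi < alpha[2L]) "**"
        else if (pi < alpha[1L]) "*"
        else "ns"
    }, character(1L))
}

#' One-way ANOVA with Bonferroni-corrected reference contrasts
#'
#' Tests whether per-replicate free energies differ across oligonucleotide
#' pairs: a one-way fixed-effects analysis of variance over all groups,
#' followed by construct-vs-reference contrasts using the pooled residual
#' variance of that ANOVA. Contrast p-values are Bonferroni-adjusted within
#' the family (m = number of construct-vs-reference comparisons, i.e. all
#' contrasts shown together in one figure; `p_adj = min(1, m p)`), and
#' annotated with [significanceStars()].
#'
#' If every value in every group is identical there is nothing to test and
#' all contrasts report p = 1 (`ns`).
#'
#' @param groups named list of numeric vectors (per-replicate delta-G values,
#'   kJ/mol); >= 2 groups with >= 2 replicates each.
#' @param reference name of the reference group (default: first).
#' @param alpha significance thresholds passed to [significanceStars()].
#' @return list with `anovaP` (omnibus p), `m` (family size), and
#'   `comparisons`: a data.frame with group, mean difference vs reference,
#'   t statistic, raw p, Bonferroni `pAdj` and `stars`.
#' @examples
#' g <- list(ref = c(-67, -68, -66), gq = c(-52, -53, -52.5))
#' anovaBonferroni(g)$comparisons
#' @export
anovaBonferroni <- function(groups, reference = names(groups)[1L],
                            alpha = c(0.05, 0.01, 0.001)) {
    if (length(groups) < 2L) stop("need at least 2 groups")
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
        stop("groups must be a named list")
    if (!reference %in% names(groups))
        stop("reference group '", reference, "' not found")
    sizes <- lengths(groups)
    if (any(sizes < 2L))
        stop("every group needs at least 2 replicates; got: ",
             paste(sizes, collapse = ", "))
    values <- unlist(groups, use.names = FALSE)
    labels <- factor(rep(names(groups), sizes), levels = names(groups))
    others <- setdiff(names(groups), reference)
    m <- length(others)
    if (length(unique(values)) == 1L) {
        comp <- data.frame(group = others,
                           diff = 0, t = 0, p = 1, pAdj = 1,
                           stars = "ns", stringsAsFactors = FALSE)
        return(list(anovaP = 1, m = m, comparisons = comp))
    }
    fit <- aov(values ~ labels)
    at <- anova(fit)
    anovaP <- at[["Pr(>F)"]][1L]
    mse <- deviance(fit) / df.residual(fit)
    dfRes <- df.residual(fit)
    mu <- vapply(groups, mean, numeric(1L))
    refMean <- mu[[reference]]
    nRef <- sizes[[reference]]
    comp <- do.call(rbind, lapply(others, function(g) {
        d <- mu[[g]] - refMean
        se <- sqrt(mse * (1 / sizes[[g]] + 1 / nRef))
        tstat <- if (se > 0) d / se else ifelse(d == 0, 0, sign(d) * Inf)
        p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), dfRes)
        data.frame(group = g, diff = d, t = tstat, p = p,
                   pAdj = min(1, m * p), stringsAsFactors = FALSE)
    }))
    comp$stars <- significanceStars(comp$pAdj, alpha)
    list(anovaP = anovaP, m = m, comparisons = comp)
}
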