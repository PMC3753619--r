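# High-level workflow: trace files -> per-pair replicate summaries ->
# destabilization comparisons, driven by the YAML experiment config.

#' Analyze all ramps of one melting trace file
#'
#' Reads a delimited trace, splits it into monotone ramps and runs the full
#' per-curve pipeline (baselines, folded fraction, van't Hoff regression) on
#' each usable ramp.
#'
#' @param path trace CSV/TSV.
#' @param molecularity,CT passed to [vantHoffFit()] (CT in mol/L, total
#'   strand concentration).
#' @param channel optional wide-file signal column name.
#' @param windowFrac,thetaWindow,smoothWindow analysis options.
#' @return list of [VantHoffFit-class], one per ramp.
#' @export
analyzeMeltFile <- function(path, molecularity, CT = NA_real_,
                            channel = NULL, windowFrac = 0.15,
                            thetaWindow = c(0.15, 0.85), smoothWindow = 11L) {
    trace <- readMeltTrace(path, channel = channel)
    curves <- splitRamps(trace)
    lapply(curves, analyzeCurve, molecularity = molecularity, CT = CT,
           windowFrac = windowFrac, thetaWindow = thetaWindow,
           smoothWindow = smoothWindow)
}

.summaryRow <- function(s) {
    data.frame(pair = s@pair, pH = s@pH, n = s@n,
               Tm_C = s@TmMean, Tm_sd = s@TmSd,
               dH_kJ_mol = s@dHMean, dH_sd = s@dHSd,
               dS_J_K_mol = s@dSMean, dS_sd = s@dSSd,
               dG_kJ_mol = s@dGMean, dG_sd = s@dGSd,
               stringsAsFactors = FALSE)
}

#' Run a configured melting experiment
#'
#' For every pair in the configuration: analyze each listed trace file,
#' aggregate the per-ramp fits into a replicate summary, and (where a
#' `reference` is configured) compute the destabilization comparison. Trace
#' paths are resolved relative to `dir`.
#'
#' @param config config list from [readExperimentConfig()], or a path to the
#'   YAML file.
#' @param dir base directory for relative trace paths.
#' @return list with `summaries` (data.frame, one row per pair),
#'   `comparisons` (data.frame from [compareStability()], possibly empty),
#'   `summaryObjects` (named list of [ThermoSummary-class]) and `fits`
#'   (named list of per-pair fit lists).
#' @export
runExperiment <- function(config, dir = ".") {
    if (is.character(config)) config <- readExperimentConfig(config)
    opts <- config$options
    summaries <- list()
    fits <- list()
    for (p in config$pairs) {
        if (is.null(p$traces) || !length(p$traces))
            stop("pair '", p$label, "' lists no trace files")
        paths <- file.path(dir, p$traces)
        ct <- if (identical(p$molecularity, "bimolecular"))
            2 * as.numeric(p$strand_concentration) else NA_real_
        pairFits <- unlist(lapply(paths, analyzeMeltFile,
                                  molecularity = p$molecularity, CT = ct,
                                  channel = p$channel,
                                  windowFrac = opts$window_frac,
                                  thetaWindow = opts$theta_window,
                                  smoothWindow = opts$smooth_window),
                           recursive = FALSE)
        summaries[[p$label]] <- aggregateReplicates(pairFits, p$label,
                                                    as.numeric(p$pH %||% NA))
        fits[[p$label]] <- pairFits
    }
    refMap <- vapply(config$pairs, function(p) p$reference %||% NA_character_, "")
    names(refMap) <- vapply(config$pairs, `[[`, "", "label")
    comparisons <- compareStability(summaries, refMap)
    list(summaries = do.call(rbind, lapply(summaries, .summaryRow)),
         comparisons = comparisons, summaryObjects = summaries, fits = fits)
}

#' Destabilization comparisons against reference pairs
#'
#' Computes delta-delta-G, delta-Tm and relative destabilization (with
#' quadrature 1-sigma errors) for every construct with a configured
#' reference, and -- when per-replicate delta-G values are available --
#' Bonferroni-corrected significance from a one-way ANOVA. Constructs
#' sharing a reference form one Bonferroni family.
#'
#' @param summaries named list of [ThermoSummary-class] objects.
#' @param referenceMap named character vector mapping each construct label
#'   to its reference label (`NA` for reference pairs themselves), or a
#'   single label naming one reference for all other summaries.
#' @return data.frame with one row per compared construct: `pair`,
#'   `reference`, `pH`, `dTm_C`, `dTm_sd`, `ddG_kJ_mol`, `ddG_sd`,
#'   `rel_destab_pct`, `rel_destab_sd`, `p_adj`, `stars`.
#' @examples
#' ref <- thermoSummary("duplex", 7.4, 3, Tm = 58.6, TmSd = 0.7,
#'                      dG = -67.5, dGSd = 1.7)
#' con <- thermoSummary("duplex+G4", 7.4, 3, Tm = 52.7, TmSd = 2.5,
#'                      dG = -52.7, dGSd = 3.4)
#' compareStability(list(duplex = ref, `duplex+G4` = con), "duplex")
#' @export
compareStability <- function(summaries, referenceMap) {
    stopifnot(is.list(summaries), length(summaries) >= 1L)
    labels <- names(summaries)
    if (length(referenceMap) == 1L && is.null(names(referenceMap))) {
        ref <- referenceMap
        referenceMap <- ifelse(labels == ref, NA_character_, ref)
        names(referenceMap) <- labels
    }
    bad <- setdiff(stats::na.omit(unique(referenceMap)), labels)
    if (length(bad))
        stop("reference label(s) not found among summaries: ",
             paste(bad, collapse = ", "))
    rows <- list()
    # one Bonferroni family per reference pair
    for (ref in stats::na.omit(unique(referenceMap))) {
        members <- names(referenceMap)[!is.na(referenceMap) & referenceMap == ref]
        refSum <- summaries[[ref]]
        groups <- list()
        if (length(refSum@dGValues) >= 2L) groups[[ref]] <- refSum@dGValues
        for (lab in members) {
            v <- summaries[[lab]]@dGValues
            if (length(v) >= 2L) groups[[lab]] <- v
        }
        stat <- if (length(groups) >= 2L && ref %in% names(groups))
            anovaBonferroni(groups, reference = ref) else NULL
        for (lab in members) {
            conSum <- summaries[[lab]]
            dd <- deltaDeltaG(refSum, conSum)
            dt <- deltaTm(refSum, conSum)
            rel <- if (is.finite(refSum@dGMean) && refSum@dGMean != 0)
                relativeDestabilization(dd$value, refSum@dGMean, dd$sd,
                                        refSum@dGSd)
            else list(value = NA_real_, sd = NA_real_)
            padj <- NA_real_
            star <- NA_character_
            if (!is.null(stat) && lab %in% stat$comparisons$group) {
                i <- match(lab, stat$comparisons$group)
                padj <- stat$comparisons$pAdj[i]
                star <- stat$comparisons$stars[i]
            }
            rows[[length(rows) + 1L]] <- data.frame(
                pair = lab, reference = ref, pH = conSum@pH,
                dTm_C = dt$value, dTm_sd = dt$sd,
                ddG_kJ_mol = dd$value, ddG_sd = dd$sd,
                rel_destab_pct = rel$value, rel_destab_sd = rel$sd,
                p_adj = padj, stars = star, stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(pair = character(), reference = character(),
                          pH = numeric(), dTm_C = numeric(),
                          dTm_sd = numeric(), ddG_kJ_mol = numeric(),
                          ddG_sd = numeric(), rel_destab_pct = numeric(),
                          rel_destab_sd = numeric(), p_adj = numeric(),
                          stars = character(), stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Write the per-pair summary / comparison tables as TSV
#'
#' Column layout mirrors how melting studies tabulate results: pair, pH, n,
#' Tm and delta-Tm in degC, delta-H in kJ/mol, delta-S in J/K/mol, delta-G
#' and delta-delta-G at 298.15 K in kJ/mol, each with its 1-sigma column.
#'
#' @param table data.frame (`summaries` or `comparisons` from
#'   [runExperiment()]).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeResultTSV <- function(table, path) {
    write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Generate trace files from the config's simulation block
#'
#' For every pair carrying a `simulate` entry (with `delta_H` kJ/mol,
#' `delta_S` J/K/mol and optional `n_replicates`, `noise_sigma`,
#' `t_start`/`t_end`/`step`), writes `n_replicates` cool-heat-cool trace
#' CSVs named `<label>_rep<i>.csv` into `outDir` and fills the pair's
#' `traces` field. Deterministic given `seed`.
#'
#' @param config config list or YAML path (see [readExperimentConfig()]).
#' @param outDir output directory (created if needed).
#' @param seed integer seed for the noise generator.
#' @return the updated config (with `traces` filled), invisibly usable with
#'   [runExperiment()].
#' @export
simulateFromConfig <- function(config, outDir, seed = 1L) {
    if (is.character(config)) config <- readExperimentConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    for (i in seq_along(config$pairs)) {
        p <- config$pairs[[i]]
        sim <- p$simulate
        if (is.null(sim)) next
        if (is.null(sim$delta_H) || is.null(sim$delta_S))
            stop("config error: pairs[", i, "] ('", p$label,
                 "'): simulate needs delta_H and delta_S")
        ct <- if (identical(p$molecularity, "bimolecular"))
            2 * as.numeric(p$strand_concentration) else NA_real_
        params <- ThermoParams(as.numeric(sim$delta_H),
                               as.numeric(sim$delta_S),
                               p$molecularity, CT = ct)
        nrep <- as.integer(sim$n_replicates %||% 3L)
        files <- character(nrep)
        for (r in seq_len(nrep)) {
            tr <- simulateMeltTrace(params,
                Trange = c(as.numeric(sim$t_start %||% 10),
                           as.numeric(sim$t_end %||% 90)),
                step = as.numeric(sim$step %||% 0.25),
                noiseSigma = as.numeric(sim$noise_sigma %||% 0))
            f <- sprintf("%s_rep%d.csv", gsub("[^A-Za-z0-9._-]", "_", p$label), r)
            writeMeltTrace(tr, file.path(outDir, f))
            files[r] <- f
        }
        config$pairs[[i]]$traces <- files
    }
    invisible(config)
}
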