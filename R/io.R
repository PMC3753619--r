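# File formats: delimited melting traces, FASTA/plain-text oligo
# registries, motif hit TSV/BED, fit JSON and the YAML experiment config.
# All temperatures degC, energies kJ/mol, entropies J/K/mol.

.traceSep <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read a delimited melting trace
#'
#' Reads a CSV/TSV trace with a `temperature` column (degC; `temp` and `T`
#' are accepted) and a `signal` column, plus optional `ramp`, `channel` and
#' `replicate` columns. Wide files carrying several signal channels (e.g.
#' `A260` and `A295` columns) are accepted: pick one with `channel`.
#'
#' @param path file path (`.tsv` is tab-separated, anything else
#'   comma-separated).
#' @param channel optional name of the signal column to use when the file is
#'   wide (defaults to the `signal` column).
#' @return data.frame with columns `temperature`, `signal` and any extra
#'   columns present.
#' @export
readMeltTrace <- function(path, channel = NULL) {
    if (!file.exists(path)) stop("trace file not found: ", path)
    df <- tryCatch(
        read.table(path, header = TRUE, sep = .traceSep(path),
                   stringsAsFactors = FALSE, check.names = FALSE),
        error = function(e) stop("malformed trace file '", path, "': ",
                                 conditionMessage(e)))
    if (!nrow(df)) stop("trace file '", path, "' contains no data rows")
    nm <- tolower(names(df))
    ti <- match(TRUE, nm %in% c("temperature", "temp", "t"))
    if (is.na(ti)) stop("trace file '", path, "' lacks a temperature column")
    if (is.null(channel)) {
        si <- match("signal", nm)
        if (is.na(si))
            stop("trace file '", path, "' lacks a 'signal' column; for wide ",
                 "files name the channel column via the 'channel' argument")
    } else {
        si <- match(tolower(channel), nm)
        if (is.na(si))
            stop("trace file '", path, "' has no column '", channel, "'")
    }
    out <- df
    names(out)[ti] <- "temperature"
    names(out)[si] <- "signal"
    out$temperature <- as.numeric(out$temperature)
    out$signal <- as.numeric(out$signal)
    if (anyNA(out$temperature) || anyNA(out$signal))
        stop("trace file '", path, "' contains non-numeric temperature/signal values")
    out
}

#' Write a melting trace to CSV/TSV
#'
#' Writes the column layout [readMeltTrace()] reads back.
#'
#' @param trace data.frame with `temperature` and `signal` (plus optional
#'   `ramp` etc.) or a [MeltCurve-class].
#' @param path output path; `.tsv` gives tab separation.
#' @return the path, invisibly.
#' @export
writeMeltTrace <- function(trace, path) {
    if (is(trace, "MeltCurve"))
        trace <- data.frame(temperature = trace@temperature,
                            signal = trace@signal)
    stopifnot(all(c("temperature", "signal") %in% names(trace)))
    write.table(trace, path, sep = .traceSep(path), row.names = FALSE,
                quote = FALSE)
    invisible(path)
}

#' Read an oligonucleotide registry
#'
#' FASTA (via Biostrings) or plain text with one sequence per line
#' (optionally `name<TAB>sequence`). Names must be unique; sequences are
#' validated against the strict ACGT alphabet. Extinction coefficients are
#' computed additively where not supplied.
#'
#' @param path FASTA (`.fa`, `.fasta`) or plain-text file.
#' @return data.frame with columns `name`, `sequence`, `epsilon`.
#' @export
readOligos <- function(path) {
    if (!file.exists(path)) stop("oligo file not found: ", path)
    if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
        ss <- Biostrings::readDNAStringSet(path)
        nm <- names(ss)
        seqs <- as.character(ss)
    } else {
        lines <- readLines(path)
        lines <- lines[nzchar(trimws(lines))]
        parts <- strsplit(lines, "\t")
        has2 <- lengths(parts) >= 2L
        nm <- ifelse(has2, vapply(parts, `[`, "", 1L),
                     paste0("seq", seq_along(lines)))
        seqs <- ifelse(has2, vapply(parts, `[`, "", 2L),
                       vapply(parts, `[`, "", 1L))
    }
    if (!length(seqs)) {
        return(data.frame(name = character(), sequence = character(),
                          epsilon = numeric(), stringsAsFactors = FALSE))
    }
    if (anyDuplicated(nm)) stop("duplicate oligo names in ", path)
    seqs <- vapply(seqs, .validDNA, "", USE.NAMES = FALSE)
    data.frame(name = nm, sequence = seqs,
               epsilon = vapply(seqs, extinctionCoefficient, 0,
                                USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
}

#' Write an oligonucleotide registry as FASTA
#'
#' @param oligos data.frame with `name` and `sequence` columns.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
writeOligosFasta <- function(oligos, path) {
    stopifnot(all(c("name", "sequence") %in% names(oligos)))
    ss <- Biostrings::DNAStringSet(oligos$sequence)
    names(ss) <- oligos$name
    Biostrings::writeXStringSet(ss, path)
    invisible(path)
}

#' Scan an oligo registry for quadruplex and i-motif motifs
#'
#' Runs [scanQuadruplex()] and/or [scanImotif()] over every sequence of a
#' registry, filling the `seqname` column of the hits.
#'
#' @param oligos data.frame with `name` and `sequence` (e.g. from
#'   [readOligos()] or [referenceOligos()]).
#' @param motif `"G4"`, `"IM"` or `"both"`.
#' @param ... scanner parameters passed through (`minRun`, `loopMin`,
#'   `loopMax`, `nRuns`, `allOverlaps`).
#' @return data.frame of hits across all sequences (possibly zero rows).
#' @examples
#' scanOligoSet(referenceOligos(), "G4")
#' @export
scanOligoSet <- function(oligos, motif = c("both", "G4", "IM"), ...) {
    motif <- match.arg(motif)
    stopifnot(all(c("name", "sequence") %in% names(oligos)))
    res <- lapply(seq_len(nrow(oligos)), function(i) {
        hits <- list()
        if (motif %in% c("both", "G4"))
            hits <- c(hits, list(scanQuadruplex(oligos$sequence[i], ...)))
        if (motif %in% c("both", "IM"))
            hits <- c(hits, list(scanImotif(oligos$sequence[i], ...)))
        h <- do.call(rbind, hits)
        if (nrow(h)) h$seqname <- oligos$name[i]
        h
    })
    do.call(rbind, res)
}

#' Write motif hits as BED or 1-based TSV
#'
#' BED uses 0-based half-open coordinates with the oligo name as the
#' chromosome field; the TSV keeps the package's 1-based inclusive
#' coordinates and adds run/loop decompositions as comma-separated lists.
#'
#' @param hits data.frame from [scanQuadruplex()]/[scanOligoSet()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMotifBED <- function(hits, path) {
    bed <- data.frame(chrom = hits$seqname,
                      chromStart = hits$start - 1L,  # 0-based half-open
                      chromEnd = hits$end,
                      name = hits$motifClass,
                      stringsAsFactors = FALSE)
    write.table(bed, path, sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    invisible(path)
}

#' @rdname writeMotifBED
#' @export
writeMotifTSV <- function(hits, path) {
    flat <- data.frame(seqname = hits$seqname, motifClass = hits$motifClass,
                       start = hits$start, end = hits$end,
                       width = hits$width, nRuns = hits$nRuns,
                       runLengths = vapply(hits$runLengths, paste,
                                           "", collapse = ","),
                       loopLengths = vapply(hits$loopLengths, paste,
                                            "", collapse = ","),
                       stringsAsFactors = FALSE)
    write.table(flat, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read and validate a YAML experiment configuration
#'
#' The configuration binds the pipeline together. Top-level keys:
#' \describe{
#'   \item{pairs}{list of entries with `label`, `molecularity`
#'     (`unimolecular`/`bimolecular`), `strand_concentration` (mol/L per
#'     strand; total concentration is twice this), `pH`, `traces` (vector of
#'     trace file paths) and optional `reference` (label of the reference
#'     pair) plus `top`/`bottom` oligo names.}
#'   \item{options}{optional analysis options: `window_frac`,
#'     `theta_window` (2 values), `smooth_window`.}
#'   \item{simulate}{optional per-pair generator settings used by
#'     [simulateFromConfig()]: `delta_H`, `delta_S`, `n_replicates`,
#'     `noise_sigma`.}
#' }
#'
#' @param path YAML file.
#' @return validated config as a nested list, with defaults filled in.
#' @export
readExperimentConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$pairs) || !length(cfg$pairs))
        stop("config error: 'pairs' is missing or empty")
    labels <- vapply(cfg$pairs, function(p) p$label %||% "", "")
    if (any(!nzchar(labels))) stop("config error: every pair needs a 'label'")
    if (anyDuplicated(labels)) stop("config error: duplicate pair labels")
    for (i in seq_along(cfg$pairs)) {
        p <- cfg$pairs[[i]]
        if (is.null(p$molecularity) ||
            !p$molecularity %in% c("unimolecular", "bimolecular"))
            stop("config error: pairs[", i, "] ('", p$label,
                 "'): molecularity must be 'unimolecular' or 'bimolecular'")
        if (identical(p$molecularity, "bimolecular")) {
            sc <- p$strand_concentration
            if (is.null(sc) || !is.finite(as.numeric(sc)) || as.numeric(sc) <= 0)
                stop("config error: pairs[", i, "] ('", p$label,
                     "'): strand_concentration (mol/L per strand) must be > 0")
        }
        if (!is.null(p$reference) && !p$reference %in% labels)
            stop("config error: pairs[", i, "] ('", p$label,
                 "'): reference '", p$reference, "' does not match any pair label")
    }
    cfg$options <- cfg$options %||% list()
    cfg$options$window_frac <- cfg$options$window_frac %||% 0.15
    cfg$options$theta_window <- cfg$options$theta_window %||% c(0.15, 0.85)
    cfg$options$smooth_window <- cfg$options$smooth_window %||% 11L
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-curve fits as JSON
#'
#' Machine-readable record of a set of van't Hoff fits: parameters, melting
#' temperatures, free energy, regression diagnostics and analysis warnings.
#'
#' @param fits list of [VantHoffFit-class] objects.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeFitsJSON <- function(fits, path) {
    rec <- lapply(fits, function(f) list(
        molecularity = f@params@molecularity,
        CT = f@params@CT,
        deltaH_kJ_mol = f@params@deltaH,
        deltaS_J_K_mol = f@params@deltaS,
        deltaG_std_kJ_mol = f@deltaG,
        Tm_obs_C = f@TmObs,
        Tm_deriv_C = f@TmDeriv,
        r_squared = f@rSquared,
        theta_window = f@thetaWindow,
        n_points = f@nPoints,
        warnings = f@notes))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
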