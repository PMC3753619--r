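test_that("melting traces round-trip through CSV and TSV", {
    tr <- data.frame(temperature = seq(20, 40, 0.5),
                     signal = runif(41), ramp = 1L)
    csv <- withr::local_tempfile(fileext = ".csv")
    writeMeltTrace(tr, csv)
    back <- readMeltTrace(csv)
    expect_equal(back$temperature, tr$temperature)
    expect_equal(back$signal, tr$signal, tolerance = 1e-12)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeMeltTrace(tr, tsv)
    expect_equal(readMeltTrace(tsv)$signal, tr$signal, tolerance = 1e-12)
    # wide multi-channel file: select a channel column
    wide <- data.frame(temperature = tr$temperature, A260 = tr$signal,
                       A295 = rev(tr$signal))
    w <- withr::local_tempfile(fileext = ".csv")
    write.csv(wide, w, row.names = FALSE)
    expect_equal(readMeltTrace(w, channel = "A295")$signal, rev(tr$signal),
                 tolerance = 1e-12)
    expect_error(readMeltTrace(w), "signal")
    empty <- withr::local_tempfile(fileext = ".csv")
    writeLines("temperature,signal", empty)
    expect_error(readMeltTrace(empty), "no data rows")
    expect_error(readMeltTrace("no/such/file.csv"), "not found")
})

test_that("oligo registries round-trip through FASTA and plain text", {
    oli <- referenceOligos()[1:5, ]
    fa <- withr::local_tempfile(fileext = ".fasta")
    writeOligosFasta(oli, fa)
    back <- readOligos(fa)
    expect_identical(back$name, oli$name)
    expect_identical(back$sequence, oli$sequence)
    expect_true(all(is.finite(back$epsilon)))
    txt <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("top1\tGGCGCGCAGA", "bottom1\tTCTGCGCGCC"), txt)
    pt <- readOligos(txt)
    expect_identical(pt$name, c("top1", "bottom1"))
    dup <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("a\tACGT", "a\tACGT"), dup)
    expect_error(readOligos(dup), "duplicate")
})

test_that("registry scanning finds motifs exactly in the overhang constructs", {
    oli <- referenceOligos()
    g4 <- scanOligoSet(oli, "G4")
    expect_setequal(unique(g4$seqname),
                    c("top1::GQ1", "top1::GQ2", "top2::GQ2", "GQ2::bottom2"))
    expect_true(all(table(g4$seqname) == 1))
    im <- scanOligoSet(oli, "IM")
    expect_true(all(c("top2::IM", "IM::bottom2") %in% im$seqname))
    expect_false("top1" %in% c(g4$seqname, im$seqname))
    # GQ1 overhang location within top1::GQ1 (after the 10 nt duplex arm)
    h <- g4[g4$seqname == "top1::GQ1", ]
    expect_identical(h$start, 11L)
    expect_identical(h$end, 28L)
})

test_that("motif hits serialize to BED (0-based half-open) and TSV (1-based)", {
    hits <- scanOligoSet(referenceOligos(), "G4")
    bed <- withr::local_tempfile(fileext = ".bed")
    writeMotifBED(hits, bed)
    b <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
    i <- match("top1::GQ1", b$V1)
    expect_identical(b$V2[i], 10L)   # 0-based start
    expect_identical(b$V3[i], 28L)   # half-open end
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeMotifTSV(hits, tsv)
    t <- read.table(tsv, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    j <- match("top1::GQ1", t$seqname)
    expect_identical(t$start[j], 11L)  # 1-based inclusive
    expect_identical(t$runLengths[j], "3,3,3,3")
})

test_that("experiment configs are validated with field-level errors", {
    writeCfg <- function(txt) {
        f <- tempfile(fileext = ".yaml")
        writeLines(txt, f)
        f
    }
    good <- writeCfg(c(
        "pairs:",
        "  - label: ref",
        "    molecularity: bimolecular",
        "    strand_concentration: 3.0e-6",
        "    pH: 7.4",
        "    traces: [ref_rep1.csv]",
        "  - label: gq",
        "    molecularity: bimolecular",
        "    strand_concentration: 3.0e-6",
        "    pH: 7.4",
        "    reference: ref",
        "    traces: [gq_rep1.csv]"))
    cfg <- readExperimentConfig(good)
    expect_identical(length(cfg$pairs), 2L)
    expect_identical(cfg$options$theta_window, c(0.15, 0.85))
    badRef <- writeCfg(c(
        "pairs:",
        "  - label: gq",
        "    molecularity: bimolecular",
        "    strand_concentration: 3.0e-6",
        "    reference: nothere"))
    expect_error(readExperimentConfig(badRef), "nothere")
    badMol <- writeCfg(c(
        "pairs:",
        "  - label: gq",
        "    molecularity: trimolecular"))
    expect_error(readExperimentConfig(badMol), "molecularity")
    expect_error(readExperimentConfig(writeCfg("options: {}")), "pairs")
})

test_that("simulate -> analyze -> compare round trip flags the quadruplex construct only", {
    cfgFile <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c(
        "pairs:",
        "  - label: duplex",
        "    molecularity: bimolecular",
        "    strand_concentration: 3.0e-6",
        "    pH: 7.4",
        "    simulate: {delta_H: -336.4, delta_S: -902.0, n_replicates: 3, noise_sigma: 3.0e-4}",
        "  - label: duplex+G4",
        "    molecularity: bimolecular",
        "    strand_concentration: 3.0e-6",
        "    pH: 7.4",
        "    reference: duplex",
        "    simulate: {delta_H: -213.8, delta_S: -547.0, n_replicates: 3, noise_sigma: 3.0e-4}",
        "  - label: control",
        "    molecularity: bimolecular",
        "    strand_concentration: 3.0e-6",
        "    pH: 7.4",
        "    reference: duplex",
        "    simulate: {delta_H: -336.4, delta_S: -902.0, n_replicates: 3, noise_sigma: 3.0e-4}"),
        cfgFile)
    outDir <- withr::local_tempdir()
    cfg <- simulateFromConfig(cfgFile, outDir, seed = 20260929)
    # deterministic: same seed writes byte-identical traces
    outDir2 <- withr::local_tempdir()
    simulateFromConfig(cfgFile, outDir2, seed = 20260929)
    f1 <- file.path(outDir, "duplex_rep1.csv")
    expect_identical(readLines(f1),
                     readLines(file.path(outDir2, "duplex_rep1.csv")))
    res <- runExperiment(cfg, dir = outDir)
    expect_identical(nrow(res$summaries), 3L)
    expect_true(all(res$summaries$n == 9L))  # 3 files x 3 ramps
    expect_true(all(is.finite(res$summaries$dG_sd)))
    cmp <- res$comparisons
    gq <- cmp[cmp$pair == "duplex+G4", ]
    expect_equal(gq$ddG_kJ_mol, 16.8, tolerance = 0.05)
    expect_identical(gq$stars, "***")
    ctl <- cmp[cmp$pair == "control", ]
    expect_lt(abs(ctl$ddG_kJ_mol), 0.5)
    expect_identical(ctl$stars, "ns")
    # tables serialize to TSV with the documented headers
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeResultTSV(res$summaries, tsv)
    back <- read.table(tsv, sep = "\t", header = TRUE)
    expect_identical(names(back)[1:4], c("pair", "pH", "n", "Tm_C"))
    # fit JSON is valid and carries the thermodynamic fields
    js <- withr::local_tempfile(fileext = ".json")
    writeFitsJSON(res$fits$duplex, js)
    rec <- jsonlite::read_json(js)
    expect_identical(length(rec), 9L)
    expect_lt(abs(rec[[1]]$deltaH_kJ_mol + 336.4) / 336.4, 0.02)
})

test_that("a single-ramp trace analyzes with an n = 1 warning", {
    p <- ThermoParams(-336.4, -902.0, "bimolecular", CT = 6e-6)
    f <- withr::local_tempfile(fileext = ".csv")
    writeMeltTrace(simulateCurve(p), f)
    fits <- analyzeMeltFile(f, "bimolecular", CT = 6e-6)
    expect_identical(length(fits), 1L)
    expect_warning(s <- aggregateReplicates(fits, "solo", 7.4),
                   "single replicate")
    expect_identical(s@n, 1L)
})

test_that("comparisons from tabulated summaries need no raw curves", {
    tab <- referenceThermoTable()
    mk <- function(i) thermoSummary(tab$pair[i], tab$pH[i], 3,
                                    Tm = tab$Tm[i], TmSd = tab$TmSd[i],
                                    dG = tab$dG[i], dGSd = tab$dGSd[i])
    sums <- list(ref = mk(1), gq2 = mk(3))
    cmp <- compareStability(sums, "ref")
    expect_equal(cmp$ddG_kJ_mol, 16.8, tolerance = 1e-9)
    expect_equal(cmp$dTm_C, 7.2, tolerance = 1e-9)
    expect_true(is.na(cmp$p_adj))  # no per-replicate values available
    expect_error(compareStability(sums, "missing"), "not found")
})
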