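# Bundled reference data for the c-kit promoter duplex system with
# telomeric G-quadruplex (GQ1/GQ2) and bcl-2 Py39WT i-motif (IM) overhangs:
# the oligonucleotide registry and the tabulated replicate-level melting
# thermodynamics used throughout examples, tests and the acceptance script.

#' Oligonucleotide registry of the c-kit duplex destabilization study
#'
#' The duplex strands derive from a c-kit promoter fragment (top1 and a
#' TA-rich variant top2) with their complements (bottom1/bottom2) and
#' mismatch series; overhang constructs append a human-telomere-type
#' quadruplex (GQ1, (G3T2)3G3), a Tetrahymena-telomere-type quadruplex
#' (GQ2, (G4T2)3G4), the bcl-2 Py39WT i-motif sequence (IM) or poly(T)
#' controls. `epsilon` is the tabulated single-strand extinction coefficient
#' at 260 nm (mM^-1 cm^-1).
#'
#' @return data.frame with columns `name`, `sequence` (5' to 3', ACGT) and
#'   `epsilon`.
#' @examples
#' oli <- referenceOligos()
#' subset(oli, name == "top1")$sequence
#' @export
referenceOligos <- function() {
    gq1 <- "GGGTTGGGTTGGGTTGGG"
    gq2 <- "GGGGTTGGGGTTGGGGTTGGGG"
    im  <- "CAGCCCCGCTCCCGCCCCCTTCCTCCCGCGCCCGCCCCT"
    top1 <- "GGCGCGCAGA"
    top2 <- "GGCGCGCATAAAA"
    data.frame(
        name = c("top1", "top1::GQ1", "top1::GQ2",
                 "top1::poly(T)1", "top1::poly(T)2", "top1::poly(T)3",
                 "bottom1", "bottom1-1MM", "bottom1-2MM", "bottom1-3MM",
                 "top2", "top2::GQ2", "top2::IM",
                 "bottom2", "bottom2-1MM", "bottom2-2MM", "bottom2-3MM",
                 "bottom2-4MM", "bottom2-5MM", "bottom2-6MM",
                 "GQ2::bottom2", "IM::bottom2"),
        sequence = c(top1, paste0(top1, gq1), paste0(top1, gq2),
                     paste0(top1, strrep("T", 22)),
                     paste0(top1, strrep("T", 10)),
                     paste0(top1, strrep("T", 27)),
                     "TCTGCGCGCC", "ACTGCGCGCC", "ATTGCGCGCC", "ATAGCGCGCC",
                     top2, paste0(top2, gq2), paste0(top2, im),
                     "TTTTATGCGCGCC", "ATTTATGCGCGCC", "AATTATGCGCGCC",
                     "AAATATGCGCGCC", "AAAAATGCGCGCC", "AAAATTGCGCGCC",
                     "AAAATAGCGCGCC",
                     paste0(gq2, "TTTTATGCGCGCC"),
                     "TCCCCGCCCGCGCCCTCCTTCCCCCGCCCTCGCCCCGACTTTTATGCGCGCC"),
        epsilon = c(108.9, 292.3, 335.7, 303.5, 197.5, 347.7,
                    88.8, 95.7, 96.9, 103.8,
                    154.2, 380.9, 487.5,
                    123.4, 130.3, 137.2, 144.1, 151.0, 144.1, 151.0,
                    350.2, 456.8),
        stringsAsFactors = FALSE)
}

#' Tabulated melting thermodynamics of the reference duplex system
#'
#' Replicate means and 1-sigma errors of the UV melting analysis of the
#' c-kit-derived duplexes with and without adjacent four-stranded
#' structures: experimental Tm (degC), van't Hoff delta-H (kJ/mol), delta-S
#' (J/K/mol), delta-G at 298.15 K (kJ/mol), and the published
#' delta-Tm/delta-delta-G columns against each row's reference pair.
#' Measurements were performed in triplicate at 3 uM per strand (total
#' strand concentration 6 uM).
#'
#' The `top1::GQ1` row is internally inconsistent as tabulated (its
#' delta-H/delta-S imply a delta-G near -77.8 kJ/mol rather than the listed
#' -52.7) and carries `consistent = FALSE`; it is excluded from
#' thermodynamic consistency checks but its delta-G/delta-delta-G columns
#' are self-consistent and retained.
#'
#' @return data.frame with columns `pair`, `reference`, `pH`, `Tm`, `TmSd`,
#'   `dTm`, `dTmSd`, `dH`, `dHSd`, `dS`, `dSSd`, `dG`, `dGSd`, `ddG`,
#'   `ddGSd`, `consistent`.
#' @export
referenceThermoTable <- function() {
    df <- data.frame(
        pair = c("top1/bottom1", "top1::GQ1/bottom1", "top1::GQ2/bottom1",
                 "top1::poly(T)1/bottom1", "top2/bottom2",
                 "top2::GQ2/bottom2", "top2/bottom2", "top2::IM/bottom2"),
        reference = c(NA, "top1/bottom1", "top1/bottom1", "top1/bottom1",
                      NA, "top2/bottom2", NA, "top2/bottom2"),
        pH   = c(7.4, 7.4, 7.4, 7.4, 7.4, 7.4, 4.0, 4.0),
        Tm   = c(58.6, 52.7, 51.4, 56.9, 54.3, 49.9, 39.4, 35.2),
        TmSd = c(0.7, 2.5, 1.8, 0.7, 0.5, 0.3, 0.9, 0.8),
        dTm  = c(NA, 5.9, 7.2, 1.7, NA, 4.4, NA, 4.1),
        dTmSd = c(NA, 2.6, 1.9, 1.0, NA, 0.6, NA, 1.2),
        dH   = c(-336.4, -252.2, -213.8, -332.8, -381.2, -245.7, -254.9, -254.0),
        dHSd = c(11.5, 56.6, 11.0, 12.1, 7.4, 14.6, 16.5, 2.1),
        dS   = c(-902.0, -585.0, -547.0, -896.7, -1052.3, -648.8, -703.9, -720.7),
        dSSd = c(32.9, 98.2, 34.8, 36.4, 23.5, 44.8, 51.9, 4.3),
        dG   = c(-67.5, -52.7, -50.7, -65.5, -67.5, -52.3, -45.1, -39.0),
        dGSd = c(1.7, 3.4, 1.3, 1.4, 0.6, 1.2, 1.2, 1.0),
        ddG  = c(NA, 14.8, 16.8, 2.0, NA, 15.2, NA, 6.0),
        ddGSd = c(NA, 3.8, 2.2, 2.2, NA, 1.4, NA, 1.6),
        stringsAsFactors = FALSE)
    df$consistent <- df$pair != "top1::GQ1/bottom1"
    df
}

#' Tabulated pH dependence of quadruplex/i-motif destabilization
#'
#' Absolute (`ddG`, kJ/mol) and relative (`rel`, percent of the duplex-alone
#' stability) destabilization of the top2/bottom2 duplex by the adjacent
#' GQ2 quadruplex and Py39WT i-motif across pH, with 1-sigma errors. The
#' duplex-alone reference free energy needed to recompute `rel` is available
#' in [referenceThermoTable()] for pH 4.0 and 7.4.
#'
#' @return data.frame with columns `construct`, `pH`, `ddG`, `ddGSd`, `rel`,
#'   `relSd`.
#' @export
referenceDestabTable <- function() {
    data.frame(
        construct = c(rep("top2::GQ2/bottom2", 6L), rep("top2::IM/bottom2", 2L)),
        pH    = c(4.0, 4.4, 5.0, 5.4, 5.9, 7.4, 4.0, 4.4),
        ddG   = c(9.6, 12.8, 16.1, 17.5, 15.5, 15.2, 6.0, 3.8),
        ddGSd = c(1.3, 1.4, 1.3, 1.5, 1.3, 1.4, 1.6, 2.2),
        rel   = c(21.28, 24.06, 25.39, 26.52, 23.31, 22.52, 13.3, 7.14),
        relSd = c(2.94, 2.68, 2.08, 2.32, 1.98, 2.08, 3.57, 4.14),
        stringsAsFactors = FALSE)
}
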