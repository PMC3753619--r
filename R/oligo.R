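# Sequence-level utilities: validation, complementarity, extinction
# coefficients and putative quadruplex / i-motif scanning.

# Validate and normalise a DNA sequence: uppercase, whitespace stripped,
# strict ACGT alphabet (U and IUPAC ambiguity codes are rejected).
.validDNA <- function(seq, allowEmpty = FALSE) {
    if (!is.character(seq) || length(seq) != 1L || is.na(seq))
        stop("sequence must be a single character string")
    s <- toupper(gsub("[[:space:]]", "", seq))
    if (!nzchar(s)) {
        if (allowEmpty) return(s)
        stop("empty sequence")
    }
    if (grepl("[^ACGT]", s)) {
        bad <- unique(strsplit(gsub("[ACGT]", "", s), "")[[1L]])
        stop("sequence contains characters outside the ACGT alphabet: ",
             paste(bad, collapse = ", "),
             " (U and IUPAC ambiguity codes are not accepted)")
    }
    s
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed (an involution). Strictly ACGT; the
#' underlying operation is delegated to Biostrings.
#'
#' @param seq a single DNA string over ACGT (whitespace is ignored).
#' @return the reverse complement, 5' to 3'.
#' @examples
#' revComp("GGCGCGCAGA")   # "TCTGCGCGCC"
#' @export
revComp <- function(seq) {
    s <- .validDNA(seq)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Count mismatched positions in a duplex
#'
#' Aligns `bottom` (5' to 3') against `top` in antiparallel orientation and
#' counts positions that are not Watson-Crick pairs; 0 means a perfect
#' duplex. Strands must have equal length (the paired region).
#'
#' @param top,bottom DNA strings over ACGT, both written 5' to 3'.
#' @return integer number of non-Watson-Crick positions.
#' @examples
#' countMismatches("GGCGCGCAGA", "TCTGCGCGCC")  # 0
#' countMismatches("GGCGCGCAGA", "ATAGCGCGCC")  # 3
#' @export
countMismatches <- function(top, bottom) {
    t <- .validDNA(top)
    b <- .validDNA(bottom)
    if (nchar(t) != nchar(b))
        stop("strands differ in length (", nchar(t), " vs ", nchar(b),
             "); pair the complementary region only")
    sum(strsplit(t, "")[[1L]] != strsplit(revComp(b), "")[[1L]])
}

#' Default monomer extinction coefficients at 260 nm
#'
#' Classical nucleoside-5'-monophosphate molar absorptivities at 260 nm in
#' mM^-1 cm^-1, used for the additive (base-composition) estimate of
#' single-strand extinction coefficients. Override via the `table` argument
#' of [extinctionCoefficient()] to use a lab-specific set.
#'
#' @return named numeric vector with entries A, C, G, T.
#' @export
defaultEpsilonTable <- function()
    c(A = 15.4, C = 7.4, G = 11.5, T = 8.7)

#' Additive extinction coefficient of an unpaired oligonucleotide
#'
#' Sum of monomer coefficients over the sequence (strictly additive under
#' concatenation). The additive estimate ignores nearest-neighbour
#' hypochromicity and is accurate to a few percent for short unstructured
#' oligonucleotides.
#'
#' @param seq DNA string over ACGT.
#' @param table named vector of monomer coefficients (mM^-1 cm^-1) with
#'   entries for A, C, G, T.
#' @return extinction coefficient in mM^-1 cm^-1.
#' @examples
#' extinctionCoefficient("TCTGCGCGCC")   # 88.9
#' @export
extinctionCoefficient <- function(seq, table = defaultEpsilonTable()) {
    s <- .validDNA(seq)
    bases <- strsplit(s, "")[[1L]]
    need <- unique(bases)
    if (!all(need %in% names(table)))
        stop("monomer table lacks entries for: ",
             paste(setdiff(need, names(table)), collapse = ", "))
    sum(table[bases])
}

#' Strand concentration from absorbance (Beer-Lambert)
#'
#' \eqn{c = A / (\epsilon l)} with \eqn{\epsilon} in mM^-1 cm^-1 and the
#' pathlength in cm, giving the concentration in mM.
#'
#' @param A260 absorbance (dimensionless, >= 0).
#' @param epsilon extinction coefficient, mM^-1 cm^-1 (> 0).
#' @param pathlength cuvette pathlength, cm (> 0).
#' @return strand concentration in mM.
#' @examples
#' concentrationFromAbsorbance(0.3267, 108.9)   # 0.003 mM = 3 uM
#' @export
concentrationFromAbsorbance <- function(A260, epsilon, pathlength = 1) {
    if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
    if (!is.finite(pathlength) || pathlength <= 0) stop("pathlength must be > 0")
    if (any(A260 < 0)) stop("absorbance must be >= 0")
    A260 / (epsilon * pathlength)
}

# Maximal runs of `base` in a sequence: data.frame(start, length), 1-based.
.baseRuns <- function(s, base) {
    r <- rle(strsplit(s, "")[[1L]] == base)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Count maximal base runs of a minimum length
#'
#' Number of maximal runs of `base` with length at least `minLen`; a
#' convenience for questions such as how many C-runs a pyrimidine-rich
#' promoter fragment contains.
#'
#' @param seq DNA string over ACGT.
#' @param base one of A, C, G, T.
#' @param minLen minimum run length (>= 1).
#' @return integer count of qualifying runs.
#' @examples
#' countBaseRuns("GGGGTTGGGGTTGGGGTTGGGG", "G", 3)  # 4
#' @export
countBaseRuns <- function(seq, base, minLen = 3L) {
    s <- .validDNA(seq, allowEmpty = TRUE)
    if (!is.character(base) || length(base) != 1L || !base %in% c("A", "C", "G", "T"))
        stop("base must be one of A, C, G, T")
    if (minLen < 1L) stop("minLen must be >= 1")
    if (!nzchar(s)) return(0L)
    sum(.baseRuns(s, base)$length >= minLen)
}

# Core run-window scanner shared by the G4 and i-motif scanners.
# Finds windows of nRuns consecutive maximal base-runs (each >= minRun)
# whose gaps (loops) all lie in [loopMin, loopMax]. Default reporting is
# greedy leftmost non-overlapping; allOverlaps = TRUE reports every window.
.scanRunWindows <- function(s, base, motifClass, minRun, loopMin, loopMax,
                            nRuns, allOverlaps) {
    empty <- data.frame(seqname = character(), motifClass = character(),
                        start = integer(), end = integer(), width = integer(),
                        nRuns = integer(), stringsAsFactors = FALSE)
    empty$runStarts <- list(); empty$runLengths <- list(); empty$loopLengths <- list()
    if (!nzchar(s)) return(empty)
    runs <- .baseRuns(s, base)
    runs <- runs[runs$length >= minRun, , drop = FALSE]
    k <- nrow(runs)
    hits <- list()
    i <- 1L
    while (i + nRuns - 1L <= k) {
        idx <- i:(i + nRuns - 1L)
        rs <- runs$start[idx]
        rl <- runs$length[idx]
        loops <- rs[-1L] - (rs[-nRuns] + rl[-nRuns])
        if (all(loops >= loopMin & loops <= loopMax)) {
            h <- data.frame(seqname = NA_character_, motifClass = motifClass,
                            start = rs[1L], end = rs[nRuns] + rl[nRuns] - 1L,
                            nRuns = nRuns, stringsAsFactors = FALSE)
            h$width <- h$end - h$start + 1L
            h$runStarts <- list(rs)
            h$runLengths <- list(rl)
            h$loopLengths <- list(loops)
            hits[[length(hits) + 1L]] <- h
            i <- if (allOverlaps) i + 1L else i + nRuns
        } else {
            i <- i + 1L
        }
    }
    if (!length(hits)) return(empty)
    out <- do.call(rbind, hits)
    out[, c("seqname", "motifClass", "start", "end", "width", "nRuns",
            "runStarts", "runLengths", "loopLengths")]
}

#' Scan for putative G-quadruplex-forming sequences
#'
#' Finds stretches of `nRuns` consecutive maximal G-runs of length at least
#' `minRun` separated by loops of `loopMin` to `loopMax` nucleotides -- the
#' canonical putative-quadruplex (PQS) grammar (four runs of three or more
#' guanines, loops 1-7 nt). Only the given strand is scanned; scan the
#' reverse complement explicitly for the other strand.
#'
#' By default hits are maximal, non-overlapping and assigned greedily left to
#' right (runs are always used whole, so longer runs are preferred over
#' splitting). With `allOverlaps = TRUE` every qualifying window of
#' consecutive runs is reported.
#'
#' @param seq DNA string over ACGT (may be empty).
#' @param minRun minimum G-run length (default 3).
#' @param loopMin,loopMax loop-length bounds in nucleotides (defaults 1, 7).
#' @param nRuns number of runs per motif (default 4).
#' @param allOverlaps report all qualifying run windows instead of greedy
#'   non-overlapping ones.
#' @return data.frame with one row per hit: `seqname` (NA here; filled by
#'   [scanOligoSet()]), `motifClass`, 1-based inclusive `start`/`end`,
#'   `width`, `nRuns`, and list columns `runStarts`, `runLengths`,
#'   `loopLengths`. Zero rows when nothing matches.
#' @examples
#' scanQuadruplex("GGGTTGGGTTGGGTTGGG")  # one hit spanning the string
#' scanQuadruplex("GGCGCGCAGA")          # none
#' @export
scanQuadruplex <- function(seq, minRun = 3L, loopMin = 1L, loopMax = 7L,
                           nRuns = 4L, allOverlaps = FALSE) {
    s <- .validDNA(seq, allowEmpty = TRUE)
    if (minRun < 1L || nRuns < 2L || loopMin < 1L || loopMin > loopMax)
        stop("invalid scanner parameters: need minRun >= 1, nRuns >= 2, 1 <= loopMin <= loopMax")
    .scanRunWindows(s, "G", "G4", minRun, loopMin, loopMax, nRuns, allOverlaps)
}

#' Scan for putative i-motif-forming sequences
#'
#' Mirror of [scanQuadruplex()] on cytosine runs: i-motifs form from runs of
#' hemi-protonated cytosines, so the same run/loop grammar applies with base
#' C. A G4 hit on one strand corresponds to an i-motif hit at mirrored
#' coordinates on the reverse complement.
#'
#' @inheritParams scanQuadruplex
#' @return data.frame of hits as in [scanQuadruplex()], `motifClass = "IM"`.
#' @export
scanImotif <- function(seq, minRun = 3L, loopMin = 1L, loopMax = 7L,
                       nRuns = 4L, allOverlaps = FALSE) {
    s <- .validDNA(seq, allowEmpty = TRUE)
    if (minRun < 1L || nRuns < 2L || loopMin < 1L || loopMin > loopMax)
        stop("invalid scanner parameters: need minRun >= 1, nRuns >= 2, 1 <= loopMin <= loopMax")
    .scanRunWindows(s, "C", "IM", minRun, loopMin, loopMax, nRuns, allOverlaps)
}
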