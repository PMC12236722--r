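#' @import methods
NULL

.RNA_ALPHABET <- c("A", "C", "G", "U")

#' MiRNA: a mature microRNA with defined seed and 3' windows
#'
#' Holds a mature miRNA sequence (5'->3', RNA alphabet) together with the
#' windows used throughout trigger-site analysis: the seed core (positions
#' 2-7), the extended seed (positions 2-8) and the 3' pairing window,
#' defined as the final `threePrimeWindowLen` nucleotides (default 13).
#'
#' @slot id miRNA identifier (e.g. `"mmu-miR-7a-5p"`).
#' @slot sequence mature sequence, 5'->3', over `{A,C,G,U}`.
#' @slot threePrimeWindowLen number of 3'-terminal nucleotides forming the
#'   3' pairing window; must not reach into the extended seed.
#'
#' @examples
#' m <- MiRNA("let-7-like", "UGAGGUAGUAGGUUGUAUAGUU")
#' seedSequence(m)
#' threePrimeWindow(m)
#' @export
setClass("MiRNA",
    representation(id = "character", sequence = "character",
                   threePrimeWindowLen = "integer"))

setValidity("MiRNA", function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    s <- object@sequence
    if (length(s) != 1L)
        return("'sequence' must be a single string")
    n <- nchar(s)
    if (n < 18L || n > 26L)
        msg <- c(msg, sprintf("miRNA length must be in [18, 26], got %d", n))
    bad <- setdiff(strsplit(s, "")[[1]], .RNA_ALPHABET)
    if (length(bad))
        msg <- c(msg, sprintf("invalid nucleotide(s): %s",
                              paste(unique(bad), collapse = ", ")))
    w <- object@threePrimeWindowLen
    if (length(w) != 1L || is.na(w) || w < 1L)
        msg <- c(msg, "'threePrimeWindowLen' must be a positive integer")
    else if (w >= n - 8L)
        msg <- c(msg, sprintf(
            "3' window (%d nt) must not overlap the extended seed (len %d)",
            w, n))
    if (length(msg)) msg else TRUE
})

#' Construct a MiRNA object
#'
#' @param id miRNA identifier.
#' @param sequence mature sequence; DNA letters and lowercase are accepted
#'   and normalized via [normalizeRNA()].
#' @param threePrimeWindowLen length of the 3' pairing window (default 13).
#' @return A [MiRNA-class] object.
#' @export
MiRNA <- function(id, sequence, threePrimeWindowLen = 13L) {
    new("MiRNA", id = as.character(id),
        sequence = normalizeRNA(sequence),
        threePrimeWindowLen = as.integer(threePrimeWindowLen))
}

#' DuplexStructure: an intermolecular RNA-RNA pairing map with energy
#'
#' Represents an antiparallel, non-crossing set of inter-strand base pairs
#' between two RNA sequences, together with its free energy (kcal/mol)
#' under the bundled nearest-neighbor duplex model. Pair indices are
#' 1-based on each strand in its 5'->3' orientation; walking along the
#' first strand 5'->3', partner positions on the second strand strictly
#' decrease.
#'
#' @slot seqA,seqB the two strands, 5'->3'.
#' @slot pairs integer matrix, one row per pair, columns `a` and `b`.
#' @slot energy duplex free energy in kcal/mol; `0` for an empty structure.
#' @export
setClass("DuplexStructure",
    representation(seqA = "character", seqB = "character",
                   pairs = "matrix", energy = "numeric"))

setValidity("DuplexStructure", function(object) {
    p <- object@pairs
    if (!is.numeric(p) && !is.integer(p)) return("'pairs' must be numeric")
    if (ncol(p) != 2L) return("'pairs' must have two columns")
    if (nrow(p) == 0L) {
        if (object@energy != 0) return("empty structure must have energy 0")
        return(TRUE)
    }
    na <- nchar(object@seqA); nb <- nchar(object@seqB)
    if (any(p[, 1L] < 1L | p[, 1L] > na) || any(p[, 2L] < 1L | p[, 2L] > nb))
        return("pair indices out of strand bounds")
    if (nrow(p) > 1L) {
        if (any(diff(p[, 1L]) <= 0L))
            return("strand-A indices must be strictly increasing")
        if (any(diff(p[, 2L]) >= 0L))
            return("strand-B indices must be strictly decreasing (antiparallel)")
    }
    a <- strsplit(object@seqA, "")[[1]][p[, 1L]]
    b <- strsplit(object@seqB, "")[[1]][p[, 2L]]
    ok <- paste0(a, b) %in% c("CG", "GC", "GU", "UG", "AU", "UA")
    if (!all(ok))
        return(sprintf("non-pairable bases at pair row %s",
                       paste(which(!ok), collapse = ", ")))
    if (object@energy > 0)
        return("non-empty structure must have energy <= 0")
    TRUE
})

#' ArchitectureReport: per-site miRNA pairing architecture metrics
#'
#' The per-site summary driving the TDMD filter cascade: the seed-match
#' class, the longest run of consecutive unpaired miRNA positions after the
#' seed (central bulge), the longest run of consecutive paired positions
#' inside the miRNA's 3' window, the 3' minimum free energy, and the
#' underlying anchored pairing map.
#'
#' @slot seedClass one of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`,
#'   `"none"`.
#' @slot centralMismatchRun longest post-seed run of unpaired miRNA
#'   positions (nt).
#' @slot threePrimePairRun longest run of consecutive paired miRNA
#'   positions entirely within the 3' window (nt).
#' @slot threePrimeMfe minimum free energy (kcal/mol) of the duplex between
#'   the miRNA 3' window and the site region upstream of the seed match.
#' @slot pairingMap the anchored [DuplexStructure-class] (miRNA vs site).
#' @slot seedSiteInterval integer `c(start, end)` of the seed-paired site
#'   positions (1-based, site-local).
#' @slot threePrimeSitePositions site-local positions paired with the
#'   miRNA 3' window.
#' @export
setClass("ArchitectureReport",
    representation(seedClass = "character",
                   centralMismatchRun = "integer",
                   threePrimePairRun = "integer",
                   threePrimeMfe = "numeric",
                   pairingMap = "DuplexStructure",
                   seedSiteInterval = "integer",
                   threePrimeSitePositions = "integer"))

setValidity("ArchitectureReport", function(object) {
    msg <- character()
    if (!object@seedClass %in% c(SEED_MATCH_CLASSES, "none"))
        msg <- c(msg, "invalid seed class")
    if (object@centralMismatchRun < 0L)
        msg <- c(msg, "centralMismatchRun must be >= 0")
    if (object@threePrimePairRun < 0L)
        msg <- c(msg, "threePrimePairRun must be >= 0")
    if (object@threePrimeMfe > 0)
        msg <- c(msg, "threePrimeMfe must be <= 0")
    if (length(msg)) msg else TRUE
})

#' AnnotationIndex: strand-aware transcript-region index
#'
#' A flattened, query-ready view of a GTF/GFF3 annotation: one
#' [GenomicRanges::GRanges] of region features (5'UTR, CDS, 3'UTR, ncRNA
#' exon, intron) with transcript/gene identifiers, supporting point
#' classification under a fixed precedence rule.
#'
#' @slot regions `GRanges` with metadata columns `regionClass`,
#'   `transcript_id`, `gene_id`.
#' @slot seqlens named integer vector of chromosome lengths (may be empty).
#' @export
setClass("AnnotationIndex",
    representation(regions = "ANY", seqlens = "integer"))
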