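#' Seed-anchored pairing map of a miRNA against a candidate site
#'
#' Builds the full-duplex pairing map used by the architecture metrics:
#' the classified seed pairs (miRNA positions 2-7, or 2-8 for m8 classes)
#' are fixed as anchors, and the miRNA remainder (positions 9..end, or
#' 8..end for 6mer/7mer-A1) is co-folded at minimum free energy against
#' the site region 5' (upstream) of the seed match. No pair can cross the
#' anchor. The structure's energy is that of the 3' co-fold; the seed
#' helix itself is not scored.
#'
#' @inheritParams classifySeedMatch
#' @param params duplex energy parameters.
#' @return A [DuplexStructure-class] with strand A = miRNA, strand B = site.
#' @export
anchoredPairingMap <- function(mirna, siteSeq, seedEnd,
                               params = defaultEnergyParams()) {
    siteSeq <- normalizeRNA(siteSeq)
    seedEnd <- as.integer(seedEnd)
    cls <- classifySeedMatch(mirna, siteSeq, seedEnd)
    if (cls == "none")
        stop("no canonical seed match at the anchor")
    seedLast <- if (cls %in% c("8mer", "7mer-m8")) 8L else 7L
    seedPairs <- cbind(2:seedLast, seedEnd - (2:seedLast) + 2L)
    remStart <- seedLast + 1L
    siteUp <- seedEnd - seedLast + 2L   # first site position of the anchor
    pairs <- seedPairs
    energy <- 0
    if (remStart <= nchar(mirna@sequence) && siteUp > 1L) {
        rest <- substr(mirna@sequence, remStart, nchar(mirna@sequence))
        upstream <- substr(siteSeq, 1L, siteUp - 1L)
        dx <- hybridize(rest, upstream, params)
        energy <- duplexEnergy(dx)
        if (nrow(duplexPairs(dx))) {
            p <- duplexPairs(dx)
            pairs <- rbind(pairs,
                           cbind(p[, 1L] + remStart - 1L, p[, 2L]))
        }
    }
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    .newDuplex(mirna@sequence, siteSeq, pairs, min(energy, 0))
}

.longestRun <- function(flags) {
    if (!length(flags) || !any(flags)) return(0L)
    r <- rle(flags)
    max(r$lengths[r$values])
}

#' Longest post-seed run of unpaired miRNA positions (central bulge)
#'
#' Scans miRNA positions 9 through the end and returns the length of the
#' longest run of consecutive positions absent from the pairing map. Both
#' true mismatches and bulged-out positions count as unpaired.
#'
#' @param map a [DuplexStructure-class] with strand A = miRNA.
#' @param mirna the [MiRNA-class] the map refers to.
#' @return Integer run length (nt).
#' @export
centralMismatchRun <- function(map, mirna) {
    stopifnot(is(map, "DuplexStructure"), is(mirna, "MiRNA"))
    n <- nchar(mirna@sequence)
    paired <- seq_len(n) %in% duplexPairs(map)[, 1L]
    .longestRun(!paired[9:n])
}

#' Longest pairing run within the miRNA 3' window
#'
#' Length of the longest run of consecutive paired miRNA positions lying
#' entirely within the final `threePrimeWindowLength` nucleotides. A run
#' extending beyond the window boundary contributes only its in-window
#' portion.
#'
#' @inheritParams centralMismatchRun
#' @return Integer run length (nt).
#' @export
maxThreePrimePairRun <- function(map, mirna) {
    stopifnot(is(map, "DuplexStructure"), is(mirna, "MiRNA"))
    n <- nchar(mirna@sequence)
    w <- mirna@threePrimeWindowLen
    paired <- seq_len(n) %in% duplexPairs(map)[, 1L]
    .longestRun(paired[(n - w + 1L):n])
}

#' Evaluate the full pairing architecture of a candidate site
#'
#' Combines seed classification, the anchored pairing map, the central
#' bulge run, the 3' pairing run and the 3' MFE into one report. When the
#' anchor carries no canonical seed match the report is still returned
#' (seed class `"none"`) with the remaining metrics at their degenerate
#' values: every post-seed position unpaired, no 3' pairing, 3' MFE 0.
#'
#' @inheritParams anchoredPairingMap
#' @return An [ArchitectureReport-class].
#' @export
evaluateArchitecture <- function(mirna, siteSeq, seedEnd,
                                 params = defaultEnergyParams()) {
    siteSeq <- normalizeRNA(siteSeq)
    seedEnd <- as.integer(seedEnd)
    cls <- classifySeedMatch(mirna, siteSeq, seedEnd)
    n <- nchar(mirna@sequence)
    if (cls == "none") {
        return(new("ArchitectureReport", seedClass = "none",
                   centralMismatchRun = n - 8L,
                   threePrimePairRun = 0L, threePrimeMfe = 0,
                   pairingMap = .newDuplex(mirna@sequence, siteSeq,
                                           integer(0), 0),
                   seedSiteInterval = c(NA_integer_, NA_integer_),
                   threePrimeSitePositions = integer(0)))
    }
    map <- anchoredPairingMap(mirna, siteSeq, seedEnd, params)
    seedLast <- if (cls %in% c("8mer", "7mer-m8")) 8L else 7L
    w <- mirna@threePrimeWindowLen
    p <- duplexPairs(map)
    in3p <- p[, 1L] >= n - w + 1L
    new("ArchitectureReport", seedClass = cls,
        centralMismatchRun = centralMismatchRun(map, mirna),
        threePrimePairRun = maxThreePrimePairRun(map, mirna),
        threePrimeMfe = threePrimeMfe(mirna, siteSeq, seedEnd, params),
        pairingMap = map,
        seedSiteInterval = c(seedEnd - seedLast + 2L, seedEnd),
        threePrimeSitePositions = as.integer(p[in3p, 2L]))
}

setMethod("seedClass", "ArchitectureReport", function(x) x@seedClass)
setMethod("centralMismatchRunLength", "ArchitectureReport",
          function(x) x@centralMismatchRun)
setMethod("threePrimePairRunLength", "ArchitectureReport",
          function(x) x@threePrimePairRun)
setMethod("threePrimeMfeValue", "ArchitectureReport",
          function(x) x@threePrimeMfe)
setMethod("pairingMap", "ArchitectureReport", function(x) x@pairingMap)

setMethod("show", "ArchitectureReport", function(object) {
    cat(sprintf(paste0(
        "ArchitectureReport\n  seed class: %s\n",
        "  central mismatch run: %d nt\n  3' pair run: %d nt\n",
        "  3' MFE: %.2f kcal/mol\n"),
        object@seedClass, object@centralMismatchRun,
        object@threePrimePairRun, object@threePrimeMfe))
})
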