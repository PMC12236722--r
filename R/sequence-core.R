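#' Seed-match classes, strongest first
#'
#' Canonical seed-match classes in decreasing strength:
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer. A window that satisfies none of them
#' is classified `"none"`.
#' @export
SEED_MATCH_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U; `N` is preserved. Any character outside
#' `{A,C,G,T,U,N}` (either case) is an error naming the first offending
#' position.
#'
#' @param raw character scalar (DNA or RNA, any case).
#' @return RNA string over `{A,C,G,U,N}`, same length as input.
#' @examples
#' normalizeRNA("acgt")  # "ACGU"
#' @export
normalizeRNA <- function(raw) {
    if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
        stop("'raw' must be a single non-empty string")
    up <- chartr("acgtun", "ACGUUN", chartr("T", "U", raw))
    bad <- regexpr("[^ACGUN]", up)
    if (bad > 0L)
        stop(sprintf("invalid nucleotide '%s' at position %d",
                     substr(raw, bad, bad), bad))
    up
}

#' Reverse complement of an RNA string
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Applying it twice
#' returns the input.
#'
#' @param seq RNA string (normalized first if needed).
#' @return RNA string.
#' @examples
#' rnaReverseComplement("AAGG")  # "CCUU"
#' @export
rnaReverseComplement <- function(seq) {
    seq <- normalizeRNA(seq)
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(seq)))
}

.comp <- function(x) chartr("ACGUN", "UGCAN", x)

setMethod("mirnaId", "MiRNA", function(x) x@id)
setMethod("mirnaSequence", "MiRNA", function(x) x@sequence)
setMethod("seedSequence", "MiRNA", function(x, extended = FALSE) {
    substr(x@sequence, 2L, if (extended) 8L else 7L)
})
setMethod("threePrimeWindow", "MiRNA", function(x) {
    n <- nchar(x@sequence)
    substr(x@sequence, n - x@threePrimeWindowLen + 1L, n)
})
setMethod("threePrimeWindowLength", "MiRNA",
          function(x) x@threePrimeWindowLen)

setMethod("show", "MiRNA", function(object) {
    cat(sprintf("MiRNA %s (%d nt)\n  5'-%s-3'\n  seed (2-8): %s | 3' window: final %d nt\n",
                object@id, nchar(object@sequence), object@sequence,
                seedSequence(object, extended = TRUE),
                object@threePrimeWindowLen))
})

#' Read mature miRNA sequences from FASTA
#'
#' Multi-record FASTA; the header token before the first whitespace is the
#' id. T/U are both accepted.
#'
#' @param path FASTA file.
#' @param threePrimeWindowLen 3' window length applied to every miRNA.
#' @return Named list of [MiRNA-class] objects.
#' @export
readMiRNAFasta <- function(path, threePrimeWindowLen = 13L) {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    out <- lapply(seq_along(ss), function(i)
        MiRNA(ids[i], as.character(ss[[i]]), threePrimeWindowLen))
    names(out) <- ids
    out
}

#' Classify the seed match anchored at a site position
#'
#' Classifies the pairing between a miRNA seed and a candidate site window
#' using the canonical definitions: 6mer = Watson-Crick pairing of the site
#' to miRNA positions 2-7; 7mer-m8 additionally pairs position 8; 7mer-A1
#' adds an adenosine at the site position opposite miRNA position 1 (the A
#' is required in the site regardless of the miRNA's first nucleotide);
#' 8mer combines both. G:U wobbles do not count in the seed, and any `N`
#' in the window yields `"none"`.
#'
#' `seedEnd` is the 1-based site position that pairs miRNA position 2 --
#' i.e. the 3' end of the seed match on the site. Pairing is antiparallel,
#' so miRNA positions 2..8 pair site positions `seedEnd`, `seedEnd - 1`,
#' ..., `seedEnd - 6`, and the site A of A1 classes sits at `seedEnd + 1`.
#'
#' @param mirna a [MiRNA-class].
#' @param siteSeq site/transcript sequence, 5'->3' (transcript sense).
#' @param seedEnd 1-based site index pairing miRNA position 2.
#' @return One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`, `"none"`.
#' @export
classifySeedMatch <- function(mirna, siteSeq, seedEnd) {
    stopifnot(is(mirna, "MiRNA"))
    siteSeq <- normalizeRNA(siteSeq)
    seedEnd <- as.integer(seedEnd)
    n <- nchar(siteSeq)
    if (seedEnd - 6L < 1L || seedEnd > n)
        stop(sprintf("seed window [%d, %d] out of site bounds [1, %d]",
                     seedEnd - 6L, seedEnd, n))
    site <- strsplit(siteSeq, "")[[1]]
    mir <- strsplit(mirna@sequence, "")[[1]]
    # miRNA position p (2..8) pairs site position seedEnd - (p - 2)
    core <- all(site[seedEnd - 0:5] == .comp(mir[2:7])) &&
        !any(site[seedEnd - 0:5] == "N")
    if (!core) return("none")
    m8 <- site[seedEnd - 6L] == .comp(mir[8L]) && site[seedEnd - 6L] != "N"
    a1 <- seedEnd + 1L <= n && site[seedEnd + 1L] == "A"
    if (m8 && a1) "8mer"
    else if (m8) "7mer-m8"
    else if (a1) "7mer-A1"
    else "6mer"
}

#' Scan a transcript for canonical seed matches
#'
#' Reports every position whose anchored classification is not `"none"`,
#' in ascending order. Overlapping matches are reported as-is.
#'
#' @inheritParams classifySeedMatch
#' @param transcriptSeq transcript sequence, 5'->3'.
#' @return `data.frame` with columns `seedEnd` (1-based site position
#'   pairing miRNA position 2), `start` (5' end of the matched window) and
#'   `class`. Empty for transcripts shorter than 8 nt.
#' @export
findSeedSites <- function(mirna, transcriptSeq) {
    stopifnot(is(mirna, "MiRNA"))
    transcriptSeq <- normalizeRNA(transcriptSeq)
    n <- nchar(transcriptSeq)
    empty <- data.frame(seedEnd = integer(), start = integer(),
                        class = character(), stringsAsFactors = FALSE)
    if (n < 8L) return(empty)
    # locate the core hexamer (reverse complement of miRNA 2-7), then
    # classify at each anchor
    hex <- rnaReverseComplement(seedSequence(mirna, extended = FALSE))
    starts <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::RNAString(hex), Biostrings::RNAString(transcriptSeq),
        fixed = TRUE))
    anchors <- starts + 5L                 # seedEnd = 3' end of the hexamer
    anchors <- anchors[anchors - 6L >= 1L] # need room for the m8 check
    if (!length(anchors)) return(empty)
    cls <- vapply(anchors, function(e)
        classifySeedMatch(mirna, transcriptSeq, e), character(1))
    keep <- cls != "none"
    data.frame(seedEnd = as.integer(anchors[keep]),
               start = as.integer(anchors[keep]) - 5L,
               class = cls[keep], stringsAsFactors = FALSE)
}
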