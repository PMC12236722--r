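# pair-type order shared with the compiled DP: CG GC GU UG AU UA
.PAIR_TYPES <- c("CG", "GC", "GU", "UG", "AU", "UA")

.pkg_env <- new.env(parent = emptyenv())

#' Read a nearest-neighbor duplex energy parameter table
#'
#' Parses the tab-separated `key<TAB>kcal` format bundled at
#' `inst/extdata/turner2004_stack.tsv`. Stacking keys are written as the
#' top-strand dinucleotide (5'->3') over the bottom-strand dinucleotide
#' (3'->5'), e.g. `GC/CG`; the scalar keys `loop_open`, `loop_extend` and
#' `terminal_au_gu` set the affine interior-loop/bulge penalty and the
#' terminal AU/GU penalty (kcal/mol).
#'
#' @param path parameter file; default is the bundled Turner 2004 table.
#' @param allowGU allow G:U wobble pairs in duplexes (default `TRUE`).
#' @return An `EnergyParams` list with elements `stack` (6x6 matrix in
#'   pair-type order CG, GC, GU, UG, AU, UA; `stack[outer, inner]`),
#'   `loopOpen`, `loopExtend`, `terminalPenalty`, `allowGU`, `version`.
#' @export
readEnergyParams <- function(path = system.file("extdata",
                                 "turner2004_stack.tsv",
                                 package = "triggerscan"),
                             allowGU = TRUE) {
    lines <- readLines(path)
    version <- sub("^#\\s*param_set:\\s*", "",
                   grep("^#\\s*param_set:", lines, value = TRUE)[1])
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                             stringsAsFactors = FALSE)
    stopifnot(identical(names(tab), c("key", "kcal")),
              all(is.finite(tab$kcal)))
    scalars <- c("loop_open", "loop_extend", "terminal_au_gu")
    sc <- stats::setNames(tab$kcal[match(scalars, tab$key)], scalars)
    if (anyNA(sc)) stop("missing loop/terminal penalty entries")
    if (any(sc < 0)) stop("penalties must be >= 0")
    stack <- matrix(NA_real_, 6, 6, dimnames = list(.PAIR_TYPES, .PAIR_TYPES))
    st <- tab[grepl("^[ACGU]{2}/[ACGU]{2}$", tab$key), ]
    for (i in seq_len(nrow(st))) {
        top <- strsplit(substr(st$key[i], 1, 2), "")[[1]]
        bot <- strsplit(substr(st$key[i], 4, 5), "")[[1]]
        outer <- paste0(top[1], bot[1]); inner <- paste0(top[2], bot[2])
        if (!(outer %in% .PAIR_TYPES) || !(inner %in% .PAIR_TYPES))
            stop("stack key with non-pairable doublet: ", st$key[i])
        stack[outer, inner] <- st$kcal[i]
    }
    if (anyNA(stack)) stop("incomplete stack table")
    list(stack = stack, loopOpen = unname(sc["loop_open"]),
         loopExtend = unname(sc["loop_extend"]),
         terminalPenalty = unname(sc["terminal_au_gu"]),
         allowGU = isTRUE(allowGU), version = version)
}

#' Default duplex energy parameters (bundled Turner 2004 stacks)
#'
#' @return Cached `EnergyParams` list; see [readEnergyParams()].
#' @export
defaultEnergyParams <- function() {
    if (is.null(.pkg_env$params))
        .pkg_env$params <- readEnergyParams()
    .pkg_env$params
}

.encodeRNA <- function(seq) {
    x <- match(strsplit(seq, "")[[1]], .RNA_ALPHABET) - 1L
    # N and other ambiguity codes are non-pairable: encode as a sentinel
    x[is.na(x)] <- 9L
    x
}

.newDuplex <- function(seqA, seqB, pairs, energy) {
    new("DuplexStructure", seqA = seqA, seqB = seqB,
        pairs = matrix(as.integer(pairs), ncol = 2,
                       dimnames = list(NULL, c("a", "b"))),
        energy = energy)
}

#' Predict the minimum-free-energy intermolecular duplex
#'
#' Finds the lowest-energy antiparallel, non-crossing set of inter-strand
#' base pairs between two RNAs under a nearest-neighbor duplex model:
#' stacking energies for adjacent pairs, an affine penalty for interior
#' loops and bulges (capped at 15 unpaired nt per side), a terminal AU/GU
#' penalty at both helix ends, no intramolecular structure and no dangling
#' ends. If no structure with non-positive energy exists the empty
#' structure with energy 0 is returned. Co-optimal structures are resolved
#' deterministically: more pairs first, then the 5'-most anchor on `seqA`.
#'
#' @param seqA,seqB RNA strings, 5'->3'.
#' @param params an `EnergyParams` list; see [defaultEnergyParams()].
#' @return A [DuplexStructure-class].
#' @examples
#' hybridize("GCGC", "GCGC")
#' @export
hybridize <- function(seqA, seqB, params = defaultEnergyParams()) {
    seqA <- normalizeRNA(seqA); seqB <- normalizeRNA(seqB)
    res <- .duplexHybridC(.encodeRNA(seqA), .encodeRNA(seqB),
                          params$stack, params$loopOpen, params$loopExtend,
                          params$terminalPenalty, params$allowGU)
    .newDuplex(seqA, seqB, res$pairs, res$energy)
}

#' Exhaustive-enumeration duplex minimum energy
#'
#' Scores every valid antiparallel non-crossing pairing explicitly and
#' returns the minimum energy (0 if nothing beats the empty structure).
#' Exponential in sequence length; intended as an independent check of
#' [hybridize()] on short sequences.
#'
#' @inheritParams hybridize
#' @return Energy in kcal/mol.
#' @export
enumerateDuplexMfe <- function(seqA, seqB, params = defaultEnergyParams()) {
    seqA <- normalizeRNA(seqA); seqB <- normalizeRNA(seqB)
    .duplexEnumMinC(.encodeRNA(seqA), .encodeRNA(seqB),
                    params$stack, params$loopOpen, params$loopExtend,
                    params$terminalPenalty, params$allowGU)
}

#' Cross-check the duplex DP against enumeration over all short pairs
#'
#' Runs [hybridize()] and the exhaustive enumerator over every pair of RNA
#' sequences up to the given lengths and counts energy disagreements.
#'
#' @param maxLenA,maxLenB maximum strand lengths (full 4-letter alphabet).
#' @inheritParams hybridize
#' @return Named vector `c(checked, mismatches, maxAbsDiff)` (energies in
#'   kcal/mol for `maxAbsDiff`).
#' @export
duplexOracleSweep <- function(maxLenA, maxLenB,
                              params = defaultEnergyParams()) {
    r <- .duplexCheckAllC(as.integer(maxLenA), as.integer(maxLenB),
                          params$stack, params$loopOpen, params$loopExtend,
                          params$terminalPenalty, params$allowGU)
    c(checked = r[1], mismatches = r[2], maxAbsDiff = r[3] / 100)
}

setMethod("duplexEnergy", "DuplexStructure", function(x) x@energy)
setMethod("duplexPairs", "DuplexStructure", function(x) x@pairs)

setMethod("show", "DuplexStructure", function(object) {
    cat(sprintf("DuplexStructure: %d pair(s), %.2f kcal/mol\n",
                nrow(object@pairs), object@energy))
    if (nrow(object@pairs)) {
        a <- strsplit(object@seqA, "")[[1]]
        b <- strsplit(object@seqB, "")[[1]]
        cat(sprintf("  A 5'-%s-3' [%d-%d]\n", object@seqA,
                    object@pairs[1, 1], object@pairs[nrow(object@pairs), 1]))
        cat(sprintf("  B 5'-%s-3' [%d-%d]\n", object@seqB,
                    object@pairs[nrow(object@pairs), 2], object@pairs[1, 2]))
    }
})

#' 3' minimum free energy of a seed-anchored site
#'
#' Hybridizes the miRNA's 3' window (its final `threePrimeWindowLength`
#' nucleotides, default 13) against the portion of the site 5' of the
#' seed-pairing region -- the region available for 3' pairing under
#' antiparallel geometry. Requires a canonical seed match at the anchor.
#'
#' @inheritParams classifySeedMatch
#' @param params duplex energy parameters.
#' @return Energy in kcal/mol (`<= 0`; 0 when no 3' pairing exists).
#' @export
threePrimeMfe <- function(mirna, siteSeq, seedEnd,
                          params = defaultEnergyParams()) {
    siteSeq <- normalizeRNA(siteSeq)
    cls <- classifySeedMatch(mirna, siteSeq, seedEnd)
    if (cls == "none")
        stop("no canonical seed match at the anchor; 3' MFE undefined")
    seedStart <- seedEnd - (if (cls %in% c("8mer", "7mer-m8")) 6L else 5L)
    if (seedStart <= 1L) return(0)
    upstream <- substr(siteSeq, 1L, seedStart - 1L)
    duplexEnergy(hybridize(threePrimeWindow(mirna), upstream, params))
}
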