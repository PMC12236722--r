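.REGION_CLASSES <- c("UTR3", "UTR5", "ncRNA_exon", "CDS", "intron",
                     "intergenic")

#' Load a GTF/GFF3 annotation into a region index
#'
#' Imports transcript/exon/CDS features and flattens them into the region
#' classes used by the trigger filter: `UTR5`, `CDS`, `UTR3`, `ncRNA_exon`
#' and `intron`. When UTR features are not explicit they are derived from
#' exon-minus-CDS arithmetic: exonic sequence 5' of the CDS span (in
#' transcript orientation) is `UTR5`, 3' of it is `UTR3`. Transcripts
#' without CDS contribute `ncRNA_exon`; intra-transcript gaps between
#' exons contribute `intron`.
#'
#' @param gtfPath GTF or GFF3 file.
#' @return An [AnnotationIndex-class].
#' @export
loadAnnotation <- function(gtfPath) {
    empty <- !any(nzchar(sub("#.*", "", readLines(gtfPath))))
    gr <- if (empty) GenomicRanges::GRanges()
        else tryCatch(rtracklayer::import(gtfPath),
                      error = function(e) stop("failed to parse annotation: ",
                                               conditionMessage(e)))
    if (!length(gr)) {
        return(new("AnnotationIndex",
                   regions = GenomicRanges::GRanges(),
                   seqlens = integer(0)))
    }
    type <- as.character(gr$type)
    txid <- as.character(gr$transcript_id)
    gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else txid
    keep <- type %in% c("exon", "CDS", "five_prime_utr", "three_prime_utr",
                        "UTR", "5UTR", "3UTR") & !is.na(txid)
    gr <- gr[keep]; type <- type[keep]; gid <- gid[keep]; txid <- txid[keep]
    pieces <- list()
    for (tx in unique(txid)) {
        sel <- txid == tx
        ex <- gr[sel & type == "exon"]
        cds <- gr[sel & type == "CDS"]
        if (!length(ex)) ex <- range(gr[sel])
        strand <- as.character(GenomicRanges::strand(ex))[1]
        exr <- GenomicRanges::reduce(ex, ignore.strand = TRUE)
        out <- GenomicRanges::GRanges()
        if (length(cds)) {
            cdsr <- GenomicRanges::reduce(cds, ignore.strand = TRUE)
            utr <- GenomicRanges::setdiff(exr, cdsr, ignore.strand = TRUE)
            cdsSpan <- range(cdsr)
            cls <- character(length(utr))
            if (length(utr)) {
                before <- GenomicRanges::end(utr) <
                    GenomicRanges::start(cdsSpan)
                cls <- ifelse(before,
                              if (strand == "-") "UTR3" else "UTR5",
                              if (strand == "-") "UTR5" else "UTR3")
            }
            out <- c(GenomicRanges::granges(cdsr), GenomicRanges::granges(utr))
            S4Vectors::mcols(out)$regionClass <-
                c(rep("CDS", length(cdsr)), cls)
        } else {
            out <- GenomicRanges::granges(exr)
            S4Vectors::mcols(out)$regionClass <-
                rep("ncRNA_exon", length(exr))
        }
        introns <- GenomicRanges::setdiff(range(exr), exr,
                                          ignore.strand = TRUE)
        if (length(introns)) {
            S4Vectors::mcols(introns)$regionClass <-
                rep("intron", length(introns))
            out <- c(out, introns)
        }
        GenomicRanges::strand(out) <- strand
        S4Vectors::mcols(out)$transcript_id <- tx
        S4Vectors::mcols(out)$gene_id <- gid[sel][1]
        pieces[[tx]] <- out
    }
    regions <- sort(suppressWarnings(do.call(c, unname(pieces))))
    sl <- GenomeInfoDb::seqlengths(gr)
    sl <- sl[!is.na(sl)]
    new("AnnotationIndex", regions = regions,
        seqlens = stats::setNames(as.integer(sl), names(sl)))
}

setMethod("show", "AnnotationIndex", function(object) {
    cat(sprintf("AnnotationIndex: %d region feature(s), %d transcript(s)\n",
                length(object@regions),
                length(unique(object@regions$transcript_id))))
})

#' Classify a genomic point into a transcript region class
#'
#' Classifies the position of the seed match (not the whole site) against
#' same-strand overlapping transcripts. When isoforms disagree the
#' precedence `UTR3 > UTR5 > ncRNA_exon > CDS > intron > intergenic`
#' applies, so any isoform placing the position in a noncoding region
#' counts. Positions on chromosomes absent from the annotation classify as
#' `intergenic` with a warning.
#'
#' @param annotation an [AnnotationIndex-class].
#' @param chrom chromosome name.
#' @param pos 1-based genomic position (the seed-match position).
#' @param strand `"+"` or `"-"`.
#' @return One of `"UTR5"`, `"UTR3"`, `"CDS"`, `"ncRNA_exon"`, `"intron"`,
#'   `"intergenic"`.
#' @export
classifyRegion <- function(annotation, chrom, pos, strand) {
    stopifnot(is(annotation, "AnnotationIndex"))
    reg <- annotation@regions
    if (!length(reg)) return("intergenic")
    if (!chrom %in% as.character(GenomeInfoDb::seqnames(
            GenomeInfoDb::seqinfo(reg)))) {
        warning("chromosome '", chrom, "' absent from annotation")
        return("intergenic")
    }
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                                strand = strand)
    hits <- GenomicRanges::findOverlaps(q, reg, ignore.strand = FALSE)
    if (!length(hits)) return("intergenic")
    classes <- reg$regionClass[S4Vectors::subjectHits(hits)]
    .REGION_CLASSES[min(match(classes, .REGION_CLASSES))]
}

#' Read a per-base conservation track (bedGraph / wiggle)
#'
#' Loads phyloP-style per-base scores. bedGraph intervals may span
#' multiple bases; queries expand them as constant over the interval.
#' Positions not covered by any interval are treated as missing.
#'
#' @param path bedGraph (`.bedGraph`/`.bg`) or wiggle (`.wig`) file.
#' @return A `GRanges` with a numeric `score` column.
#' @export
readConservation <- function(path) {
    fmt <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig"
           else "bedGraph"
    gr <- rtracklayer::import(path, format = fmt)
    stopifnot(all(is.finite(gr$score)))
    gr
}

.trackScores <- function(track, chrom, positions) {
    if (!length(positions)) return(numeric(0))
    q <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(positions, positions))
    hits <- GenomicRanges::findOverlaps(q, track, ignore.strand = TRUE)
    out <- rep(NA_real_, length(positions))
    out[S4Vectors::queryHits(hits)] <-
        track$score[S4Vectors::subjectHits(hits)]
    out
}

#' Conservation summary for a candidate site
#'
#' Computes the arithmetic mean conservation score over the seed-binding
#' positions and over the site positions predicted to pair with the miRNA
#' 3' window, and applies the positivity rule: under `rule = "mean"`
#' (default) both region means must be strictly positive; under
#' `rule = "all"` every available per-base score must be positive.
#' Positions missing from the track are excluded from the means; if either
#' region has no scored position the site fails with `allMissing = TRUE`.
#'
#' @param track conservation `GRanges` from [readConservation()].
#' @param chrom chromosome of the site.
#' @param seedPositions genomic positions (1-based) of the seed-binding
#'   region; must be non-empty.
#' @param threePrimePositions genomic positions pairing the miRNA 3'
#'   window; must be non-empty.
#' @param rule `"mean"` or `"all"`.
#' @return List with `seedMean`, `threePrimeMean`, `pass`, `allMissing`.
#' @export
conservationStats <- function(track, chrom, seedPositions,
                              threePrimePositions, rule = c("mean", "all")) {
    rule <- match.arg(rule)
    if (!length(seedPositions) || !length(threePrimePositions))
        stop("both position sets must be non-empty")
    s <- .trackScores(track, chrom, seedPositions)
    t3 <- .trackScores(track, chrom, threePrimePositions)
    allMissing <- all(is.na(s)) || all(is.na(t3))
    seedMean <- if (all(is.na(s))) NA_real_ else mean(s, na.rm = TRUE)
    threePrimeMean <- if (all(is.na(t3))) NA_real_ else mean(t3, na.rm = TRUE)
    pass <- if (allMissing) FALSE
        else if (rule == "mean") seedMean > 0 && threePrimeMean > 0
        else all(s > 0, na.rm = TRUE) && all(t3 > 0, na.rm = TRUE)
    list(seedMean = seedMean, threePrimeMean = threePrimeMean,
         pass = isTRUE(pass), allMissing = allMissing)
}
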