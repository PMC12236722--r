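.CHIMERA_COLS <- c("read_id", "mirna_id", "chrom", "start", "end",
                   "strand", "target_seq")

#' Read chimeric miRNA:target interaction records
#'
#' Reads the TSV produced by upstream chimeric-read processing. Required
#' columns: `read_id`, `mirna_id`, `chrom`, `start`, `end` (0-based
#' half-open, BED convention), `strand`, `target_seq` (transcript sense);
#' an optional `sample` column labels libraries. Records whose `mirna_id`
#' is absent from `mirnas` are dropped and reported via the
#' `"dropped_mirna_ids"` attribute.
#'
#' @param tsvPath chimera TSV with header.
#' @param mirnas named list of [MiRNA-class] (see [readMiRNAFasta()]).
#' @return `data.frame` of validated records.
#' @export
readChimeras <- function(tsvPath, mirnas) {
    df <- utils::read.delim(tsvPath, stringsAsFactors = FALSE)
    miss <- setdiff(.CHIMERA_COLS, names(df))
    if (length(miss))
        stop("missing chimera column(s): ", paste(miss, collapse = ", "))
    if (!"sample" %in% names(df)) df$sample <- "sample1"
    bad <- which(df$end <= df$start)
    if (length(bad))
        stop("end <= start at row ", bad[1])
    bad <- which(!df$strand %in% c("+", "-"))
    if (length(bad))
        stop("invalid strand at row ", bad[1])
    bad <- which(nchar(df$target_seq) != df$end - df$start)
    if (length(bad))
        stop("target_seq length does not match interval at row ", bad[1])
    df$target_seq <- vapply(df$target_seq, normalizeRNA, character(1),
                            USE.NAMES = FALSE)
    unknown <- !df$mirna_id %in% names(mirnas)
    dropped <- unique(df$mirna_id[unknown])
    if (any(unknown)) {
        warning(sum(unknown), " record(s) with unknown miRNA id dropped: ",
                paste(dropped, collapse = ", "))
        df <- df[!unknown, , drop = FALSE]
    }
    rownames(df) <- NULL
    attr(df, "dropped_mirna_ids") <- dropped
    df
}

.chimeraGRanges <- function(records) {
    GenomicRanges::GRanges(records$chrom,
                           IRanges::IRanges(records$start + 1L, records$end),
                           strand = records$strand)
}

#' Cluster chimeras into candidate site intervals
#'
#' Per-miRNA, strand-aware overlap merge of chimera target intervals, a
#' lightweight stand-in for an upstream peak caller. Each merged interval
#' is extended by `extend5p` nucleotides at its 5' end (start side on `+`,
#' end side on `-`), clipped at chromosome bounds, and clusters supported
#' by fewer than `minReads` chimeras are dropped.
#'
#' @param records chimera `data.frame` from [readChimeras()].
#' @param minReads minimum chimera support per cluster (default 1).
#' @param extend5p 5'-end extension in nt (default 10).
#' @param seqlens named chromosome lengths for clipping (optional).
#' @return `data.frame` with columns `mirna_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `read_count`.
#' @export
clusterSites <- function(records, minReads = 1L, extend5p = 10L,
                         seqlens = NULL) {
    out <- list()
    for (key in unique(paste(records$mirna_id, records$chrom,
                             records$strand))) {
        sel <- paste(records$mirna_id, records$chrom,
                     records$strand) == key
        gr <- .chimeraGRanges(records[sel, , drop = FALSE])
        red <- GenomicRanges::reduce(gr)
        cnt <- GenomicRanges::countOverlaps(red, gr)
        first <- which(sel)[1]
        out[[key]] <- data.frame(
            mirna_id = records$mirna_id[first],
            chrom = records$chrom[first],
            start = GenomicRanges::start(red) - 1L,
            end = GenomicRanges::end(red),
            strand = records$strand[first],
            read_count = cnt, stringsAsFactors = FALSE)
    }
    cl <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    if (is.null(cl) || !nrow(cl)) {
        return(data.frame(mirna_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), read_count = integer(),
                          stringsAsFactors = FALSE))
    }
    plus <- cl$strand == "+"
    cl$start[plus] <- pmax(0L, cl$start[plus] - as.integer(extend5p))
    cl$end[!plus] <- cl$end[!plus] + as.integer(extend5p)
    if (!is.null(seqlens)) {
        lim <- unname(seqlens[cl$chrom])
        has <- !is.na(lim)
        cl$end[has] <- pmin(cl$end[has], lim[has])
    }
    cl <- cl[cl$read_count >= minReads, , drop = FALSE]
    cl <- cl[order(cl$mirna_id, cl$chrom, cl$start), , drop = FALSE]
    rownames(cl) <- NULL
    cl
}

#' Extract transcript-sense site sequences for clusters
#'
#' @param clusters cluster `data.frame` from [clusterSites()].
#' @param genome a named `DNAStringSet` or path to a genome FASTA.
#' @return `clusters` with an added `site_seq` column (RNA alphabet,
#'   transcript sense: reverse-complemented for `-` strand).
#' @export
extractSiteSequences <- function(clusters, genome) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    seqs <- character(nrow(clusters))
    for (i in seq_len(nrow(clusters))) {
        chrom <- clusters$chrom[i]
        if (!chrom %in% names(genome))
            stop("chromosome '", chrom, "' absent from genome")
        s <- Biostrings::subseq(genome[[chrom]],
                                clusters$start[i] + 1L, clusters$end[i])
        if (clusters$strand[i] == "-")
            s <- Biostrings::reverseComplement(s)
        seqs[i] <- chartr("T", "U", as.character(s))
    }
    clusters$site_seq <- seqs
    clusters
}

# site-local (1-based, transcript sense) -> genomic 1-based
.localToGenomic <- function(cluster, localPos) {
    if (cluster$strand == "+") cluster$start + localPos
    else cluster$end - localPos + 1L
}

.CRITERIA <- c("pass_seed", "pass_region", "pass_bulge", "pass_run3p",
               "pass_conservation", "pass_mfe")

#' Nominate TDMD trigger sites by the six-criterion cascade
#'
#' Evaluates every canonical seed site within every cluster and applies
#' the filter cascade: (1) a canonical seed match (6mer/7mer-A1/7mer-m8/
#' 8mer); (2) location in a noncoding region (5'UTR, 3'UTR or ncRNA
#' exon); (3) no central bulge longer than `maxCentralRun` (default 7)
#' consecutive unpaired miRNA positions after the seed; (4) at least
#' `minThreePrimeRun` (default 6) consecutive base pairs within the miRNA
#' 3' window; (5) positive conservation of the seed-binding and
#' 3'-pairing nucleotides; (6) a negative 3' minimum free energy, the
#' metric by which passing candidates are ranked (most negative = rank 1).
#' All evaluated sites are returned with per-criterion verdicts. A cluster
#' containing no canonical seed site yields one record failing criterion 1
#' with the remaining verdicts `NA`.
#'
#' For ranking, the best passing site represents its cluster; ties in 3'
#' MFE break by seed-class strength, then higher seed conservation mean,
#' then genomic coordinate.
#'
#' @param clusters cluster `data.frame` with `site_seq` (see
#'   [extractSiteSequences()]), or without it if `genome` is supplied.
#' @param mirnas named list of [MiRNA-class].
#' @param annotation an [AnnotationIndex-class].
#' @param conservation conservation `GRanges` from [readConservation()].
#' @param genome optional genome (passed to [extractSiteSequences()]).
#' @param params duplex energy parameters.
#' @param maxCentralRun criterion-3 threshold (nt).
#' @param minThreePrimeRun criterion-4 threshold (nt).
#' @param consRule conservation aggregation rule (see
#'   [conservationStats()]).
#' @return `data.frame` of evaluated sites with architecture metrics,
#'   verdicts, `overall_pass` and `rank`.
#' @export
nominateTriggers <- function(clusters, mirnas, annotation, conservation,
                             genome = NULL,
                             params = defaultEnergyParams(),
                             maxCentralRun = 7L, minThreePrimeRun = 6L,
                             consRule = c("mean", "all")) {
    consRule <- match.arg(consRule)
    if (!"site_seq" %in% names(clusters)) {
        if (is.null(genome))
            stop("clusters lack 'site_seq'; supply 'genome'")
        clusters <- extractSiteSequences(clusters, genome)
    }
    rows <- list()
    for (i in seq_len(nrow(clusters))) {
        cl <- clusters[i, ]
        mirna <- mirnas[[cl$mirna_id]]
        if (is.null(mirna))
            stop("miRNA '", cl$mirna_id, "' not found")
        sites <- findSeedSites(mirna, cl$site_seq)
        if (!nrow(sites)) {
            rows[[length(rows) + 1L]] <- data.frame(
                cluster = i, mirna_id = cl$mirna_id, chrom = cl$chrom,
                start = cl$start, end = cl$end, strand = cl$strand,
                read_count = cl$read_count,
                seed_genomic_pos = NA_integer_,
                region_class = NA_character_, seed_class = "none",
                central_mismatch_run = NA_integer_,
                three_prime_pair_run = NA_integer_,
                three_prime_mfe = NA_real_,
                seed_cons_mean = NA_real_, three_prime_cons_mean = NA_real_,
                pass_seed = FALSE, pass_region = NA, pass_bulge = NA,
                pass_run3p = NA, pass_conservation = NA, pass_mfe = NA,
                overall_pass = FALSE, stringsAsFactors = FALSE)
            next
        }
        for (k in seq_len(nrow(sites))) {
            e <- sites$seedEnd[k]
            arch <- evaluateArchitecture(mirna, cl$site_seq, e, params)
            seedGpos <- .localToGenomic(cl, e)
            region <- classifyRegion(annotation, cl$chrom, seedGpos,
                                     cl$strand)
            seedLocal <- arch@seedSiteInterval[1]:arch@seedSiteInterval[2]
            consSeed <- .localToGenomic(cl, seedLocal)
            cons3p <- if (length(arch@threePrimeSitePositions))
                .localToGenomic(cl, arch@threePrimeSitePositions)
                else integer(0)
            cons <- if (length(cons3p))
                conservationStats(conservation, cl$chrom, consSeed, cons3p,
                                  rule = consRule)
                else list(seedMean = NA_real_, threePrimeMean = NA_real_,
                          pass = FALSE, allMissing = TRUE)
            v <- c(pass_seed = TRUE,
                   pass_region = region %in% c("UTR5", "UTR3", "ncRNA_exon"),
                   pass_bulge = arch@centralMismatchRun <= maxCentralRun,
                   pass_run3p = arch@threePrimePairRun >= minThreePrimeRun,
                   pass_conservation = cons$pass,
                   pass_mfe = arch@threePrimeMfe < 0)
            rows[[length(rows) + 1L]] <- data.frame(
                cluster = i, mirna_id = cl$mirna_id, chrom = cl$chrom,
                start = cl$start, end = cl$end, strand = cl$strand,
                read_count = cl$read_count,
                seed_genomic_pos = seedGpos,
                region_class = region, seed_class = arch@seedClass,
                central_mismatch_run = arch@centralMismatchRun,
                three_prime_pair_run = arch@threePrimePairRun,
                three_prime_mfe = arch@threePrimeMfe,
                seed_cons_mean = cons$seedMean,
                three_prime_cons_mean = cons$threePrimeMean,
                pass_seed = v[["pass_seed"]],
                pass_region = v[["pass_region"]],
                pass_bulge = v[["pass_bulge"]],
                pass_run3p = v[["pass_run3p"]],
                pass_conservation = v[["pass_conservation"]],
                pass_mfe = v[["pass_mfe"]],
                overall_pass = all(v), stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out$rank <- NA_integer_
    if (any(out$overall_pass)) {
        p <- out[out$overall_pass, ]
        # best site per cluster represents the cluster
        keyOrd <- order(p$three_prime_mfe,
                        match(p$seed_class, SEED_MATCH_CLASSES),
                        -ifelse(is.na(p$seed_cons_mean), -Inf,
                                p$seed_cons_mean),
                        p$chrom, p$start)
        p <- p[keyOrd, ]
        repIdx <- rownames(p)[!duplicated(p$cluster)]
        reps <- out[repIdx, ]
        for (m in unique(reps$mirna_id)) {
            sel <- repIdx[reps$mirna_id == m]
            out[sel, "rank"] <- seq_along(sel)
        }
    }
    out
}

#' Proportion of chimeras per transcript region
#'
#' Classifies each chimera's location and tabulates per-sample
#' proportions. With `seedFilter = TRUE` (default) only chimeras whose
#' target fragment contains a canonical seed match for the ligated miRNA
#' are counted, and the location classified is the seed-match position;
#' otherwise the fragment midpoint is used for seedless chimeras.
#'
#' @param records chimera `data.frame` from [readChimeras()].
#' @param mirnas named list of [MiRNA-class].
#' @param annotation an [AnnotationIndex-class].
#' @param seedFilter restrict to seed-matched chimeras (default `TRUE`).
#' @return `data.frame` with columns `sample`, `region_class`, `count`,
#'   `proportion`; proportions sum to 1 within each sample. Empty input
#'   yields an empty table.
#' @export
chimeraLocationProfile <- function(records, mirnas, annotation,
                                   seedFilter = TRUE) {
    empty <- data.frame(sample = character(), region_class = character(),
                        count = integer(), proportion = numeric(),
                        stringsAsFactors = FALSE)
    if (!nrow(records)) return(empty)
    cls <- character(nrow(records))
    keep <- logical(nrow(records))
    for (i in seq_len(nrow(records))) {
        rec <- records[i, ]
        mirna <- mirnas[[rec$mirna_id]]
        sites <- findSeedSites(mirna, rec$target_seq)
        if (nrow(sites)) {
            best <- which.min(match(sites$class, SEED_MATCH_CLASSES))
            pos <- .localToGenomic(rec, sites$seedEnd[best])
            keep[i] <- TRUE
        } else {
            pos <- .localToGenomic(
                rec, as.integer(ceiling((rec$end - rec$start) / 2)))
            keep[i] <- !seedFilter
        }
        cls[i] <- classifyRegion(annotation, rec$chrom, pos, rec$strand)
    }
    rec <- records[keep, , drop = FALSE]; cls <- cls[keep]
    if (!nrow(rec)) return(empty)
    tab <- as.data.frame(table(sample = rec$sample, region_class = cls),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "count"
    tab <- tab[tab$count > 0, , drop = FALSE]
    tot <- stats::ave(tab$count, tab$sample, FUN = sum)
    tab$proportion <- tab$count / tot
    tab[order(tab$sample, -tab$count), ]
}

#' Chimera enrichment gain (RPM in enriched vs unenriched libraries)
#'
#' Normalizes per-miRNA chimera counts to reads per million chimeras in
#' each library and reports the enrichment ratio. Ratios with a zero
#' unenriched RPM are `Inf` and flagged.
#'
#' @param enrichedCounts,unenrichedCounts named non-negative integer
#'   vectors of chimera counts per miRNA.
#' @return `data.frame` with `mirna_id`, `rpm_enriched`, `rpm_unenriched`,
#'   `ratio`, `infinite_ratio`.
#' @export
enrichmentGain <- function(enrichedCounts, unenrichedCounts) {
    stopifnot(all(enrichedCounts >= 0), all(unenrichedCounts >= 0))
    if (sum(enrichedCounts) == 0 || sum(unenrichedCounts) == 0)
        stop("a library with zero chimeras cannot be normalized")
    ids <- union(names(enrichedCounts), names(unenrichedCounts))
    e <- stats::setNames(rep(0, length(ids)), ids)
    u <- e
    e[names(enrichedCounts)] <- enrichedCounts
    u[names(unenrichedCounts)] <- unenrichedCounts
    rpmE <- e / sum(e) * 1e6
    rpmU <- u / sum(u) * 1e6
    data.frame(mirna_id = ids, rpm_enriched = unname(rpmE),
               rpm_unenriched = unname(rpmU),
               ratio = unname(rpmE / rpmU),
               infinite_ratio = unname(rpmU == 0 & rpmE > 0),
               stringsAsFactors = FALSE)
}

.CANDIDATE_COLS <- c("mirna_id", "gene", "chrom", "start", "end", "strand",
                     "region_class", "seed_class", "central_mismatch_run",
                     "three_prime_pair_run", "three_prime_mfe",
                     "seed_cons_mean", "three_prime_cons_mean",
                     .CRITERIA, "overall_pass", "rank")

#' Write nominated candidates to TSV
#'
#' Emits the stable, round-trip-readable candidate table (BED-convention
#' coordinates). A missing `gene` column is filled with `NA`.
#'
#' @param candidates output of [nominateTriggers()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCandidates <- function(candidates, path) {
    if (!"gene" %in% names(candidates))
        candidates[["gene"]] <- rep(NA_character_, nrow(candidates))
    out <- candidates[, .CANDIDATE_COLS, drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read a candidate TSV written by [writeCandidates()]
#'
#' @param path candidate TSV.
#' @return `data.frame` with the candidate columns.
#' @export
readCandidates <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(rank = "integer"))
}
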