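# Fixture generator: toy genome + annotation + conservation + chimera
# libraries with planted trigger/canonical/decoy sites and exact ground
# truth, so the whole nomination pipeline is testable offline.

.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
    force(code)
}

.randDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
.randRNA <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                     replace = TRUE), collapse = "")

#' Generate random mature miRNA sequences
#'
#' @param n number of miRNAs.
#' @param length mature length (default 22).
#' @param seed RNG seed.
#' @return Named list of [MiRNA-class] objects (`synthmiR-1`, ...).
#' @export
generateMiRNAs <- function(n = 10L, length = 22L, seed = 1L) {
    .withSeed(seed, {
        out <- lapply(seq_len(n), function(i)
            MiRNA(sprintf("synthmiR-%d", i), .randRNA(length)))
        names(out) <- vapply(out, mirnaId, character(1))
        out
    })
}

#' Generate a toy genome with annotated genes
#'
#' Random-background chromosomes carrying non-overlapping genes on both
#' strands: mRNAs with a 200-nt 5'UTR, 900-nt CDS and 900-nt 3'UTR (every
#' fourth mRNA carries a 300-nt intron inside the CDS), and single-exon
#' ncRNA genes (every fourth gene). The GTF contains gene/transcript/exon/
#' CDS rows only; UTRs are left to exon-minus-CDS arithmetic.
#'
#' @param nGenes number of genes (default 20).
#' @param nChroms chromosomes (default 2).
#' @param chromLen chromosome length in nt (default 1e5).
#' @param seed RNG seed.
#' @return List with `genome` (`DNAStringSet`), `features` (GTF-style
#'   `data.frame`, 1-based closed), `regions` (per-gene region intervals
#'   for planting), `seqlens`.
#' @export
generateGenome <- function(nGenes = 20L, nChroms = 2L, chromLen = 1e5L,
                           seed = 1L) {
    stopifnot(nGenes >= 1L, nChroms >= 1L)
    .withSeed(seed, {
        chromLen <- as.integer(chromLen)
        chroms <- sprintf("chrS%d", seq_len(nChroms))
        genome <- Biostrings::DNAStringSet(
            vapply(chroms, function(x) .randDNA(chromLen), character(1)))
        names(genome) <- chroms
        feats <- list(); regs <- list()
        cursor <- stats::setNames(rep(1000L, nChroms), chroms)
        for (g in seq_len(nGenes)) {
            chrom <- chroms[(g - 1L) %% nChroms + 1L]
            strand <- if (g %% 2L == 0L) "-" else "+"
            ncRNA <- g %% 4L == 0L
            intron <- !ncRNA && g %% 4L == 2L
            txLen <- if (ncRNA) 1200L else if (intron) 2300L else 2000L
            s <- cursor[[chrom]]
            e <- s + txLen - 1L
            if (e + 1000L > chromLen)
                stop("chromosome too short for requested gene structure")
            cursor[[chrom]] <- e + 1000L
            gid <- sprintf("gene%02d", g); tid <- sprintf("tx%02d", g)
            addF <- function(type, fs, fe)
                data.frame(chrom = chrom, type = type, start = fs, end = fe,
                           strand = strand, gene_id = gid,
                           transcript_id = tid, stringsAsFactors = FALSE)
            addR <- function(cls, fs, fe)
                data.frame(gene_id = gid, transcript_id = tid, chrom = chrom,
                           strand = strand, regionClass = cls,
                           start = fs, end = fe, stringsAsFactors = FALSE)
            fr <- list(addF("gene", s, e), addF("transcript", s, e))
            rr <- list()
            if (ncRNA) {
                fr <- c(fr, list(addF("exon", s, e)))
                rr <- c(rr, list(addR("ncRNA_exon", s, e)))
            } else {
                # genomic layout 5'->3' in transcript orientation
                segs <- if (intron)
                    list(c("UTR5", 200L), c("CDS", 450L), c("intron", 300L),
                         c("CDS", 450L), c("UTR3", 900L))
                else
                    list(c("UTR5", 200L), c("CDS", 900L), c("UTR3", 900L))
                if (strand == "-") segs <- rev(segs)
                pos <- s
                exonRuns <- list(); cur <- NULL
                for (sg in segs) {
                    len <- as.integer(sg[2]); cls <- sg[1]
                    fs <- pos; fe <- pos + len - 1L; pos <- fe + 1L
                    if (cls == "intron") {
                        if (!is.null(cur)) exonRuns <- c(exonRuns, list(cur))
                        cur <- NULL
                    } else {
                        cur <- if (is.null(cur)) c(fs, fe)
                               else c(cur[1], fe)
                        if (cls == "CDS")
                            fr <- c(fr, list(addF("CDS", fs, fe)))
                        rr <- c(rr, list(addR(cls, fs, fe)))
                    }
                }
                if (!is.null(cur)) exonRuns <- c(exonRuns, list(cur))
                for (ex in exonRuns)
                    fr <- c(fr, list(addF("exon", ex[1], ex[2])))
            }
            feats[[g]] <- do.call(rbind, fr)
            regs[[g]] <- do.call(rbind, rr)
        }
        list(genome = genome,
             features = do.call(rbind, c(feats, list(make.row.names = FALSE))),
             regions = do.call(rbind, c(regs, list(make.row.names = FALSE))),
             seqlens = stats::setNames(rep(chromLen, nChroms), chroms))
    })
}

#' Write a features table as GTF
#'
#' @param features the `features` element of [generateGenome()].
#' @param path output GTF.
#' @return `path`, invisibly.
#' @export
writeGTF <- function(features, path) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     features$gene_id, features$transcript_id)
    lines <- sprintf("%s\ttriggerscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     features$chrom, features$type, features$start,
                     features$end, features$strand, attrs)
    writeLines(lines, path)
    invisible(path)
}

.PLANT_KINDS <- c("trigger", "canonical", "decoy_seed_mismatch",
                  "decoy_cds", "decoy_bulge", "decoy_short3p",
                  "decoy_nonconserved")

#' Default planting specification table
#'
#' Three full trigger-architecture sites, five canonical (seed-only)
#' sites, and one decoy for each of the five single-violation kinds.
#' Trigger/decoy knobs follow the filter thresholds: triggers use an 8mer
#' seed, an 8-nt 3' run and a 4-nt central bulge; `decoy_bulge` stretches
#' the bulge to 8 nt (one past the 7-nt limit), `decoy_short3p` shortens
#' the 3' run to 5 nt (one short of the 6-nt requirement).
#'
#' @param mirnaIds miRNA ids to draw from (recycled as needed).
#' @return `data.frame` of plant specs, one row per site.
#' @export
defaultPlantSpecs <- function(mirnaIds) {
    kinds <- c(rep("trigger", 3), rep("canonical", 5),
               "decoy_seed_mismatch", "decoy_cds", "decoy_bulge",
               "decoy_short3p", "decoy_nonconserved")
    n <- length(kinds)
    ids <- rep_len(mirnaIds, n)
    data.frame(
        site_id = sprintf("site%02d", seq_len(n)),
        mirna_id = ids, kind = kinds,
        region = ifelse(kinds == "decoy_cds", "CDS", "UTR3"),
        seed_class = "8mer",
        three_prime_run = ifelse(kinds == "canonical", 0L,
                          ifelse(kinds == "decoy_bulge", 6L,
                          ifelse(kinds == "decoy_short3p", 5L, 8L))),
        bulge_len = ifelse(kinds == "decoy_bulge", 8L, 4L),
        conserved = kinds != "decoy_nonconserved",
        stringsAsFactors = FALSE)
}

# letters that can WC/GU-pair with x
.pairsWith <- function(x) switch(x, A = "U", C = "G", G = c("C", "U"),
                                 U = c("A", "G"))
.canPair <- function(a, b) b %in% .pairsWith(a)

# TRUE if u (site, 5'->3') and m (miRNA region, 5'->3') admit >= minRun
# consecutive antiparallel pairs in some register
.hasHelix <- function(u, m, minRun) {
    uu <- strsplit(u, "")[[1]]; mm <- rev(strsplit(m, "")[[1]])
    nu <- length(uu); nm <- length(mm)
    if (nu < minRun || nm < minRun) return(FALSE)
    for (d in (-(nm - minRun)):(nu - minRun)) {
        run <- 0L
        for (k in seq_len(nm)) {
            i <- k + d
            if (i < 1L || i > nu) { run <- 0L; next }
            if (.canPair(uu[i], mm[k])) {
                run <- run + 1L
                if (run >= minRun) return(TRUE)
            } else run <- 0L
        }
    }
    FALSE
}

# Random RNA filler. Constraints keep planted architectures exact: no
# >= 6-nt pairable run with the miRNA remainder (so a filler can never
# satisfy the 3'-run criterion by chance), blocked boundary letters (so
# the planted helix cannot be extended by stacking), and no stray seed
# hexamer. Weak incidental complementarity is permitted -- attaching a
# short helix through a loop costs more than it gains under the bundled
# parameters -- and the final arbiter is exact post-construction
# verification with resampling.
.fillerRNA <- function(len, mirRemainder, avoidHexamers,
                       blockFirst = NULL, blockLast = NULL,
                       tries = 200L) {
    if (len == 0L) return("")
    for (t in seq_len(tries)) {
        x <- .randRNA(len)
        xs <- strsplit(x, "")[[1]]
        if (!is.null(blockFirst) && .canPair(xs[1L], blockFirst)) next
        if (!is.null(blockLast) && .canPair(xs[len], blockLast)) next
        if (!is.null(mirRemainder) && .hasHelix(x, mirRemainder, 6L)) next
        if (any(vapply(avoidHexamers, function(h) grepl(h, x, fixed = TRUE),
                       logical(1)))) next
        return(x)
    }
    stop("could not sample a non-pairing filler sequence")
}

# Build one planted site in transcript sense plus its exact local geometry.
# Layout 5'->3': pad5 | rc(3' run) | spacer(bulge) | rc(seed 2-8) | A | pad3
.buildSite <- function(mirna, spec, pad5 = 20L, minLen = 53L) {
    mir <- strsplit(mirna@sequence, "")[[1]]
    n <- length(mir)
    w <- mirna@threePrimeWindowLen
    L <- as.integer(spec$three_prime_run)
    B <- as.integer(spec$bulge_len)
    seedLast <- 8L  # planted anchors are 8mer-style
    p <- 9L + B     # miRNA position where the 3' run starts
    if (L > 0L && (p + L - 1L > n || p < n - w + 1L))
        stop("3' run does not fit the miRNA 3' window")
    remainder <- substr(mirna@sequence, 9L, n)
    seedSeg <- rnaReverseComplement(substr(mirna@sequence, 2L, seedLast))
    hex <- rnaReverseComplement(substr(mirna@sequence, 2L, 7L))
    rc3p <- if (L > 0L)
        rnaReverseComplement(substr(mirna@sequence, p, p + L - 1L))
        else ""
    if (spec$kind == "decoy_seed_mismatch") {
        # substitute the site base opposite miRNA position 4 with a
        # non-pairing letter (keeps everything else intact)
        idx <- seedLast - 4L + 1L  # position within seedSeg (5'->3')
        cur <- substr(seedSeg, idx, idx)
        repl <- setdiff(c("A", "C", "G", "U"),
                        c(cur, .pairsWith(mir[4L])))[1]
        substr(seedSeg, idx, idx) <- repl
    }
    pad3 <- max(6L, minLen - (pad5 + L + B + (seedLast - 1L) + 1L))
    spacer <- .fillerRNA(B, remainder, hex,
                         blockFirst = if (L > 0L) mir[p - 1L] else NULL,
                         blockLast = mir[9L])
    padA <- .fillerRNA(pad5, remainder, hex,
                       blockLast = if (L > 0L && p + L <= n) mir[p + L]
                                   else NULL)
    padB <- .fillerRNA(pad3, NULL, hex)
    site <- paste0(padA, rc3p, spacer, seedSeg, "A", padB)
    runStart <- pad5 + 1L
    seedStart <- pad5 + nchar(rc3p) + B + 1L
    # seedSeg covers miRNA 8..2 -> its LAST base pairs miRNA position 2
    seedEnd <- seedStart + (seedLast - 2L)
    gap2 <- if (L > 0L) n - (p + L - 1L) else 0L
    list(site = site,
         seedEnd = seedEnd,
         seedLocal = seedStart:seedEnd,
         run3pLocal = if (L > 0L) runStart:(runStart + L - 1L) else integer(0),
         expected = list(
             seed_class = if (spec$kind == "decoy_seed_mismatch") "none"
                          else "8mer",
             central_run = if (L > 0L) max(B, gap2) else NA_integer_,
             run3p = if (L > 0L) min(L, (p + L - 1L) -
                                        max(p, n - w + 1L) + 1L)
                     else NA_integer_))
}

# exact-architecture verification of a candidate construction
.verifyPlanted <- function(mirna, spec, cand, params) {
    if (spec$kind == "decoy_seed_mismatch")
        return(nrow(findSeedSites(mirna, cand$site)) == 0L)
    sites <- findSeedSites(mirna, cand$site)
    if (nrow(sites) != 1L || sites$seedEnd != cand$seedEnd) return(FALSE)
    a <- evaluateArchitecture(mirna, cand$site, cand$seedEnd, params)
    if (spec$three_prime_run == 0L) {
        if (!identical(seedClass(a), "8mer") ||
            threePrimePairRunLength(a) >= 6L) return(FALSE)
        # canonical sites carry no single dominant helix, so the MFE
        # co-fold optimum can shift when the pipeline evaluates the
        # cluster-cropped view of the site (local 3..52 for the default
        # 40-nt fragments with 10-nt 5' extension); verify that view too
        cropped <- substr(cand$site, 3L, min(52L, nchar(cand$site)))
        aC <- evaluateArchitecture(mirna, cropped, cand$seedEnd - 2L,
                                   params)
        return(identical(seedClass(aC), "8mer") &&
               threePrimePairRunLength(aC) < 6L)
    }
    identical(seedClass(a), cand$expected$seed_class) &&
        centralMismatchRunLength(a) == cand$expected$central_run &&
        threePrimePairRunLength(a) == cand$expected$run3p &&
        identical(sort(a@threePrimeSitePositions),
                  as.integer(sort(cand$run3pLocal))) &&
        threePrimeMfeValue(a) < 0
}

#' Plant ground-truth sites into a toy genome
#'
#' Writes each requested site into a gene region of the requested class:
#' the reverse complement of the miRNA seed (positions 2-8 plus the A1
#' adenosine) and, for architectures with 3' pairing, the reverse
#' complement of a run of `three_prime_run` nucleotides of the miRNA 3'
#' window, separated by a spacer of `bulge_len` nucleotides. Spacers and
#' pads are rejection-sampled (no long pairable run with the miRNA
#' remainder, no helix-extending boundary letters, no stray seed
#' hexamer), and every planted locus is verified to reproduce its
#' intended architecture metrics exactly, resampling if needed. If a
#' miRNA's own sequence makes a spec unrealizable (e.g. its 3' region
#' happens to contain the seed hexamer) the next miRNA in `mirnas` is
#' substituted; the truth table records the miRNA actually used.
#'
#' @param genomeObj result of [generateGenome()].
#' @param mirnas named list of [MiRNA-class].
#' @param specs plant-spec `data.frame` (see [defaultPlantSpecs()]).
#' @param seed RNG seed.
#' @param params duplex energy parameters (used for verification).
#' @return List with the modified `genome` and `truth`, a `data.frame`
#'   with one row per planted site: genomic interval (0-based half-open),
#'   seed position, expected metrics, expected failing criterion.
#' @export
plantSites <- function(genomeObj, mirnas, specs, seed = 1L,
                       params = defaultEnergyParams()) {
    .withSeed(seed, {
        genome <- genomeObj$genome
        regions <- genomeObj$regions
        used <- character(0)
        truth <- list()
        for (i in seq_len(nrow(specs))) {
            spec <- specs[i, ]
            hosts <- regions[regions$regionClass == spec$region &
                             !(regions$gene_id %in% used) &
                             regions$end - regions$start + 1L >= 120L, ]
            if (!nrow(hosts))
                stop("no free host region of class ", spec$region)
            host <- hosts[1, ]
            used <- c(used, host$gene_id)
            mirOrder <- unique(c(spec$mirna_id,
                                 setdiff(names(mirnas), spec$mirna_id)))
            built <- NULL
            for (mid in mirOrder) {
                mirna <- mirnas[[mid]]
                for (try in 1:25) {
                    cand <- tryCatch(.buildSite(mirna, spec),
                                     error = function(e) NULL)
                    if (!is.null(cand) &&
                        .verifyPlanted(mirna, spec, cand, params)) {
                        built <- cand; break
                    }
                }
                if (!is.null(built)) break
            }
            if (is.null(built))
                stop("failed to construct site ", spec$site_id)
            siteLen <- nchar(built$site)
            mid2 <- (host$start + host$end) %/% 2L
            gs <- mid2 - siteLen %/% 2L          # 1-based genomic start
            ge <- gs + siteLen - 1L
            dna <- chartr("U", "T", built$site)
            if (host$strand == "-")
                dna <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(dna)))
            genome[[host$chrom]] <- Biostrings::replaceAt(
                genome[[host$chrom]], IRanges::IRanges(gs, ge), dna)
            loc2gen <- function(loc) {
                if (!length(loc)) return(integer(0))
                if (host$strand == "+") gs + loc - 1L else ge - loc + 1L
            }
            truth[[i]] <- data.frame(
                site_id = spec$site_id, mirna_id = mirnaId(mirna),
                kind = spec$kind, region = spec$region,
                chrom = host$chrom, strand = host$strand,
                gene_id = host$gene_id,
                start = gs - 1L, end = ge,        # BED convention
                seed_genomic_pos = loc2gen(built$seedEnd),
                seed_positions = paste(loc2gen(built$seedLocal),
                                       collapse = ","),
                run3p_positions = paste(loc2gen(built$run3pLocal),
                                        collapse = ","),
                exp_seed_class = built$expected$seed_class,
                exp_central_run = built$expected$central_run,
                exp_run3p = built$expected$run3p,
                conserved = spec$conserved,
                exp_fail = switch(spec$kind,
                    trigger = "",
                    canonical = "pass_run3p",
                    decoy_seed_mismatch = "pass_seed",
                    decoy_cds = "pass_region",
                    decoy_bulge = "pass_bulge",
                    decoy_short3p = "pass_run3p",
                    decoy_nonconserved = "pass_conservation"),
                stringsAsFactors = FALSE)
        }
        list(genome = genome,
             truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
    })
}

#' Simulate chimeric reads around planted sites
#'
#' Emits `depth` chimera records per planted site: `fragLen`-nt target
#' fragments positioned over the site, optionally jittered, in transcript
#' sense. Background records pairing random miRNAs with random genomic
#' fragments are added at rate `backgroundRate` (expected count per
#' planted site).
#'
#' @param genome `DNAStringSet` (after planting).
#' @param truth truth `data.frame` from [plantSites()].
#' @param mirnas named list of [MiRNA-class].
#' @param depth chimeras per site (default 5).
#' @param backgroundRate expected background chimeras per planted site.
#' @param fragLen fragment length (default 40).
#' @param jitterSd positional jitter SD in nt (default 0).
#' @param seed RNG seed.
#' @param sampleName sample label.
#' @return Chimera `data.frame` in [readChimeras()] layout.
#' @export
simulateChimeras <- function(genome, truth, mirnas, depth = 5L,
                             backgroundRate = 0, fragLen = 40L,
                             jitterSd = 0, seed = 1L, sampleName = "sim1") {
    .withSeed(seed, {
        rows <- list()
        rid <- 0L
        seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
        grab <- function(chrom, s0, e0, strand) {
            s <- Biostrings::subseq(genome[[chrom]], s0 + 1L, e0)
            if (strand == "-")
                s <- Biostrings::reverseComplement(s)
            chartr("T", "U", as.character(s))
        }
        for (i in seq_len(nrow(truth))) {
            tr <- truth[i, ]
            for (d in seq_len(depth)) {
                jit <- as.integer(round(stats::rnorm(1, 0, jitterSd)))
                # the fragment's 5' end (transcript sense) sits 12 nt into
                # the planted segment so the 10-nt cluster extension stays
                # inside sampled, hexamer-free sequence
                if (tr$strand == "+") {
                    fs <- tr$start + 12L + jit
                    fe <- fs + fragLen
                } else {
                    fe <- tr$end - 12L + jit
                    fs <- fe - fragLen
                }
                fs <- max(0L, fs); fe <- min(fe, seqlens[[tr$chrom]])
                rid <- rid + 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    read_id = sprintf("read%05d", rid),
                    mirna_id = tr$mirna_id, chrom = tr$chrom,
                    start = fs, end = fe, strand = tr$strand,
                    target_seq = grab(tr$chrom, fs, fe, tr$strand),
                    sample = sampleName, stringsAsFactors = FALSE)
            }
        }
        nBg <- stats::rpois(1, backgroundRate * nrow(truth))
        for (b in seq_len(nBg)) {
            chrom <- sample(names(genome), 1)
            fs <- sample.int(seqlens[[chrom]] - fragLen - 1L, 1)
            strand <- sample(c("+", "-"), 1)
            rid <- rid + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                read_id = sprintf("read%05d", rid),
                mirna_id = sample(names(mirnas), 1), chrom = chrom,
                start = fs, end = fs + fragLen, strand = strand,
                target_seq = grab(chrom, fs, fs + fragLen, strand),
                sample = sampleName, stringsAsFactors = FALSE)
        }
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    })
}

#' Simulate a phyloP-style conservation track
#'
#' Planted seed-binding and 3'-pairing positions of conserved sites score
#' `conservedLevel` (plus optional per-base noise); everything else scores
#' `backgroundLevel`. The result covers every base of every chromosome
#' with non-overlapping intervals.
#'
#' @param genome `DNAStringSet` (defines chromosome extents).
#' @param truth truth `data.frame` from [plantSites()].
#' @param conservedLevel score at conserved planted positions (default 2).
#' @param backgroundLevel score elsewhere (default -0.5).
#' @param noiseSd Gaussian noise SD at planted positions (default 0).
#' @param seed RNG seed.
#' @return `GRanges` with `score`, suitable for [conservationStats()] and
#'   for export via [writeBedGraph()].
#' @export
simulateConservation <- function(genome, truth, conservedLevel = 2,
                                 backgroundLevel = -0.5, noiseSd = 0,
                                 seed = 1L) {
    .withSeed(seed, {
        pieces <- list()
        for (chrom in names(genome)) {
            len <- Biostrings::width(genome)[names(genome) == chrom]
            sel <- truth[truth$chrom == chrom & truth$conserved, ,
                         drop = FALSE]
            pos <- sort(unique(unlist(lapply(
                seq_len(nrow(sel)), function(i) {
                    v <- c(strsplit(sel$seed_positions[i], ",")[[1]],
                           strsplit(sel$run3p_positions[i], ",")[[1]])
                    as.integer(v[nzchar(v)])
                }))))
            if (length(pos)) {
                consGr <- GenomicRanges::GRanges(
                    chrom, IRanges::IRanges(pos, pos),
                    score = conservedLevel + stats::rnorm(length(pos),
                                                          0, noiseSd))
                bgGr <- GenomicRanges::setdiff(
                    GenomicRanges::GRanges(chrom, IRanges::IRanges(1, len)),
                    GenomicRanges::granges(consGr))
                bgGr$score <- rep(backgroundLevel, length(bgGr))
                pieces[[chrom]] <- c(consGr, bgGr)
            } else {
                pieces[[chrom]] <- GenomicRanges::GRanges(
                    chrom, IRanges::IRanges(1, len),
                    score = backgroundLevel)
            }
        }
        sort(suppressWarnings(do.call(c, unname(pieces))),
             ignore.strand = TRUE)
    })
}

#' Write a scored GRanges as bedGraph
#'
#' @param gr `GRanges` with a `score` column.
#' @param path output bedGraph.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(gr, path) {
    lines <- sprintf("%s\t%d\t%d\t%g",
                     as.character(GenomeInfoDb::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L,
                     GenomicRanges::end(gr), gr$score)
    writeLines(lines, path)
    invisible(path)
}

#' Precision/recall of trigger recovery against planted ground truth
#'
#' Matches evaluated candidate rows to planted sites by miRNA and
#' interval overlap. Precision and recall score cluster-level
#' `overall_pass` against `kind == "trigger"`. The confusion table
#' records, per planted site, which criteria failed and whether the
#' outcome is "clean": triggers must fail nothing; each decoy must fail
#' exactly its planted criterion; canonical sites must fail the 3'-run
#' criterion (other architecture-dependent verdicts are unconstrained).
#'
#' @param candidates output of [nominateTriggers()].
#' @param truth truth `data.frame` from [plantSites()].
#' @return List with `precision`, `recall`, `nPassClusters`, and
#'   `confusion`, a per-site `data.frame`.
#' @export
evaluateRecovery <- function(candidates, truth) {
    conf <- list()
    matchedPassCluster <- integer(0)
    for (i in seq_len(nrow(truth))) {
        tr <- truth[i, ]
        rows <- candidates[candidates$mirna_id == tr$mirna_id &
                           candidates$chrom == tr$chrom &
                           candidates$strand == tr$strand &
                           candidates$start < tr$end &
                           candidates$end > tr$start, , drop = FALSE]
        if (!nrow(rows))
            stop("no evaluated candidate overlaps planted site ",
                 tr$site_id)
        hit <- rows[!is.na(rows$seed_genomic_pos) &
                    rows$seed_genomic_pos == tr$seed_genomic_pos, ,
                    drop = FALSE]
        if (!nrow(hit)) hit <- rows[1, , drop = FALSE]
        vm <- unlist(hit[1, .CRITERIA])
        failed <- .CRITERIA[!is.na(vm) & !vm]
        passed <- any(rows$overall_pass)
        clean <- switch(tr$kind,
            trigger = length(failed) == 0L && passed,
            canonical = !passed && "pass_run3p" %in% failed,
            !passed && identical(failed, tr$exp_fail))
        if (passed)
            matchedPassCluster <- union(matchedPassCluster,
                                        rows$cluster[rows$overall_pass])
        conf[[i]] <- data.frame(
            site_id = tr$site_id, kind = tr$kind,
            passed = passed,
            failedCriteria = paste(failed, collapse = ";"),
            cleanViolation = clean, stringsAsFactors = FALSE)
    }
    conf <- do.call(rbind, c(conf, list(make.row.names = FALSE)))
    passClusters <- unique(candidates$cluster[candidates$overall_pass])
    truePos <- sum(conf$passed & conf$kind == "trigger")
    nTrig <- sum(conf$kind == "trigger")
    precision <- if (!length(passClusters)) NA_real_
                 else truePos / length(passClusters)
    recall <- if (nTrig == 0L) NA_real_ else truePos / nTrig
    list(precision = precision, recall = recall,
         nPassClusters = length(passClusters), confusion = conf)
}

#' Generate a complete synthetic trigger study on disk
#'
#' Convenience wrapper chaining [generateGenome()], [generateMiRNAs()],
#' [plantSites()], [simulateChimeras()] and [simulateConservation()], and
#' writing `genome.fa`, `annotation.gtf`, `conservation.bedGraph`,
#' `mirnas.fa`, `chimeras.tsv` and `truth.tsv` into `outDir`. All
#' randomness derives from `seed`.
#'
#' @param outDir output directory (created if needed).
#' @param seed master RNG seed.
#' @param nGenes,nChroms,chromLen genome shape (see [generateGenome()]).
#' @param nMirnas number of miRNAs.
#' @param specs plant specs; default [defaultPlantSpecs()].
#' @param depth,backgroundRate,jitterSd chimera simulation knobs.
#' @return Invisible list with the in-memory objects (`genome`, `mirnas`,
#'   `truth`, `chimeras`, `conservation`, `features`, `seqlens`) and file
#'   `paths`.
#' @export
simulateTriggerStudy <- function(outDir, seed = 1L, nGenes = 20L,
                                 nChroms = 2L, chromLen = 1e5L,
                                 nMirnas = 10L, specs = NULL,
                                 depth = 5L, backgroundRate = 0,
                                 jitterSd = 0) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(seed)
    gen <- generateGenome(nGenes, nChroms, chromLen, seed = seed)
    mirnas <- generateMiRNAs(nMirnas, seed = seed + 1L)
    if (is.null(specs)) specs <- defaultPlantSpecs(names(mirnas))
    planted <- plantSites(gen, mirnas, specs, seed = seed + 2L)
    chim <- simulateChimeras(planted$genome, planted$truth, mirnas,
                             depth = depth,
                             backgroundRate = backgroundRate,
                             jitterSd = jitterSd, seed = seed + 3L)
    cons <- simulateConservation(planted$genome, planted$truth,
                                 seed = seed + 4L)
    paths <- list(
        genome = file.path(outDir, "genome.fa"),
        gtf = file.path(outDir, "annotation.gtf"),
        conservation = file.path(outDir, "conservation.bedGraph"),
        mirnas = file.path(outDir, "mirnas.fa"),
        chimeras = file.path(outDir, "chimeras.tsv"),
        truth = file.path(outDir, "truth.tsv"))
    Biostrings::writeXStringSet(planted$genome, paths$genome)
    writeGTF(gen$features, paths$gtf)
    writeBedGraph(cons, paths$conservation)
    writeLines(unlist(lapply(mirnas, function(m)
        c(paste0(">", mirnaId(m)), mirnaSequence(m)))), paths$mirnas)
    utils::write.table(chim, paths$chimeras, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(planted$truth, paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(list(genome = planted$genome, mirnas = mirnas,
                   truth = planted$truth, chimeras = chim,
                   conservation = cons, features = gen$features,
                   seqlens = gen$seqlens, paths = paths))
}
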