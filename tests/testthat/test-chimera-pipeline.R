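mkMirnas <- function() list(`let7-fix` = LET7)

writeChimeraTSV <- function(df) {
    path <- tempfile(fileext = ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

chimRow <- function(read_id = "r1", mirna_id = "let7-fix",
                    chrom = "chrT", start = 100L, end = 140L,
                    strand = "+", target_seq = NULL) {
    if (is.null(target_seq)) target_seq <- strrep("ACGU", (end - start) / 4)
    data.frame(read_id = read_id, mirna_id = mirna_id, chrom = chrom,
               start = start, end = end, strand = strand,
               target_seq = target_seq, stringsAsFactors = FALSE)
}

test_that("readChimeras validates rows and reports unknown miRNAs", {
    df <- rbind(chimRow("r1"), chimRow("r2", start = 200, end = 240),
                chimRow("r3", start = 300, end = 340))
    got <- readChimeras(writeChimeraTSV(df), mkMirnas())
    expect_identical(nrow(got), 3L)
    bad <- rbind(chimRow("r1"), chimRow("r2", start = 240, end = 240))
    expect_error(readChimeras(writeChimeraTSV(bad), mkMirnas()), "row 2")
    bad2 <- chimRow("r1", target_seq = "ACGU")
    expect_error(readChimeras(writeChimeraTSV(bad2), mkMirnas()),
                 "length")
    unk <- rbind(chimRow("r1"), chimRow("r2", mirna_id = "miR-unknown",
                                        start = 200, end = 240))
    expect_warning(got2 <- readChimeras(writeChimeraTSV(unk), mkMirnas()),
                   "unknown")
    expect_identical(nrow(got2), 1L)
    expect_identical(attr(got2, "dropped_mirna_ids"), "miR-unknown")
})

test_that("clusterSites merges overlaps and extends the 5' end by 10 nt", {
    rec <- suppressWarnings(
        readChimeras(writeChimeraTSV(chimRow()), mkMirnas()))
    cl <- clusterSites(rec)
    expect_identical(cl$start, 90L)   # plus strand: start - 10
    expect_identical(cl$end, 140L)
    recM <- readChimeras(writeChimeraTSV(chimRow(strand = "-")),
                         mkMirnas())
    clM <- clusterSites(recM)
    expect_identical(clM$start, 100L) # minus strand: end + 10
    expect_identical(clM$end, 150L)
    # two overlapping chimeras merge into one supported cluster
    both <- rbind(chimRow("r1", start = 100, end = 148,
                          target_seq = strrep("ACGU", 12)),
                  chimRow("r2", start = 140, end = 188,
                          target_seq = strrep("ACGU", 12)))
    cl2 <- clusterSites(readChimeras(writeChimeraTSV(both), mkMirnas()))
    expect_identical(nrow(cl2), 1L)
    expect_identical(cl2$start, 90L)
    expect_identical(cl2$end, 188L)
    expect_identical(cl2$read_count, 2L)
    # strand-aware: same interval on opposite strands stays separate
    two <- rbind(chimRow("r1"), chimRow("r2", strand = "-"))
    expect_identical(nrow(clusterSites(readChimeras(writeChimeraTSV(two),
                                                    mkMirnas()))), 2L)
    # min-read threshold and chromosome clipping
    expect_identical(nrow(clusterSites(readChimeras(
        writeChimeraTSV(chimRow()), mkMirnas()), minReads = 2)), 0L)
    clip <- clusterSites(readChimeras(writeChimeraTSV(
        chimRow(strand = "-")), mkMirnas()),
        seqlens = c(chrT = 145L))
    expect_identical(clip$end, 145L)
})

test_that("enrichmentGain computes RPM and flags zero denominators", {
    r <- enrichmentGain(c(m1 = 50, m2 = 50), c(m1 = 50, m2 = 50))
    expect_equal(r$rpm_enriched, c(5e5, 5e5))
    r2 <- enrichmentGain(c(m1 = 9000, m2 = 1000),
                         c(m1 = 300, m2 = 9700))
    expect_equal(r2$ratio[r2$mirna_id == "m1"],
                 (9000 / 10000) / (300 / 10000))
    r3 <- enrichmentGain(c(m1 = 10, m2 = 10), c(m1 = 0, m2 = 20))
    expect_true(is.infinite(r3$ratio[r3$mirna_id == "m1"]))
    expect_true(r3$infinite_ratio[r3$mirna_id == "m1"])
    expect_error(enrichmentGain(c(m1 = 0), c(m1 = 0)), "zero")
})

test_that("chimeraLocationProfile tabulates per-sample proportions", {
    gtf <- writeToyGTF(tempfile(fileext = ".gtf"))
    ann <- loadAnnotation(gtf)
    rc28 <- rnaReverseComplement(substr(mirnaSequence(LET7), 2, 8))
    seedFrag <- paste0(strrep("A", 20), rc28, "A", strrep("A", 12))
    noSeed <- strrep("AC", 20)
    # 6 seed-matched chimeras in tx1 UTR3 (seed lands ~ position 330),
    # 4 in CDS (~ position 230), 2 seedless
    mk <- function(id, start, seq) chimRow(id, start = start,
                                           end = start + 40L,
                                           target_seq = seq)
    df <- rbind(
        do.call(rbind, lapply(1:6, function(i)
            mk(paste0("u", i), 300L, seedFrag))),
        do.call(rbind, lapply(1:4, function(i)
            mk(paste0("c", i), 200L, seedFrag))),
        mk("n1", 100L, noSeed), mk("n2", 600L, noSeed))
    rec <- readChimeras(writeChimeraTSV(df), mkMirnas())
    prof <- chimeraLocationProfile(rec, mkMirnas(), ann,
                                   seedFilter = TRUE)
    expect_equal(sum(prof$proportion), 1)
    expect_equal(prof$proportion[prof$region_class == "UTR3"], 0.6)
    expect_equal(prof$proportion[prof$region_class == "CDS"], 0.4)
    # seedless chimeras enter the denominator only without the filter
    prof2 <- chimeraLocationProfile(rec, mkMirnas(), ann,
                                    seedFilter = FALSE)
    expect_equal(sum(prof2$count), 12)
    expect_equal(sum(prof2$proportion), 1)
    # empty input: empty table, no division by zero
    empty <- rec[0, ]
    expect_identical(nrow(chimeraLocationProfile(empty, mkMirnas(), ann)),
                     0L)
})

test_that("candidate tables round-trip and rank by ascending 3' MFE", {
    sim <- simulateTriggerStudy(tempfile("study"), seed = 7)
    mirnas <- readMiRNAFasta(sim$paths$mirnas)
    ann <- loadAnnotation(sim$paths$gtf)
    cons <- readConservation(sim$paths$conservation)
    chim <- readChimeras(sim$paths$chimeras, mirnas)
    cl <- clusterSites(chim, seqlens = sim$seqlens)
    cand <- nominateTriggers(cl, mirnas, ann, cons,
                             genome = sim$paths$genome)
    # overall_pass is the conjunction of the six verdicts
    v <- cand[, c("pass_seed", "pass_region", "pass_bulge", "pass_run3p",
                  "pass_conservation", "pass_mfe")]
    expect_identical(cand$overall_pass,
                     apply(v, 1, function(x) isTRUE(all(x))))
    # the conjunction is order-invariant: any criterion permutation gives
    # the same passing set
    set.seed(77)
    for (i in 1:5)
        expect_identical(apply(v[, sample(6)], 1,
                               function(x) isTRUE(all(x))),
                         cand$overall_pass)
    # ranks: 1..k per miRNA, ordered by ascending 3' MFE
    ranked <- cand[!is.na(cand$rank), ]
    for (m in unique(ranked$mirna_id)) {
        rm <- ranked[ranked$mirna_id == m, ]
        expect_identical(sort(rm$rank), seq_len(nrow(rm)))
        expect_false(is.unsorted(rm$three_prime_mfe[order(rm$rank)]))
    }
    # round trip
    path <- tempfile(fileext = ".tsv")
    writeCandidates(cand, path)
    back <- readCandidates(path)
    expect_identical(nrow(back), nrow(cand))
    expect_equal(back$three_prime_mfe, cand$three_prime_mfe)
    expect_identical(back$overall_pass, cand$overall_pass)
    expect_identical(back$rank, cand$rank)
    # empty candidate list -> header-only file
    path2 <- tempfile(fileext = ".tsv")
    writeCandidates(cand[0, ], path2)
    expect_identical(nrow(readCandidates(path2)), 0L)
})

test_that("two passing sites for one miRNA rank by MFE", {
    # two trigger sites for the same miRNA with different 3' run lengths
    # (8 vs 6) give distinct MFEs and ranks 1 and 2
    mir <- generateMiRNAs(2, seed = 3)
    specs <- defaultPlantSpecs(names(mir))[c(1, 1), ]
    specs$site_id <- c("sA", "sB")
    specs$mirna_id <- names(mir)[1]
    specs$three_prime_run <- c(8L, 6L)
    gen <- generateGenome(6, 1, 5e4, seed = 3)
    planted <- plantSites(gen, mir, specs, seed = 3)
    chim <- simulateChimeras(planted$genome, planted$truth, mir, seed = 3)
    cons <- simulateConservation(planted$genome, planted$truth, seed = 3)
    gtf <- tempfile(fileext = ".gtf"); writeGTF(gen$features, gtf)
    fa <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(planted$genome, fa)
    cand <- nominateTriggers(clusterSites(chim, seqlens = gen$seqlens),
                             mir, loadAnnotation(gtf), cons, genome = fa)
    ranked <- cand[!is.na(cand$rank), ]
    expect_identical(nrow(ranked), 2L)
    expect_identical(ranked$rank[order(ranked$three_prime_mfe)], 1:2)
    expect_lt(ranked$three_prime_mfe[ranked$rank == 1],
              ranked$three_prime_mfe[ranked$rank == 2])
})
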