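test_that("generateGenome is deterministic and structurally consistent", {
    g1 <- generateGenome(8, 2, 5e4, seed = 9)
    g2 <- generateGenome(8, 2, 5e4, seed = 9)
    expect_identical(as.character(g1$genome), as.character(g2$genome))
    expect_identical(g1$features, g2$features)
    g3 <- generateGenome(8, 2, 5e4, seed = 10)
    expect_false(identical(as.character(g1$genome),
                           as.character(g3$genome)))
    # every feature lies within its chromosome
    expect_true(all(g1$features$start >= 1))
    expect_true(all(g1$features$end <= g1$seqlens[g1$features$chrom]))
    # exon cover equals the union of region classes per transcript
    gtf <- tempfile(fileext = ".gtf"); writeGTF(g1$features, gtf)
    ann <- loadAnnotation(gtf)
    for (i in seq_len(nrow(g1$regions))) {
        r <- g1$regions[i, ]
        mid <- (r$start + r$end) %/% 2
        expect_identical(classifyRegion(ann, r$chrom, mid, r$strand),
                         r$regionClass, )
    }
})

test_that("plantSites realizes the requested architectures exactly", {
    mir <- generateMiRNAs(6, seed = 13)
    gen <- generateGenome(18, 2, 8e4, seed = 13)
    specs <- defaultPlantSpecs(names(mir))
    planted <- plantSites(gen, mir, specs, seed = 13)
    tr <- planted$truth
    expect_identical(nrow(tr), nrow(specs))
    genomePath <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(planted$genome, genomePath)
    fa <- Biostrings::readDNAStringSet(genomePath)
    for (i in seq_len(nrow(tr))) {
        t1 <- tr[i, ]
        s <- Biostrings::subseq(fa[[t1$chrom]], t1$start + 1, t1$end)
        if (t1$strand == "-") s <- Biostrings::reverseComplement(s)
        siteSeq <- chartr("T", "U", as.character(s))
        m <- mir[[t1$mirna_id]]
        hits <- findSeedSites(m, siteSeq)
        if (t1$kind == "decoy_seed_mismatch") {
            expect_identical(nrow(hits), 0L)
            next
        }
        expect_identical(nrow(hits), 1L)
        a <- evaluateArchitecture(m, siteSeq, hits$seedEnd)
        expect_identical(seedClass(a), t1$exp_seed_class)
        if (!is.na(t1$exp_central_run))
            expect_identical(centralMismatchRunLength(a),
                             t1$exp_central_run)
        if (!is.na(t1$exp_run3p))
            expect_identical(threePrimePairRunLength(a), t1$exp_run3p)
        if (t1$kind == "canonical")
            expect_lt(threePrimePairRunLength(a), 6L)
    }
})

test_that("simulateChimeras counts, jitter and determinism behave", {
    mir <- generateMiRNAs(3, seed = 14)
    gen <- generateGenome(8, 1, 6e4, seed = 14)
    specs <- defaultPlantSpecs(names(mir))[c(1, 4, 9), ]
    planted <- plantSites(gen, mir, specs, seed = 14)
    ch <- simulateChimeras(planted$genome, planted$truth, mir,
                           depth = 5, backgroundRate = 0, seed = 14)
    expect_identical(nrow(ch), 15L)  # depth x sites, no background
    # every fragment overlaps its planted site
    for (i in seq_len(nrow(ch))) {
        t1 <- planted$truth[planted$truth$mirna_id == ch$mirna_id[i] &
                            planted$truth$chrom == ch$chrom[i], ]
        expect_true(any(ch$start[i] < t1$end & ch$end[i] > t1$start))
    }
    # zero jitter: the five fragments of the first site are identical
    expect_identical(length(unique(ch$start[1:5])), 1L)
    ch2 <- simulateChimeras(planted$genome, planted$truth, mir,
                            depth = 5, backgroundRate = 0, seed = 14)
    expect_identical(ch, ch2)
    # jitter spreads fragment starts
    ch3 <- simulateChimeras(planted$genome, planted$truth, mir,
                            depth = 20, jitterSd = 3, seed = 15)
    expect_gt(length(unique(ch3$start)), 3L)
})

test_that("simulateConservation scores planted positions and background", {
    mir <- generateMiRNAs(3, seed = 16)
    gen <- generateGenome(8, 1, 6e4, seed = 16)
    specs <- defaultPlantSpecs(names(mir))[c(1, 13), ]  # trigger + noncons
    planted <- plantSites(gen, mir, specs, seed = 16)
    cons <- simulateConservation(planted$genome, planted$truth,
                                 conservedLevel = 2,
                                 backgroundLevel = -0.5, seed = 16)
    tr <- planted$truth[planted$truth$kind == "trigger", ]
    seedPos <- as.integer(strsplit(tr$seed_positions, ",")[[1]])
    r <- conservationStats(cons, tr$chrom, seedPos,
        as.integer(strsplit(tr$run3p_positions, ",")[[1]]))
    expect_equal(r$seedMean, 2); expect_true(r$pass)
    nc <- planted$truth[planted$truth$kind == "decoy_nonconserved", ]
    r2 <- conservationStats(cons, nc$chrom,
        as.integer(strsplit(nc$seed_positions, ",")[[1]]),
        as.integer(strsplit(nc$run3p_positions, ",")[[1]]))
    expect_equal(r2$seedMean, -0.5); expect_false(r2$pass)
    # track covers every base exactly once
    cov <- GenomicRanges::coverage(cons)
    expect_true(all(vapply(cov, function(x) all(S4Vectors::runValue(x)
                                                %in% c(0, 1)), logical(1))))
})

test_that("generator outputs validate through their own readers", {
    sim <- simulateTriggerStudy(tempfile("study"), seed = 21)
    mirnas <- readMiRNAFasta(sim$paths$mirnas)
    expect_identical(sort(names(mirnas)),
                     sort(unname(vapply(sim$mirnas, mirnaId,
                                        character(1)))))
    chim <- readChimeras(sim$paths$chimeras, mirnas)
    expect_identical(nrow(chim), nrow(sim$chimeras))
    fa <- Biostrings::readDNAStringSet(sim$paths$genome)
    expect_identical(names(fa), names(sim$genome))
    ann <- loadAnnotation(sim$paths$gtf)
    expect_s4_class(ann, "AnnotationIndex")
    cons <- readConservation(sim$paths$conservation)
    expect_identical(length(cons), length(sim$conservation))
})

test_that("noise-free recovery is perfect and decoys fail cleanly", {
    sim <- simulateTriggerStudy(tempfile("study"), seed = 31)
    mirnas <- readMiRNAFasta(sim$paths$mirnas)
    ann <- loadAnnotation(sim$paths$gtf)
    cons <- readConservation(sim$paths$conservation)
    chim <- readChimeras(sim$paths$chimeras, mirnas)
    cl <- clusterSites(chim, seqlens = sim$seqlens)
    cand <- nominateTriggers(cl, mirnas, ann, cons,
                             genome = sim$paths$genome)
    rec <- evaluateRecovery(cand, sim$truth)
    expect_equal(rec$precision, 1)
    expect_equal(rec$recall, 1)
    expect_true(all(rec$confusion$cleanViolation))
    # background chimeras may add evaluated sites but never flip a decoy
    chimN <- simulateChimeras(sim$genome, sim$truth, mirnas, depth = 5,
                              backgroundRate = 2, seed = 31)
    clN <- clusterSites(chimN, seqlens = sim$seqlens)
    candN <- nominateTriggers(clN, mirnas, ann, cons,
                              genome = sim$paths$genome)
    recN <- evaluateRecovery(candN, sim$truth)
    expect_equal(recN$recall, 1)
    expect_true(all(recN$confusion$cleanViolation))
})
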