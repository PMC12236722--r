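test_that("loadAnnotation derives UTRs from exon/CDS arithmetic", {
    gtf <- writeToyGTF(tempfile(fileext = ".gtf"))
    ann <- loadAnnotation(gtf)
    # probe points on tx1 (+): UTR5 101-200, CDS 201-300 & 501-550,
    # UTR3 301-400 & 551-600, intron 401-500
    expect_identical(classifyRegion(ann, "chrT", 150, "+"), "UTR5")
    expect_identical(classifyRegion(ann, "chrT", 250, "+"), "CDS")
    expect_identical(classifyRegion(ann, "chrT", 350, "+"), "UTR3")
    expect_identical(classifyRegion(ann, "chrT", 520, "+"), "CDS")
    expect_identical(classifyRegion(ann, "chrT", 580, "+"), "UTR3")
    expect_identical(classifyRegion(ann, "chrT", 450, "+"), "intron")
    # minus-strand tx2: genomic-left exonic chunk is the 3' UTR
    expect_identical(classifyRegion(ann, "chrT", 1100, "-"), "UTR3")
    expect_identical(classifyRegion(ann, "chrT", 1300, "-"), "CDS")
    expect_identical(classifyRegion(ann, "chrT", 1500, "-"), "UTR5")
    # ncRNA exon; strandedness; intergenic fallback
    expect_identical(classifyRegion(ann, "chrT", 2100, "+"), "ncRNA_exon")
    expect_identical(classifyRegion(ann, "chrT", 2100, "-"), "intergenic")
    expect_identical(classifyRegion(ann, "chrT", 5000, "+"), "intergenic")
    expect_warning(cls <- classifyRegion(ann, "chrZ", 10, "+"), "absent")
    expect_identical(cls, "intergenic")
    # explicit UTR rows must not change the classification
    gtf2 <- writeToyGTF(tempfile(fileext = ".gtf"), withUTRlines = TRUE)
    ann2 <- loadAnnotation(gtf2)
    for (p in c(150, 250, 350, 450, 520, 580))
        expect_identical(classifyRegion(ann2, "chrT", p, "+"),
                         classifyRegion(ann, "chrT", p, "+"))
})

test_that("classification is invariant to GTF record order", {
    gtf <- writeToyGTF(tempfile(fileext = ".gtf"))
    lines <- readLines(gtf)
    set.seed(31)
    shuf <- tempfile(fileext = ".gtf")
    writeLines(sample(lines), shuf)
    ann1 <- loadAnnotation(gtf); ann2 <- loadAnnotation(shuf)
    for (p in c(150, 250, 350, 450, 520, 580, 1100, 1300, 1500, 2100))
        expect_identical(classifyRegion(ann1, "chrT", p, "+"),
                         classifyRegion(ann2, "chrT", p, "+"))
})

test_that("isoform precedence favors noncoding classes", {
    # same locus annotated as CDS in one transcript and 3' UTR (via
    # exon-minus-CDS) in another: the UTR3 call wins
    gtf <- tempfile(fileext = ".gtf")
    writeLines(c(
        gtfLine("chrT", "exon", 100, 500, "+", "g1", "tA"),
        gtfLine("chrT", "CDS", 100, 400, "+", "g1", "tA"),
        gtfLine("chrT", "exon", 100, 500, "+", "g1", "tB"),
        gtfLine("chrT", "CDS", 100, 250, "+", "g1", "tB")), gtf)
    ann <- loadAnnotation(gtf)
    expect_identical(classifyRegion(ann, "chrT", 300, "+"), "UTR3")
    expect_identical(classifyRegion(ann, "chrT", 200, "+"), "CDS")
})

test_that("empty annotation classifies everything intergenic", {
    gtf <- tempfile(fileext = ".gtf")
    writeLines(character(0), gtf)
    ann <- loadAnnotation(gtf)
    expect_identical(classifyRegion(ann, "chrT", 100, "+"), "intergenic")
})

test_that("conservationStats applies the strict-positivity rule", {
    track <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(1:100, 1:100), score = rep(1, 100))
    r <- conservationStats(track, "chrT", 10:16, 40:45)
    expect_equal(r$seedMean, 1); expect_equal(r$threePrimeMean, 1)
    expect_true(r$pass)
    # negative seed mean fails even with strongly conserved 3' pairing
    track2 <- track
    track2$score[10:16] <- -0.1
    track2$score[40:45] <- 2
    expect_false(conservationStats(track2, "chrT", 10:16, 40:45)$pass)
    # boundary: mean exactly zero is not "positive"
    track3 <- track
    track3$score[10:16] <- c(-3, 1, 1, 1, 0, 0, 0)
    expect_equal(conservationStats(track3, "chrT", 10:16, 40:45)$seedMean, 0)
    expect_false(conservationStats(track3, "chrT", 10:16, 40:45)$pass)
    # missing positions are excluded; all-missing fails with the flag
    rNA <- conservationStats(track, "chrT", c(10, 200, 300), 40:45)
    expect_equal(rNA$seedMean, 1)
    rAllNA <- conservationStats(track, "chrT", 200:205, 40:45)
    expect_false(rAllNA$pass); expect_true(rAllNA$allMissing)
    expect_error(conservationStats(track, "chrT", integer(0), 40:45),
                 "non-empty")
    # per-base rule: one non-positive base fails
    expect_false(conservationStats(track3, "chrT", 10:16, 40:45,
                                   rule = "all")$pass)
    # means equal an independent recomputation on random tracks
    set.seed(32)
    for (i in 1:20) {
        sc <- rnorm(100)
        tr <- GenomicRanges::GRanges("chrT",
            IRanges::IRanges(1:100, 1:100), score = sc)
        sp <- sample(1:100, 7); tp <- sample(1:100, 5)
        r2 <- conservationStats(tr, "chrT", sp, tp)
        expect_equal(r2$seedMean, mean(sc[sp]))
        expect_equal(r2$threePrimeMean, mean(sc[tp]))
        expect_identical(r2$pass, mean(sc[sp]) > 0 && mean(sc[tp]) > 0)
    }
})

test_that("bedGraph round trip preserves per-base queries", {
    gr <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(c(1, 11, 21), c(10, 20, 30)),
        score = c(-0.5, 2, 0.25))
    path <- tempfile(fileext = ".bedGraph")
    writeBedGraph(gr, path)
    back <- readConservation(path)
    r <- conservationStats(back, "chrT", 12:18, 22:28)
    expect_equal(r$seedMean, 2)
    expect_equal(r$threePrimeMean, 0.25)
    expect_true(r$pass)
})
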