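# Shared fixtures and independent oracles used across the suite.

# fixed 22-nt miRNA (let-7 family mature sequence, a convenient fixture
# with an asymmetric seed)
LET7 <- MiRNA("let7-fix", "UGAGGUAGUAGGUUGUAUAGUU")

.ocomp <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

# literal-definition seed classifier: site window w (8 characters,
# 5'->3'), whose position 7 pairs miRNA position 2 and position 8 is the
# A1 slot. Applies the four definitions verbatim, WC only.
oracleClassify <- function(mirSeq, w) {
    m <- strsplit(mirSeq, "")[[1]]
    s <- strsplit(w, "")[[1]]
    core <- all(s[7:2] == .ocomp[m[2:7]]) && !any(s[7:2] == "N")
    if (!core) return("none")
    m8 <- s[1] == .ocomp[m[8]] && s[1] != "N"
    a1 <- s[8] == "A"
    if (m8 && a1) "8mer" else if (m8) "7mer-m8"
    else if (a1) "7mer-A1" else "6mer"
}

# vectorized version over a matrix of window letters (rows = windows)
oracleClassifyAll <- function(mirSeq, mat) {
    m <- strsplit(mirSeq, "")[[1]]
    core <- rep(TRUE, nrow(mat))
    for (k in 0:5)  # window col 7-k pairs miRNA position 2+k
        core <- core & mat[, 7 - k] == .ocomp[[m[2 + k]]]
    m8 <- mat[, 1] == .ocomp[[m[8]]]
    a1 <- mat[, 8] == "A"
    out <- rep("none", nrow(mat))
    out[core] <- "6mer"
    out[core & a1] <- "7mer-A1"
    out[core & m8] <- "7mer-m8"
    out[core & m8 & a1] <- "8mer"
    out
}

# linear-scan run oracles over an explicit paired/unpaired vector
oracleLongestRun <- function(flags) {
    best <- 0L; cur <- 0L
    for (f in flags) {
        cur <- if (isTRUE(f)) cur + 1L else 0L
        best <- max(best, cur)
    }
    best
}

# a valid DuplexStructure pairing arbitrary miRNA positions: strand B is
# the reverse complement of the miRNA, so position i pairs n + 1 - i
mapWithPairs <- function(mirna, mirPositions) {
    seqA <- mirnaSequence(mirna)
    n <- nchar(seqA)
    seqB <- rnaReverseComplement(seqA)
    mirPositions <- sort(unique(as.integer(mirPositions)))
    new("DuplexStructure", seqA = seqA, seqB = seqB,
        pairs = cbind(a = mirPositions, b = n + 1L - mirPositions),
        energy = if (length(mirPositions)) -1 else 0)
}

# exact one-sided rank-sum p-value by full enumeration of group
# assignments (alternative: x shifted toward smaller values)
oracleRankSumP <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    r <- rank(pooled)
    wObs <- sum(r[seq_len(n)])
    combs <- utils::combn(length(pooled), n)
    ws <- apply(combs, 2, function(idx) sum(r[idx]))
    mean(ws <= wObs)
}

randomRNA <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")

# tiny annotation: one + strand mRNA with explicit structure, one - strand
# mRNA, one ncRNA; written as a GTF with exon/CDS rows only
writeToyGTF <- function(path, withUTRlines = FALSE) {
    lines <- c(
        # mRNA tx1 on +: exon 101-400, CDS 201-300 -> UTR5 101-200,
        # UTR3 301-400; intron 401-500 implied by second exon 501-600
        gtfLine("chrT", "exon", 101, 400, "+", "g1", "t1"),
        gtfLine("chrT", "exon", 501, 600, "+", "g1", "t1"),
        gtfLine("chrT", "CDS", 201, 300, "+", "g1", "t1"),
        gtfLine("chrT", "CDS", 501, 550, "+", "g1", "t1"),
        # mRNA tx2 on -: exon 1001-1600, CDS 1201-1400 ->
        # UTR3 1001-1200 (3' end on minus), UTR5 1401-1600
        gtfLine("chrT", "exon", 1001, 1600, "-", "g2", "t2"),
        gtfLine("chrT", "CDS", 1201, 1400, "-", "g2", "t2"),
        # ncRNA on +
        gtfLine("chrT", "exon", 2001, 2400, "+", "g3", "t3"))
    if (withUTRlines)
        lines <- c(lines,
                   gtfLine("chrT", "five_prime_utr", 101, 200, "+",
                           "g1", "t1"),
                   gtfLine("chrT", "three_prime_utr", 301, 400, "+",
                           "g1", "t1"))
    writeLines(lines, path)
    path
}

gtfLine <- function(chrom, type, s, e, strand, gid, tid) {
    sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            chrom, type, s, e, strand, gid, tid)
}
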