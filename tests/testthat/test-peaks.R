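test_that("per-base coverage counts overlapping alignments exactly", {
    lens <- c(chr1 = 10000)
    si <- makeSeqinfo(lens)
    # one read [100, 150) over region [100, 200)
    bam <- makeTestBam("chr1", 100, 60, lens)
    region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
    cov <- perBaseCoverage(bam, region)
    expect_identical(cov, c(rep(1L, 50), rep(0L, 50)))

    # no reads -> all zero
    empty <- makeTestBam(character(0), numeric(0), integer(0), lens)
    expect_identical(perBaseCoverage(empty, region), rep(0L, 100))

    # two overlapping reads [100,150) and [120,170): coverage 2 on [120,150)
    bam2 <- makeTestBam("chr1", c(100, 120), 60, lens)
    cov2 <- perBaseCoverage(bam2, GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(101, 200)))
    expect_identical(cov2, as.integer(bruteCoverage(c(100, 120), 50L,
                                                    100L, 200L)))
    expect_identical(which(cov2 == 2L), 21:50)

    expect_error(perBaseCoverage(bam, GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(9990, 10050))), "outside")
})

test_that("coverage matches brute-force counting on a random fixture", {
    set.seed(701)
    lens <- c(chr1 = 5000)
    starts <- sort(sample(0:4900, 80, replace = TRUE))
    bam <- makeTestBam("chr1", starts, 60, lens)
    region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 3000))
    cov <- perBaseCoverage(bam, region)
    expect_identical(cov, as.integer(bruteCoverage(starts, 50L, 1000L, 3000L)))
})

test_that("coverage respects the same MAPQ filter as binning", {
    lens <- c(chr1 = 1000)
    bam <- makeTestBam("chr1", c(100, 100, 100), c(29, 30, 31), lens)
    cov <- perBaseCoverage(bam, GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(101, 150)))
    expect_identical(unique(cov), 2L)
})

test_that("peak centers sit at the coverage maximum, plateau midpoint on ties", {
    pc <- findPeakCenter(c(1, 3, 2), regionStart = 1000)
    expect_identical(pc$center, 1001L)
    expect_identical(pc$maxCoverage, 3L)

    plateau <- findPeakCenter(c(0, 5, 5, 5, 0), regionStart = 2000)
    expect_identical(plateau$center, 2002L)

    # leftmost plateau wins when separate plateaus tie
    lm <- findPeakCenter(c(5, 5, 0, 5, 5), regionStart = 0)
    expect_identical(lm$center, 0L)

    expect_warning(zero <- findPeakCenter(rep(0, 10), regionStart = 100),
                   "midpoint")
    expect_identical(zero$center, 104L)
    expect_identical(zero$maxCoverage, 0L)
})

test_that("centers extend to fixed-width intervals clamped at bounds", {
    si <- makeSeqinfo(c(chr1 = 100000))
    gr <- extendCenter(5000, "chr1", si, flank = 100)
    expect_identical(GenomicRanges::start(gr), 4901L)  # 0-based 4900
    expect_identical(GenomicRanges::end(gr), 5100L)
    expect_identical(GenomicRanges::width(gr), 200L)

    near <- extendCenter(50, "chr1", si, flank = 100)
    expect_identical(GenomicRanges::start(near), 1L)
    expect_identical(GenomicRanges::end(near), 150L)

    wide <- extendCenter(5000, "chr1", si, flank = 250)
    expect_identical(GenomicRanges::width(wide), 500L)
    expect_error(extendCenter(5000, "chr1", si, flank = 0), "positive")
})

test_that("each enriched region refines to one peak at its summit", {
    set.seed(703)
    lens <- c(chr1 = 50000)
    si <- makeSeqinfo(lens)
    summits <- c(12000, 30500)
    # symmetric pileups: read starts centered so coverage peaks at summit
    starts <- unlist(lapply(summits, function(s)
        round(rnorm(200, s - 25, 10))))
    bam <- makeTestBam("chr1", starts, 60, lens)
    domains <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(10001, 29001), c(14000, 32000)))
    peaks <- peakCenters(domains, bam, si)
    expect_length(peaks, length(domains))  # one peak per region
    expect_identical(GenomicRanges::width(peaks), rep(200L, 2))
    expect_lt(max(abs(S4Vectors::mcols(peaks)$center - summits)), 10)

    # flank override controls width
    wide <- peakCenters(domains, bam, si, flank = 250)
    expect_identical(GenomicRanges::width(wide), rep(500L, 2))

    # chromosome-name mismatch is reported with the offender
    bad <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 100))
    expect_error(peakCenters(bad, bam, si), "chrZ")
})

test_that("summit recovery holds across seeds at modest read counts", {
    lens <- c(chr1 = 20000)
    si <- makeSeqinfo(lens)
    for (seed in 1:5) {
        set.seed(seed)
        summit <- 10000
        starts <- round(rnorm(50, summit - 25, 10))
        bam <- makeTestBam("chr1", starts, 60, lens)
        dom <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9001, 11000))
        pk <- peakCenters(dom, bam, si)
        expect_lt(abs(S4Vectors::mcols(pk)$center - summit), 10)
    }
})

test_that("peaks persist as BED4 with center and coverage in the name", {
    si <- makeSeqinfo(c(chr1 = 10000))
    bam <- makeTestBam("chr1", c(4000, 4010, 4020), 60, c(chr1 = 10000))
    dom <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3001, 5000))
    pk <- peakCenters(dom, bam, si)
    f <- tempfile(fileext = ".bed")
    writePeaksBed(pk, f)
    tab <- read.table(f, sep = "\t")
    expect_identical(nrow(tab), 1L)
    expect_identical(tab$V3 - tab$V2, 200L)
    expect_match(tab$V4, "^peak00001_c")
})
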