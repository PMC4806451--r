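test_that("chrom.sizes files parse in order and reject malformed input", {
    f <- tempfile()
    writeLines(c("chr1\t1000000", "chr2 500000", "", "chrM\t16569\textra"), f)
    si <- readChromSizes(f)
    expect_identical(GenomeInfoDb::seqnames(si), c("chr1", "chr2", "chrM"))
    expect_identical(unname(GenomeInfoDb::seqlengths(si)),
                     c(1000000L, 500000L, 16569L))

    writeLines(character(0), f)
    expect_error(readChromSizes(f), "empty")

    writeLines("chr1 abc", f)
    expect_error(readChromSizes(f), "line 1")

    writeLines(c("chr1\t100", "chr1\t200"), f)
    expect_error(readChromSizes(f), "duplicate")

    writeLines("chr1", f)
    expect_error(readChromSizes(f), "at least 2 fields")

    writeLines(c("chr1\t0"), f)
    expect_error(readChromSizes(f), "positive")
})

test_that("reads map to bins by 0-based start with half-open boundaries", {
    expect_identical(assignReadToBin(0, 1000), 0L)
    expect_identical(assignReadToBin(1500, 1000), 1L)
    expect_identical(assignReadToBin(c(999, 1000), 1000), c(0L, 1L))
    expect_error(assignReadToBin(-1, 1000), ">= 0")
    expect_error(assignReadToBin(10, 0), "positive")
})

test_that("the MAPQ filter keeps exactly the reads at or above threshold", {
    bam <- makeTestBam("chr1", starts0 = c(100, 100, 100),
                       mapq = c(29, 30, 31), chromLengths = c(chr1 = 10000))
    br <- countBamBins(bam, makeSeqinfo(c(chr1 = 10000)), binWidth = 1000,
                       minMapq = 30)
    expect_identical(sum(counts(br[["chr1"]])), 2L)
    expect_identical(totalReads(br), 2)
})

test_that("an empty BAM yields all-zero counts for every chromosome", {
    lens <- c(chr1 = 3000, chr2 = 1500)
    bam <- makeTestBam(character(0), numeric(0), integer(0), lens)
    br <- countBamBins(bam, makeSeqinfo(lens), binWidth = 1000)
    expect_identical(counts(br[["chr1"]]), c(0L, 0L, 0L))
    expect_identical(counts(br[["chr2"]]), c(0L, 0L))
    expect_identical(totalReads(br), 0)
})

test_that("uniformly spaced reads land in the expected bins", {
    # 10 reads at 0, 100, ..., 900 with 500 bp bins -> 5 reads per bin
    bam <- makeTestBam("chr1", starts0 = seq(0, 900, by = 100), mapq = 60,
                       chromLengths = c(chr1 = 1000), readLength = 50L)
    br <- countBamBins(bam, makeSeqinfo(c(chr1 = 1000)), binWidth = 500)
    expect_identical(counts(br[["chr1"]]), c(5L, 5L))
})

test_that("counting conserves reads and refines consistently across widths", {
    set.seed(401)
    lens <- c(chrA = 20000, chrB = 8000)
    n <- 500
    chrom <- sample(names(lens), n, replace = TRUE)
    starts <- floor(runif(n) * (lens[chrom] - 50))
    bam <- makeTestBam(chrom, starts, mapq = 60, chromLengths = lens)
    si <- makeSeqinfo(lens)

    coarse <- countBamBins(bam, si, binWidth = 1000)
    fine <- countBamBins(bam, si, binWidth = 500)
    # conservation: every filtered read increments exactly one bin
    expect_identical(sum(sapply(chromBins(coarse), function(b)
        sum(counts(b)))), as.integer(n))
    # determinism: bit-identical on re-run
    again <- countBamBins(bam, si, binWidth = 1000)
    expect_identical(lapply(chromBins(coarse), counts),
                     lapply(chromBins(again), counts))
    # halving the width: coarse bin = sum of its two refining bins
    for (chr in names(lens)) {
        f <- counts(fine[[chr]])
        expect_identical(counts(coarse[[chr]]),
                         as.integer(f[c(TRUE, FALSE)] + f[c(FALSE, TRUE)]))
    }
})

test_that("unknown chromosomes and out-of-range reads are skipped with warnings", {
    lens <- c(chr1 = 10000, chrX = 5000)
    bam <- makeTestBam(c("chr1", "chrX", "chrX"), c(100, 200, 300),
                       mapq = 60, chromLengths = lens)
    # chrX present in the BAM but absent from chrom.sizes
    expect_warning(
        br <- countBamBins(bam, makeSeqinfo(c(chr1 = 10000))),
        "chrX")
    expect_identical(totalReads(br), 1)

    # declared length shorter than where a read starts
    expect_warning(
        br2 <- countBamBins(bam, makeSeqinfo(c(chr1 = 50, chrX = 5000))),
        "beyond")
    expect_identical(totalReads(br2), 2)
})

test_that("unindexed BAM input is rejected", {
    bam <- makeTestBam("chr1", 100, 60, c(chr1 = 1000))
    noidx <- file.path(tempdir(), "noindex.bam")
    file.copy(bam, noidx, overwrite = TRUE)
    expect_error(countBamBins(noidx, makeSeqinfo(c(chr1 = 1000))), "index")
    unlink(noidx)
})

test_that("secondary and unmapped alignments are never counted", {
    # flags: 0 primary, 256 secondary, 4 unmapped
    bam <- makeTestBam("chr1", c(100, 100, 100), mapq = 60,
                       chromLengths = c(chr1 = 1000),
                       flag = c(0L, 256L, 4L))
    br <- countBamBins(bam, makeSeqinfo(c(chr1 = 1000)))
    expect_identical(totalReads(br), 1)
})

test_that("binned counts persist as three-column text", {
    bam <- makeTestBam("chr1", c(100, 1500), mapq = 60,
                       chromLengths = c(chr1 = 2500))
    br <- countBamBins(bam, makeSeqinfo(c(chr1 = 2500)))
    f <- tempfile()
    writeBinnedCounts(br, f)
    tab <- read.table(f, sep = "\t")
    expect_identical(tab$V2, c(0L, 1000L, 2000L))
    expect_identical(tab$V3, c(1L, 1L, 0L))
})
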