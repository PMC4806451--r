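# Build small BAM fixtures in code: write a SAM by hand (independent of
# the package's own read simulator) and convert/sort/index with Rsamtools.
makeTestBam <- function(chrom, starts0, mapq, chromLengths,
                        readLength = 50L, flag = NULL) {
    n <- length(starts0)
    if (is.null(flag))
        flag <- rep(0L, n)
    if (length(chrom) == 1L)
        chrom <- rep(chrom, n)
    if (length(mapq) == 1L)
        mapq <- rep(mapq, n)
    o <- order(match(chrom, names(chromLengths)), starts0)
    sam <- tempfile(fileext = ".sam")
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths),
                     as.integer(chromLengths)))
    body <- if (n) {
        sprintf("t%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                seq_len(n), flag[o], chrom[o], as.integer(starts0[o]) + 1L,
                as.integer(mapq[o]), readLength, strrep("A", readLength))
    } else character(0)
    writeLines(c(hdr, body), sam)
    bam <- Rsamtools::asBam(sam, destination = tempfile(),
                            overwrite = TRUE, indexDestination = FALSE)
    srt <- Rsamtools::sortBam(bam, destination = tempfile())
    Rsamtools::indexBam(srt)
    unlink(c(sam, bam))
    srt
}

makeSeqinfo <- function(chromLengths) {
    GenomeInfoDb::Seqinfo(seqnames = names(chromLengths),
                          seqlengths = chromLengths)
}

# Brute-force per-base overlap counting over half-open reads [s, s+len).
bruteCoverage <- function(starts0, readLength, regionStart0, regionEnd0) {
    ends0 <- starts0 + readLength
    vapply(regionStart0:(regionEnd0 - 1L), function(x) {
        sum(starts0 <= x & x < ends0)
    }, numeric(1))
}
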