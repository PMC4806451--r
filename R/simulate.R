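## Known-truth synthetic inputs at two levels: observation series drawn
## from a specified two-state Gaussian HMM, and read-level BAM fixtures
## with planted enriched domains and narrow-peak summits.

#' Simulate an observation series from a known HMM
#'
#' Samples a state path from the prior/transition structure of `params`
#' and observation values from the corresponding Gaussian emissions.
#' Deterministic given `seed`.
#'
#' @param params Generating [HMMParams-class].  The defaults used
#'   throughout the test-suite (`HMMParams(means = c(0, 15), sds = c(5, 5),
#'   transitions = matrix(c(.95,.05,.05,.95), 2))`) mimic control-subtracted
#'   data at typical depth: a null distribution centered on 0 with
#'   standard deviation about 5, shifted upward in enriched bins.
#' @param nBins Number of bins to simulate.
#' @param seed Integer seed.
#' @param chromosome Chromosome label for the series (default "sim").
#' @return A list: `series` (an [ObservationSeries-class]) and `states`
#'   (the true state path, integer 1 = depleted, 2 = enriched).
#' @examples
#' p <- HMMParams(means = c(0, 15), sds = c(5, 5))
#' sim <- simulateObservations(p, nBins = 100, seed = 7)
#' table(sim$states)
#' @export
simulateObservations <- function(params, nBins, seed, chromosome = "sim") {
    stopifnot(is(params, "HMMParams"), nBins >= 1)
    withr::with_seed(as.integer(seed), {
        states <- integer(nBins)
        states[1L] <- sample.int(2L, 1L, prob = params@prior)
        if (nBins > 1L) {
            for (b in 2:nBins) {
                states[b] <- sample.int(
                    2L, 1L, prob = params@transitions[states[b - 1L], ])
            }
        }
        values <- rnorm(nBins, params@means[states], params@sds[states])
        list(series = ObservationSeries(chromosome, values,
                                        binWidth = 1000),
             states = states)
    })
}

#' Draw a synthetic genome with planted enrichment
#'
#' Generates a truth set on a small synthetic genome: non-overlapping
#' enriched domains (placed on the bin grid so base-level truth accounting
#' is unambiguous) each containing one narrow-peak summit.  The defaults -
#' two 2-Mb chromosomes, five domains of 10-50 kb, 8-fold enrichment -
#' give a compact analogue of an independently validated site list.
#'
#' @param chromLengths Named vector of chromosome lengths (default two
#'   2-Mb chromosomes).
#' @param nDomains Number of planted domains (default 5).
#' @param domainWidths Candidate domain widths in bp; sampled per domain
#'   (default 10-50 kb on a 1 kb grid).
#' @param enrichment Fold enrichment of treatment read density inside
#'   domains (default 8).
#' @param binWidth Grid the domains are aligned to (default 1000).
#' @param seed Integer seed.
#' @return A [TruthSet-class].
#' @export
simulateTruthSet <- function(chromLengths = c(chrS1 = 2e6, chrS2 = 2e6),
                             nDomains = 5, domainWidths = (10:50) * 1000,
                             enrichment = 8, binWidth = 1000, seed = 1) {
    si <- GenomeInfoDb::Seqinfo(seqnames = names(chromLengths),
                                seqlengths = chromLengths)
    withr::with_seed(as.integer(seed), {
        widths <- sample(domainWidths, nDomains, replace = TRUE)
        chrs <- sample(names(chromLengths), nDomains, replace = TRUE)
        ## place on the bin grid, rejecting overlaps (with 10 kb clearance)
        placed <- GenomicRanges::GRanges(seqinfo = si)
        for (i in seq_len(nDomains)) {
            repeat {
                maxStartBin <- (chromLengths[[chrs[i]]] - widths[i]) %/%
                    binWidth
                s0 <- sample.int(maxStartBin - 20L, 1L) + 10L  # keep off ends
                cand <- GenomicRanges::GRanges(
                    chrs[i], IRanges::IRanges(start = s0 * binWidth + 1L,
                                              width = widths[i]))
                pad <- GenomicRanges::resize(cand, widths[i] + 2e4,
                                             fix = "center")
                if (!length(GenomicRanges::findOverlaps(pad, placed)))
                    break
            }
            placed <- c(placed, cand)
        }
        ## one summit per domain, away from the domain edges
        offs <- vapply(GenomicRanges::width(placed), function(w) {
            sample.int(w - 2000L, 1L) + 1000L
        }, integer(1))
        summits <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(placed),
            IRanges::IRanges(start = GenomicRanges::start(placed) + offs,
                             width = 1L))
        GenomeInfoDb::seqinfo(placed) <- si
        GenomeInfoDb::seqinfo(summits) <- si
        new("TruthSet", seqinfo = si, domains = placed, summits = summits,
            params = list(enrichment = enrichment, binWidth = binWidth),
            seed = as.integer(seed))
    })
}

## Write one chromosome-sorted single-end read set as SAM, convert to a
## sorted, indexed BAM with Rsamtools.  starts0 must be 0-based.
.writeReadsBam <- function(chrom, starts0, mapq, si, dest, readLength) {
    o <- order(match(chrom, GenomeInfoDb::seqnames(si)), starts0)
    chrom <- chrom[o]
    starts0 <- starts0[o]
    mapq <- mapq[o]
    sam <- tempfile(fileext = ".sam")
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", GenomeInfoDb::seqnames(si),
                     GenomeInfoDb::seqlengths(si)))
    seqStr <- strrep("A", readLength)
    body <- sprintf("r%07d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                    seq_along(starts0), chrom, starts0 + 1L, mapq,
                    readLength, seqStr)
    writeLines(c(hdr, body), sam)
    bam <- Rsamtools::asBam(sam, destination = tempfile(),
                            overwrite = TRUE, indexDestination = FALSE)
    sorted <- Rsamtools::sortBam(bam, destination = dest)
    Rsamtools::indexBam(sorted)
    unlink(c(sam, bam))
    sorted
}

## Sample 0-based read starts at piecewise-constant rate: uniform
## background everywhere plus (enrichment - 1) extra weight inside domains.
.sampleStarts <- function(n, si, domains, enrichment, readLength) {
    chrs <- GenomeInfoDb::seqnames(si)
    lens <- GenomeInfoDb::seqlengths(si)
    segChrom <- character(0)
    segStart <- numeric(0)
    segWidth <- numeric(0)
    segWeight <- numeric(0)
    for (chr in chrs) {
        dom <- domains[as.character(GenomicRanges::seqnames(domains)) == chr]
        bounds <- sort(unique(c(0, lens[[chr]],
                                GenomicRanges::start(dom) - 1L,
                                GenomicRanges::end(dom))))
        for (k in seq_len(length(bounds) - 1L)) {
            a <- bounds[k]
            b <- bounds[k + 1L]
            mid <- (a + b) / 2
            inDom <- length(dom) && any(
                GenomicRanges::start(dom) - 1L <= mid &
                GenomicRanges::end(dom) > mid)
            segChrom <- c(segChrom, chr)
            segStart <- c(segStart, a)
            segWidth <- c(segWidth, b - a)
            segWeight <- c(segWeight,
                           (b - a) * if (inDom) enrichment else 1)
        }
    }
    segIdx <- sample.int(length(segWeight), n, replace = TRUE,
                         prob = segWeight)
    starts <- floor(segStart[segIdx] + runif(n) * segWidth[segIdx])
    chrom <- segChrom[segIdx]
    ## keep reads inside the chromosome
    starts <- pmin(starts, lens[chrom] - readLength)
    list(chrom = chrom, starts0 = as.numeric(starts))
}

#' Simulate treatment and control read sets with planted enrichment
#'
#' Control reads are uniform over each chromosome; treatment reads are
#' uniform background with `enrichment`-fold density inside the planted
#' domains, plus a sharp unimodal pileup of `summitReads` reads around
#' each planted summit (read starts drawn from a narrow Gaussian so
#' per-base coverage peaks at the summit).  Reads are 50 bp single-end;
#' a `lowMapqFrac` fraction receives MAPQ 10 (below the default filter of
#' 30, exercising it), the rest MAPQ 60.  Both read sets are written as
#' coordinate-sorted, indexed BAM files.  Deterministic given `seed`.
#'
#' @param truth A [TruthSet-class] from [simulateTruthSet()].
#' @param treatmentReads,controlReads Reads per dataset (defaults 1e5
#'   each, i.e. about 200k reads total).
#' @param summitReads Extra treatment reads piled on each summit
#'   (default 400, drawn from the treatment budget).
#' @param readLength Read length in bp (default 50).
#' @param lowMapqFrac Fraction of reads given MAPQ 10 (default 0.1).
#' @param seed Integer seed.
#' @param dir Output directory (default `tempdir()`).
#' @return Named list with elements `treatment` and `control` (BAM paths,
#'   indexed) and `chromSizes` (the truth's Seqinfo).
#' @export
simulateReads <- function(truth, treatmentReads = 1e5, controlReads = 1e5,
                          summitReads = 400, readLength = 50,
                          lowMapqFrac = 0.1, seed = 1, dir = tempdir()) {
    stopifnot(is(truth, "TruthSet"))
    si <- truthSeqinfo(truth)
    enr <- truth@params$enrichment
    withr::with_seed(as.integer(seed), {
        ## control: uniform background
        ctl <- .sampleStarts(controlReads, si, GenomicRanges::GRanges(),
                             1, readLength)
        ## treatment: background + domains + summit pileups
        nSummit <- summitReads * length(trueSummits(truth))
        nBody <- max(0L, as.integer(treatmentReads - nSummit))
        trt <- .sampleStarts(nBody, si, trueDomains(truth), enr, readLength)
        if (nSummit > 0L) {
            sChr <- rep(as.character(
                GenomicRanges::seqnames(trueSummits(truth))),
                each = summitReads)
            sPos <- rep(GenomicRanges::start(trueSummits(truth)) - 1L,
                        each = summitReads)
            sStarts <- round(rnorm(nSummit, sPos - readLength / 2, 15))
            lens <- GenomeInfoDb::seqlengths(si)
            sStarts <- pmax(0, pmin(sStarts, lens[sChr] - readLength))
            trt$chrom <- c(trt$chrom, sChr)
            trt$starts0 <- c(trt$starts0, sStarts)
        }
        mkMapq <- function(n) {
            ifelse(runif(n) < lowMapqFrac, 10L, 60L)
        }
        treatment <- .writeReadsBam(trt$chrom, trt$starts0,
                                    mkMapq(length(trt$starts0)), si,
                                    file.path(dir, sprintf(
                                        "treatment_seed%d", seed)),
                                    readLength)
        control <- .writeReadsBam(ctl$chrom, ctl$starts0,
                                  mkMapq(length(ctl$starts0)), si,
                                  file.path(dir, sprintf(
                                      "control_seed%d", seed)),
                                  readLength)
        list(treatment = treatment, control = control, chromSizes = si)
    })
}

#' Write a Seqinfo as a chrom.sizes file
#'
#' @param si A [GenomeInfoDb::Seqinfo].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeChromSizes <- function(si, path) {
    writeLines(sprintf("%s\t%d", GenomeInfoDb::seqnames(si),
                       GenomeInfoDb::seqlengths(si)), path)
    invisible(path)
}
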