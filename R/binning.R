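## Stage 1: MAPQ-filtered read counting into uniform genomic bins.

#' Read a UCSC-style chrom.sizes file
#'
#' Parses a two-column whitespace-delimited text file of chromosome names
#' and lengths (the UCSC `chrom.sizes` dialect).  Extra columns are
#' ignored; blank lines are skipped.  File order is preserved.
#'
#' @param path Path to the chrom.sizes file.
#' @return A [GenomeInfoDb::Seqinfo] object with one entry per chromosome.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t1000000", "chr2\t500000"), f)
#' readChromSizes(f)
#' @export
readChromSizes <- function(path) {
    if (!file.exists(path))
        stop("chrom.sizes file not found: ", path)
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    if (!any(keep))
        stop("chrom.sizes file is empty: ", path)
    nms <- character(0)
    lens <- numeric(0)
    for (i in which(keep)) {
        fields <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
        if (length(fields) < 2L)
            stop("malformed chrom.sizes line ", i,
                 ": expected at least 2 fields, got ", length(fields))
        len <- suppressWarnings(as.numeric(fields[2]))
        if (is.na(len) || len <= 0 || len != floor(len))
            stop("malformed chrom.sizes line ", i,
                 ": length '", fields[2], "' is not a positive integer")
        nms <- c(nms, fields[1])
        lens <- c(lens, len)
    }
    if (anyDuplicated(nms))
        stop("duplicate chromosome name(s) in ", path, ": ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
    GenomeInfoDb::Seqinfo(seqnames = nms, seqlengths = lens)
}

#' Assign a read to a genomic bin
#'
#' A read is assigned to exactly one bin by its 0-based leftmost aligned
#' coordinate: bin index `floor(position / binWidth)`.  Bins are half-open,
#' so position `binWidth - 1` falls in bin 0 and position `binWidth` in
#' bin 1.
#'
#' @param position 0-based leftmost aligned coordinate(s).
#' @param binWidth Bin width in bp.
#' @return Integer bin index (0-based), vectorized over `position`.
#' @examples
#' assignReadToBin(c(0, 999, 1000, 1500), binWidth = 1000)
#' @export
assignReadToBin <- function(position, binWidth) {
    if (any(position < 0))
        stop("read positions must be >= 0 (0-based leftmost coordinate)")
    if (binWidth <= 0)
        stop("'binWidth' must be positive")
    as.integer(position %/% binWidth)
}

.bamIndexPath <- function(file) {
    cand <- c(paste0(file, ".bai"), sub("\\.bam$", ".bai", file))
    cand[file.exists(cand)][1]
}

#' Count MAPQ-filtered reads into uniform genomic bins
#'
#' Reads a coordinate-sorted, indexed BAM file and counts reads into
#' uniform bins spanning each chromosome in `chromSizes`.  Only mapped,
#' primary, non-supplementary alignments with mapping quality at least
#' `minMapq` are counted; the default threshold of 30 removes reads that
#' map to multiple locations or align poorly.  Each surviving read
#' increments exactly one bin, chosen by its 0-based leftmost aligned
#' coordinate.  For paired-end input each mapped mate is counted
#' independently.
#'
#' Chromosomes present in the BAM header but absent from `chromSizes` are
#' skipped with a warning, as are reads whose start lies at or beyond the
#' declared chromosome length.  Chromosomes in `chromSizes` with no reads
#' get all-zero counts.
#'
#' @param file Path to a coordinate-sorted BAM file with a `.bai` index.
#' @param chromSizes A [GenomeInfoDb::Seqinfo], e.g. from
#'   [readChromSizes()].
#' @param binWidth Bin width in bp (default 1000).
#' @param minMapq Minimum mapping quality (default 30).
#' @return A [BinnedReads-class] object; `totalReads()` gives the number of
#'   counted reads (the quantity depth normalization uses).
#' @seealso [makeObservations()] for the next pipeline stage.
#' @export
countBamBins <- function(file, chromSizes, binWidth = 1000, minMapq = 30) {
    stopifnot(is(chromSizes, "Seqinfo"))
    if (!file.exists(file))
        stop("BAM file not found: ", file)
    idx <- .bamIndexPath(file)
    if (is.na(idx))
        stop("BAM index (.bai) not found for ", file,
             "; input must be coordinate-sorted and indexed")
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = minMapq,
                                     what = c("rname", "pos"))
    res <- Rsamtools::scanBam(file, index = idx, param = param)[[1]]
    rname <- as.character(res$rname)
    pos0 <- res$pos - 1L  # BAM pos is 1-based
    known <- GenomeInfoDb::seqnames(chromSizes)
    extra <- setdiff(unique(rname), known)
    if (length(extra)) {
        warning("skipping reads on chromosome(s) absent from chrom.sizes: ",
                paste(extra, collapse = ", "))
        keep <- rname %in% known
        rname <- rname[keep]
        pos0 <- pos0[keep]
    }
    lens <- GenomeInfoDb::seqlengths(chromSizes)
    beyond <- pos0 >= lens[rname]
    if (any(beyond)) {
        warning(sum(beyond), " read(s) start at or beyond the declared ",
                "chromosome length; skipped")
        rname <- rname[!beyond]
        pos0 <- pos0[!beyond]
    }
    bins <- lapply(known, function(chr) {
        nbins <- as.integer(ceiling(lens[[chr]] / binWidth))
        p <- pos0[rname == chr]
        cnt <- tabulate(assignReadToBin(p, binWidth) + 1L, nbins = nbins)
        BinnedCounts(chr, cnt, binWidth = binWidth)
    })
    names(bins) <- known
    BinnedReads(bins, totalReads = length(pos0), binWidth = binWidth)
}

#' Write binned counts as three-column text
#'
#' Persists a [BinnedReads-class] object as plain text
#' (chromosome, 0-based bin start, count), one row per bin.
#'
#' @param binned A [BinnedReads-class] object.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeBinnedCounts <- function(binned, path) {
    rows <- lapply(chromBins(binned), function(bc) {
        data.frame(chrom = chromName(bc),
                   start = (seq_along(counts(bc)) - 1L) * binWidth(bc),
                   count = counts(bc))
    })
    df <- do.call(rbind, rows)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
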