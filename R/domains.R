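## Stage 3: per-bin posteriors -> BED domain calls and colored bin tracks.

#' Merge confident enriched bins into domain calls
#'
#' Enriched bins whose posterior exceeds `minPosterior` are grouped into
#' maximal runs of genomically consecutive bin indices; each run becomes
#' one domain spanning `[firstBin * binWidth, (lastBin + 1) * binWidth)`
#' (0-based half-open), reported as a `GRanges` (1-based closed, as usual
#' in Bioconductor).  Bins dropped during preprocessing (no reads in
#' either dataset) break contiguity by default - they carry no evidence of
#' enrichment - but `bridgeGaps = N` allows a run to span up to `N`
#' consecutive missing bins.
#'
#' Each call records `minPosterior` (the minimum enriched posterior over
#' its member bins, i.e. the confidence of its weakest bin) and `nBins`.
#'
#' @param track A [PosteriorTrack-class] from [decodeStates()].
#' @param minPosterior Posterior threshold; only bins strictly above it
#'   enter domains (default 0.9, the highest-confidence tier).
#' @param bridgeGaps Number of missing bins a run may span (default 0).
#' @return A `GRanges` with metadata columns `minPosterior` and `nBins`.
#' @export
binsToDomains <- function(track, minPosterior = 0.9, bridgeGaps = 0L) {
    stopifnot(is(track, "PosteriorTrack"))
    sel <- stateCalls(track) == "enriched" &
        statePosteriors(track) > minPosterior
    idx <- binIndices(track)[sel]
    post <- statePosteriors(track)[sel]
    bw <- binWidth(track)
    if (!length(idx)) {
        return(GenomicRanges::GRanges(seqnames = character(0),
                                      ranges = IRanges::IRanges(),
                                      minPosterior = numeric(0),
                                      nBins = integer(0)))
    }
    runId <- cumsum(c(1L, as.integer(diff(idx) > bridgeGaps + 1L)))
    first <- tapply(idx, runId, min)
    last <- tapply(idx, runId, max)
    minp <- as.numeric(tapply(post, runId, min))
    nb <- as.integer(tapply(idx, runId, length))
    GenomicRanges::GRanges(
        seqnames = chromName(track),
        ranges = IRanges::IRanges(start = as.integer(first) * bw + 1L,
                                  end = (as.integer(last) + 1L) * bw),
        minPosterior = minp, nBins = nb)
}

#' Clamp domain calls to chromosome bounds
#'
#' Ensures start/end coordinates conform to the chromosome sizes: ends are
#' cut back to the chromosome length (the last bin of a chromosome whose
#' length is not a multiple of the bin width extends past it otherwise),
#' starts are floored at position 0, and calls entirely outside the
#' chromosome are dropped.
#'
#' @param calls A `GRanges` of domain calls.
#' @param chromSizes A [GenomeInfoDb::Seqinfo].
#' @return The clamped `GRanges`.
#' @export
clampToChrom <- function(calls, chromSizes) {
    stopifnot(is(chromSizes, "Seqinfo"))
    chrs <- as.character(GenomicRanges::seqnames(calls))
    unknown <- setdiff(unique(chrs), GenomeInfoDb::seqnames(chromSizes))
    if (length(unknown))
        stop("domain call(s) on chromosome(s) absent from chrom.sizes: ",
             paste(unknown, collapse = ", "))
    if (!length(calls))
        return(calls)
    lens <- GenomeInfoDb::seqlengths(chromSizes)[chrs]
    newStart <- pmax(GenomicRanges::start(calls), 1L)
    newEnd <- pmin(GenomicRanges::end(calls), lens)
    keep <- newStart <= newEnd
    out <- calls[keep]
    IRanges::ranges(out) <- IRanges::IRanges(start = newStart[keep],
                                             end = newEnd[keep])
    out
}

.POSTERIOR_TIERS <- data.frame(
    floor = c(0.9, 0.8, 0.7),
    rgb = c("0,0,0", "120,120,120", "180,180,180")
)

.tierColor <- function(p) {
    out <- rep(NA_character_, length(p))
    for (k in seq_len(nrow(.POSTERIOR_TIERS)))
        out[is.na(out) & p > .POSTERIOR_TIERS$floor[k]] <-
            .POSTERIOR_TIERS$rgb[k]
    out
}

#' Write domain calls as a BED4 file
#'
#' One row per domain: chrom, 0-based half-open start/end, and a name that
#' carries the call's minimum enriched posterior (full precision, so the
#' file round-trips exactly through [readDomainsBed()]).
#'
#' @param calls A clamped `GRanges` from [binsToDomains()] /
#'   [clampToChrom()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeDomainsBed <- function(calls, path) {
    o <- order(as.character(GenomicRanges::seqnames(calls)),
               GenomicRanges::start(calls))
    calls <- calls[o]
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(calls)),
        start = GenomicRanges::start(calls) - 1L,
        end = GenomicRanges::end(calls),
        name = sprintf("dom%05d_p%s", seq_along(calls),
                       vapply(S4Vectors::mcols(calls)$minPosterior,
                              function(p) format(p, digits = 17),
                              character(1)))
    )
    con <- file(path, "w")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read a BED4 domains file back into GRanges
#'
#' Inverse of [writeDomainsBed()]: parses the BED with
#' `rtracklayer::import` and recovers the `minPosterior` metadata column
#' from the name field.
#'
#' @param path Path to a BED file written by [writeDomainsBed()].
#' @return A `GRanges` with `minPosterior` metadata.
#' @export
readDomainsBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- S4Vectors::mcols(gr)$name
    S4Vectors::mcols(gr) <- NULL
    S4Vectors::mcols(gr)$minPosterior <-
        as.numeric(sub("^.*_p", "", nm))
    gr
}

#' Write posterior-shaded enriched bins as a BED9 file
#'
#' One row per enriched bin with posterior above 0.7, color-coded by
#' confidence for the UCSC genome browser: black (`0,0,0`) above 0.9, then
#' sequentially lighter greys (`120,120,120` above 0.8, `180,180,180`
#' above 0.7).  Bins at or below 0.7 are omitted.  A track line with
#' `itemRgb="On"` is emitted so browsers honor the colors; the BED score
#' column carries `round(1000 * posterior)`.
#'
#' @param track A [PosteriorTrack-class] (or list of them) from
#'   [decodeStates()].
#' @param chromSizes A [GenomeInfoDb::Seqinfo] for end clamping.
#' @param path Output path.
#' @param trackName Name used in the track line.
#' @return Invisibly, the path.
#' @export
writeColoredBinsBed <- function(track, chromSizes, path,
                                trackName = "domainHMM_bins") {
    tracks <- if (is(track, "PosteriorTrack")) list(track) else track
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(
        'track name="%s" description="enriched bins shaded by posterior" itemRgb="On"',
        trackName), con)
    for (tr in tracks) {
        sel <- stateCalls(tr) == "enriched" & statePosteriors(tr) > 0.7
        if (!any(sel))
            next
        idx <- binIndices(tr)[sel]
        p <- statePosteriors(tr)[sel]
        bw <- binWidth(tr)
        len <- GenomeInfoDb::seqlengths(chromSizes)[[chromName(tr)]]
        start <- idx * bw
        end <- pmin((idx + 1L) * bw, len)
        df <- data.frame(
            chrom = chromName(tr), start = start, end = end,
            name = sprintf("bin%d_p%.3f", idx, p),
            score = as.integer(round(1000 * p)), strand = ".",
            thickStart = start, thickEnd = end, itemRgb = .tierColor(p))
        write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    invisible(path)
}
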