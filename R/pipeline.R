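## Full pipeline driver: bin -> normalize -> fit per chromosome (with
## average-parameter fallback) -> decode -> BED outputs + run report.

.formatParams <- function(p) {
    sprintf(paste0("prior=(%.4f,%.4f) trans=(%.4f,%.4f;%.4f,%.4f) ",
                   "mu=(%.4f,%.4f) sd=(%.4f,%.4f) enriched=%d"),
            p@prior[1], p@prior[2],
            p@transitions[1, 1], p@transitions[1, 2],
            p@transitions[2, 1], p@transitions[2, 2],
            p@means[1], p@means[2], p@sds[1], p@sds[2],
            resolveEnrichedState(p))
}

#' Call enriched domains from BAM files
#'
#' Runs the full three-stage pipeline: (1) MAPQ-filtered read binning for
#' the treatment and (optionally) control BAM, (2) depth normalization,
#' control subtraction, zero-bin exclusion and truncation followed by
#' per-chromosome EM fitting of the two-state Gaussian HMM - chromosomes
#' whose fit does not converge fall back to the average parameters of the
#' chromosomes that did - and posterior decoding, (3) merging of confident
#' enriched bins into domain calls clamped to chromosome bounds.
#'
#' If `outPrefix` is given, writes `<prefix>_domains.bed` (BED4),
#' `<prefix>_bins.bed` (BED9 colored by posterior tier) and
#' `<prefix>_report.txt` (per-chromosome parameters, log-likelihoods and
#' convergence flags).  Outputs are byte-identical across runs with the
#' same inputs, settings and seed.
#'
#' @param treatment Path to the treatment/ChIP BAM (sorted, indexed).
#' @param chromSizes A [GenomeInfoDb::Seqinfo] or path to a chrom.sizes
#'   file.
#' @param control Optional control/input BAM path.
#' @param binWidth Bin width in bp (default 1000).
#' @param minMapq Minimum mapping quality (default 30).
#' @param maxCount,minCount Truncation bounds for normalized values
#'   (defaults 200 and -10).
#' @param minPosterior Posterior threshold for the domains file
#'   (default 0.9).
#' @param bridgeGaps Missing bins a domain may span (default 0).
#' @param tol,maxIter EM settings (defaults 1e-4, 500).
#' @param seed Seed for the EM restart ladder (default 1).
#' @param outPrefix Optional output path prefix.
#' @return A list: `domains` (`GRanges`), `tracks` (list of
#'   [PosteriorTrack-class]), `fits` (list of [HMMFit-class]),
#'   `fallbackParams` ([HMMParams-class] or NULL), `report` (character
#'   vector), `files` (named vector of written paths, if any).
#' @examples
#' \donttest{
#' truth <- simulateTruthSet(seed = 1)
#' rd <- simulateReads(truth, treatmentReads = 2e4, controlReads = 2e4,
#'                     seed = 1)
#' res <- callDomains(rd$treatment, rd$chromSizes, control = rd$control,
#'                    maxCount = 3000, minCount = -300)
#' res$domains
#' }
#' @export
callDomains <- function(treatment, chromSizes, control = NULL,
                        binWidth = 1000, minMapq = 30, maxCount = 200,
                        minCount = -10, minPosterior = 0.9, bridgeGaps = 0L,
                        tol = 1e-4, maxIter = 500L, seed = 1L,
                        outPrefix = NULL) {
    if (is.character(chromSizes))
        chromSizes <- readChromSizes(chromSizes)
    stopifnot(is(chromSizes, "Seqinfo"))
    if (!(minPosterior > 0.5 && minPosterior < 1))
        stop("'minPosterior' must lie in (0.5, 1)")
    chip <- countBamBins(treatment, chromSizes, binWidth = binWidth,
                         minMapq = minMapq)
    ctl <- if (!is.null(control))
        countBamBins(control, chromSizes, binWidth = binWidth,
                     minMapq = minMapq)
    obs <- makeObservations(chip, ctl, maxCount = maxCount,
                            minCount = minCount)
    nonEmpty <- names(obs)[vapply(obs, function(s)
        length(obsValues(s)) > 0L, logical(1))]
    fits <- lapply(obs[nonEmpty], fitChromosome, tol = tol,
                   maxIter = maxIter, seed = seed)
    conv <- vapply(fits, converged, logical(1))
    fallback <- NULL
    if (any(!conv)) {
        fallback <- averageParams(fits[conv])  # errors if none converged
        warning("chromosome(s) ", paste(nonEmpty[!conv], collapse = ", "),
                " did not converge; using average parameters from the ",
                "other chromosomes")
    }
    tracks <- lapply(nonEmpty, function(chr) {
        p <- if (conv[[chr]]) fittedParams(fits[[chr]]) else fallback
        decodeStates(obs[[chr]], p)
    })
    names(tracks) <- nonEmpty
    calls <- lapply(tracks, binsToDomains, minPosterior = minPosterior,
                    bridgeGaps = bridgeGaps)
    empty <- GenomicRanges::GRanges(seqnames = character(0),
                                    ranges = IRanges::IRanges(),
                                    minPosterior = numeric(0),
                                    nBins = integer(0))
    calls <- lapply(c(unname(calls), list(empty)), function(g) {
        GenomeInfoDb::seqlevels(g) <- GenomeInfoDb::seqnames(chromSizes)
        g
    })
    domains <- clampToChrom(do.call(c, calls), chromSizes)
    o <- order(as.character(GenomicRanges::seqnames(domains)),
               GenomicRanges::start(domains))
    domains <- domains[o]
    report <- c(
        "domainHMM run report",
        sprintf("treatment: %s (counted reads: %.0f)", treatment,
                totalReads(chip)),
        if (!is.null(control))
            sprintf("control: %s (counted reads: %.0f)", control,
                    totalReads(ctl))
        else "control: none (no-control normalization, floor 0)",
        sprintf("binWidth=%d minMapq=%d maxCount=%g minCount=%g", binWidth,
                minMapq, maxCount, if (is.null(control)) 0 else minCount),
        sprintf("minPosterior=%g bridgeGaps=%d tol=%g maxIter=%d seed=%d",
                minPosterior, as.integer(bridgeGaps), tol,
                as.integer(maxIter), as.integer(seed)),
        sprintf("divisor=%g", selectDivisor(
            if (is.null(control)) totalReads(chip)
            else min(totalReads(chip), totalReads(ctl)))),
        sprintf("domains called: %d", length(domains)),
        "per-chromosome fits:",
        vapply(nonEmpty, function(chr) {
            f <- fits[[chr]]
            sprintf("  %s: converged=%s iter=%d loglik=%.6f %s%s", chr,
                    converged(f), f@nIterations,
                    if (length(loglikTrace(f)))
                        tail(loglikTrace(f), 1) else NA_real_,
                    .formatParams(if (conv[[chr]]) fittedParams(f)
                                  else fallback),
                    if (conv[[chr]]) "" else " [average-parameter fallback]")
        }, character(1)))
    files <- character(0)
    if (!is.null(outPrefix)) {
        files <- c(domains = paste0(outPrefix, "_domains.bed"),
                   bins = paste0(outPrefix, "_bins.bed"),
                   report = paste0(outPrefix, "_report.txt"))
        writeDomainsBed(domains, files[["domains"]])
        writeColoredBinsBed(tracks, chromSizes, files[["bins"]])
        writeLines(report, files[["report"]])
    }
    list(domains = domains, tracks = tracks, fits = fits,
         fallbackParams = fallback, report = report, files = files)
}

#' Refine a domains BED to peak centers (file-level driver)
#'
#' Reads a domains BED (as written by [callDomains()]), refines each
#' domain to its coverage-maximum peak interval with [peakCenters()], and
#' writes the result as BED4.
#'
#' @param domainsBed Path to the domains BED file.
#' @param treatment Treatment BAM path (indexed).
#' @param chromSizes A [GenomeInfoDb::Seqinfo] or chrom.sizes path.
#' @param out Output BED path.
#' @param flank Peak half-width in bp (default 100).
#' @param minMapq Minimum mapping quality (default 30).
#' @return Invisibly, the peaks `GRanges`.
#' @export
peakCentersFromBed <- function(domainsBed, treatment, chromSizes, out,
                               flank = 100, minMapq = 30) {
    if (is.character(chromSizes))
        chromSizes <- readChromSizes(chromSizes)
    domains <- readDomainsBed(domainsBed)
    peaks <- peakCenters(domains, treatment, chromSizes, flank = flank,
                         minMapq = minMapq)
    writePeaksBed(peaks, out)
    invisible(peaks)
}
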