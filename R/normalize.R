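## Stage 2 preprocessing: tiered depth normalization, control subtraction,
## zero-bin exclusion, truncation.

#' Select the tiered depth-normalization divisor
#'
#' The divisor is keyed on the smaller of the two datasets' total counted
#' reads: fewer than 1e7, 1e8 or 1e9 reads select divisors 1e6, 1e7 or 1e8
#' respectively.  Beyond 1e9 the pattern continues in powers of ten
#' (divisor = `10^(floor(log10(total)) - 1)`).
#'
#' @param minTotalReads Total counted reads of the smaller dataset.
#' @return The divisor (a power of ten).
#' @examples
#' selectDivisor(5e6)    # 1e6
#' selectDivisor(5e7)    # 1e7
#' @export
selectDivisor <- function(minTotalReads) {
    if (length(minTotalReads) != 1L || is.na(minTotalReads) ||
        minTotalReads <= 0)
        stop("total read count must be a single positive number")
    if (minTotalReads < 1e7) return(1e6)
    if (minTotalReads < 1e8) return(1e7)
    if (minTotalReads < 1e9) return(1e8)
    10^(floor(log10(minTotalReads)) - 1)
}

#' Depth-normalize binned read counts
#'
#' Expresses each bin's count in units of "reads per `divisor` sequenced
#' reads": `raw * divisor / totalReads`.  Both the ChIP and the control
#' dataset are normalized with the same divisor (chosen from the smaller
#' dataset by [selectDivisor()]) so that their values are comparable before
#' subtraction.
#'
#' @param counts A [BinnedCounts-class] object or a numeric vector of raw
#'   counts.
#' @param totalReads Total counted reads in the dataset the counts came
#'   from.
#' @param divisor Normalization divisor, from [selectDivisor()].
#' @return Numeric vector of normalized per-bin values.
#' @examples
#' normalizeCounts(c(0, 10), totalReads = 5e6, divisor = 1e6)
#' @export
normalizeCounts <- function(counts, totalReads, divisor) {
    if (totalReads <= 0)
        stop("'totalReads' must be positive")
    raw <- if (is(counts, "BinnedCounts")) counts(counts) else as.numeric(counts)
    raw * divisor / totalReads
}

#' Subtract normalized control from ChIP and drop empty bins
#'
#' Computes per-bin normalized differences (ChIP minus control) and retains
#' only bins with at least one raw read in either dataset; bins with no
#' reads in both carry no evidence and are excluded from the model.  The
#' returned series records which genomic bins survived.
#'
#' @param chipNorm,controlNorm Normalized per-bin values (equal length).
#' @param chipRaw,controlRaw The corresponding raw [BinnedCounts-class]
#'   objects (used for the zero-bin filter and for bin/chromosome
#'   bookkeeping).
#' @return An [ObservationSeries-class] of retained differences.
#' @export
subtractAndFilter <- function(chipNorm, controlNorm, chipRaw, controlRaw) {
    stopifnot(is(chipRaw, "BinnedCounts"), is(controlRaw, "BinnedCounts"))
    n <- length(chipNorm)
    if (length(controlNorm) != n || length(counts(chipRaw)) != n ||
        length(counts(controlRaw)) != n)
        stop("chip/control vectors must all have the same length")
    keep <- (counts(chipRaw) + counts(controlRaw)) >= 1L
    ObservationSeries(chromName(chipRaw),
                      values = (chipNorm - controlNorm)[keep],
                      binIndices = which(keep) - 1L,
                      binWidth = binWidth(chipRaw))
}

#' Truncate observation values into a fixed range
#'
#' Clamps every observation into `[minCount, maxCount]`.  Truncation limits
#' the influence of repetitive regions on the fitted emission variances.
#' The defaults (200 and -10) suit control-subtracted values whose null
#' distribution is approximately normal, centered on 0 with standard
#' deviation around 5: the floor allows two standard deviations of
#' depletion while the ceiling caps extreme pile-ups.  Values exactly at a
#' bound are retained (clamped, not dropped), and truncation is idempotent.
#'
#' @param series An [ObservationSeries-class].
#' @param maxCount Ceiling (default 200).
#' @param minCount Floor (default -10).
#' @return The truncated [ObservationSeries-class]; bin indices unchanged.
#' @examples
#' s <- ObservationSeries("chr1", c(-25, 37.5, 350))
#' obsValues(truncateObservations(s))
#' @export
truncateObservations <- function(series, maxCount = 200, minCount = -10) {
    if (maxCount <= minCount)
        stop("'maxCount' must be greater than 'minCount'")
    ObservationSeries(chromName(series),
                      values = pmin(pmax(obsValues(series), minCount),
                                    maxCount),
                      binIndices = binIndices(series),
                      binWidth = binWidth(series))
}

#' Build an observation series without a control dataset
#'
#' When no control is available the observations are the normalized ChIP
#' counts themselves: the divisor is chosen from the ChIP total alone,
#' bins with zero ChIP reads are excluded, and the series is truncated
#' with floor 0 (counts cannot go negative without subtraction).
#'
#' @param chipRaw A [BinnedCounts-class] object.
#' @param totalReads Total counted ChIP reads.
#' @param maxCount Ceiling (default 200).
#' @param divisor Normalization divisor; defaults to
#'   `selectDivisor(totalReads)`.
#' @return An [ObservationSeries-class].
#' @export
prepareNoControl <- function(chipRaw, totalReads, maxCount = 200,
                             divisor = selectDivisor(totalReads)) {
    stopifnot(is(chipRaw, "BinnedCounts"))
    keep <- counts(chipRaw) >= 1L
    vals <- normalizeCounts(counts(chipRaw)[keep], totalReads, divisor)
    s <- ObservationSeries(chromName(chipRaw), vals,
                           binIndices = which(keep) - 1L,
                           binWidth = binWidth(chipRaw))
    truncateObservations(s, maxCount = maxCount, minCount = 0)
}

#' Turn binned ChIP (and control) counts into HMM observation series
#'
#' Per-chromosome driver for stage 2 preprocessing.  With a control, both
#' datasets are normalized with the shared divisor chosen from the smaller
#' dataset's total, the control is subtracted, bins with no reads in either
#' dataset are dropped, and the differences are truncated into
#' `[minCount, maxCount]`.  Without a control, [prepareNoControl()] is used
#' per chromosome (floor 0).
#'
#' @param chip A [BinnedReads-class] for the ChIP/treatment dataset.
#' @param control Optional [BinnedReads-class] for the control dataset.
#' @param maxCount,minCount Truncation bounds (defaults 200 and -10).
#' @return Named list of [ObservationSeries-class], one per chromosome
#'   (possibly empty series for read-free chromosomes).
#' @export
makeObservations <- function(chip, control = NULL, maxCount = 200,
                             minCount = -10) {
    stopifnot(is(chip, "BinnedReads"))
    if (is.null(control)) {
        divisor <- selectDivisor(totalReads(chip))
        return(lapply(chromBins(chip), prepareNoControl,
                      totalReads = totalReads(chip), maxCount = maxCount,
                      divisor = divisor))
    }
    stopifnot(is(control, "BinnedReads"))
    if (!identical(names(chromBins(chip)), names(chromBins(control))))
        stop("chip and control were binned over different chromosomes")
    if (binWidth(chip) != binWidth(control))
        stop("chip and control bin widths differ")
    divisor <- selectDivisor(min(totalReads(chip), totalReads(control)))
    out <- lapply(names(chromBins(chip)), function(chr) {
        chipRaw <- chip[[chr]]
        ctrlRaw <- control[[chr]]
        s <- subtractAndFilter(
            normalizeCounts(chipRaw, totalReads(chip), divisor),
            normalizeCounts(ctrlRaw, totalReads(control), divisor),
            chipRaw, ctrlRaw)
        truncateObservations(s, maxCount = maxCount, minCount = minCount)
    })
    names(out) <- names(chromBins(chip))
    out
}
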