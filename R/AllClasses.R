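#' @import methods
#' @importFrom stats dnorm rnorm runif sd var setNames rpois
#' @importFrom utils write.table tail head
#' @importFrom BiocGenerics counts
#' @importClassesFrom GenomeInfoDb Seqinfo
#' @importClassesFrom GenomicRanges GRanges
NULL

## Central value classes.  All genomic coordinates handled by these classes
## are 0-based half-open (bin index 0 covers bases [0, binWidth)); GRanges
## objects returned by higher-level functions follow the usual Bioconductor
## 1-based closed convention, and BED files are written 0-based half-open.

#' BinnedCounts: per-chromosome binned read counts
#'
#' Raw read counts over uniform genomic bins for one chromosome.  Bin index
#' 0 covers bases `[0, binWidth)`.  The number of bins is
#' `ceiling(chromLength / binWidth)`.
#'
#' @slot chromosome Chromosome name.
#' @slot binWidth Bin width in bp.
#' @slot counts Integer vector of non-negative per-bin read counts.
#'
#' @aliases BinnedCounts
#' @exportClass BinnedCounts
setClass("BinnedCounts",
    representation(
        chromosome = "character",
        binWidth = "integer",
        counts = "integer"
    )
)

setValidity("BinnedCounts", function(object) {
    msg <- NULL
    if (length(object@chromosome) != 1L || is.na(object@chromosome))
        msg <- c(msg, "'chromosome' must be a single non-NA name")
    if (length(object@binWidth) != 1L || is.na(object@binWidth) ||
        object@binWidth <= 0L)
        msg <- c(msg, "'binWidth' must be a single positive integer")
    if (anyNA(object@counts) || any(object@counts < 0L))
        msg <- c(msg, "'counts' must be non-negative and non-NA")
    if (is.null(msg)) TRUE else msg
})

#' Construct a BinnedCounts object
#'
#' @param chromosome Chromosome name.
#' @param counts Non-negative integer vector of per-bin counts.
#' @param binWidth Bin width in bp.
#' @return A [BinnedCounts-class] object.
#' @examples
#' BinnedCounts("chr1", c(0L, 3L, 1L), binWidth = 1000)
#' @export
BinnedCounts <- function(chromosome, counts, binWidth = 1000) {
    new("BinnedCounts", chromosome = as.character(chromosome),
        binWidth = as.integer(binWidth), counts = as.integer(counts))
}

#' BinnedReads: binned counts for a whole dataset
#'
#' Per-chromosome [BinnedCounts-class] objects for one sequencing dataset,
#' together with the total number of reads that passed the mapping-quality
#' filter and were counted.  The total is what depth normalization uses.
#'
#' @slot bins Named list of [BinnedCounts-class], one per chromosome.
#' @slot totalReads Number of counted reads across all chromosomes.
#' @slot binWidth Bin width in bp (shared by all chromosomes).
#'
#' @aliases BinnedReads
#' @exportClass BinnedReads
setClass("BinnedReads",
    representation(
        bins = "list",
        totalReads = "numeric",
        binWidth = "integer"
    )
)

setValidity("BinnedReads", function(object) {
    msg <- NULL
    if (!all(vapply(object@bins, is, logical(1), "BinnedCounts")))
        msg <- c(msg, "'bins' must be a list of BinnedCounts")
    nm <- names(object@bins)
    if (length(object@bins) && (is.null(nm) || anyDuplicated(nm)))
        msg <- c(msg, "'bins' must be uniquely named by chromosome")
    if (length(object@totalReads) != 1L || object@totalReads < 0)
        msg <- c(msg, "'totalReads' must be a single non-negative number")
    if (is.null(msg)) TRUE else msg
})

BinnedReads <- function(bins, totalReads, binWidth) {
    new("BinnedReads", bins = bins, totalReads = as.numeric(totalReads),
        binWidth = as.integer(binWidth))
}

#' ObservationSeries: the HMM's per-chromosome observations
#'
#' Normalized (and possibly truncated) per-bin values retained for model
#' fitting on one chromosome, with a map back to the original genomic bin
#' indices.  Bins dropped during preprocessing (no reads in either dataset)
#' are simply absent, so `binIndices` is strictly increasing but not
#' necessarily contiguous.
#'
#' @slot chromosome Chromosome name.
#' @slot values Numeric vector of observations.
#' @slot binIndices Integer vector of 0-based genomic bin indices, strictly
#'   increasing, same length as `values`.
#' @slot binWidth Bin width in bp.
#'
#' @aliases ObservationSeries
#' @exportClass ObservationSeries
setClass("ObservationSeries",
    representation(
        chromosome = "character",
        values = "numeric",
        binIndices = "integer",
        binWidth = "integer"
    )
)

setValidity("ObservationSeries", function(object) {
    msg <- NULL
    if (length(object@values) != length(object@binIndices))
        msg <- c(msg, "'values' and 'binIndices' must have equal length")
    if (length(object@binIndices) > 1L && any(diff(object@binIndices) <= 0L))
        msg <- c(msg, "'binIndices' must be strictly increasing")
    if (length(object@binIndices) && any(object@binIndices < 0L))
        msg <- c(msg, "'binIndices' must be non-negative")
    if (anyNA(object@values))
        msg <- c(msg, "'values' must not contain NA")
    if (is.null(msg)) TRUE else msg
})

#' Construct an ObservationSeries
#'
#' @param chromosome Chromosome name.
#' @param values Numeric observations.
#' @param binIndices 0-based genomic bin indices (default: `0:(n-1)`).
#' @param binWidth Bin width in bp.
#' @return An [ObservationSeries-class] object.
#' @examples
#' ObservationSeries("chr1", c(1.5, -0.2, 4), binWidth = 1000)
#' @export
ObservationSeries <- function(chromosome, values,
                              binIndices = seq_along(values) - 1L,
                              binWidth = 1000) {
    new("ObservationSeries", chromosome = as.character(chromosome),
        values = as.numeric(values), binIndices = as.integer(binIndices),
        binWidth = as.integer(binWidth))
}

#' HMMParams: two-state Gaussian HMM parameters
#'
#' The full parameter set of the segmentation model: initial state
#' distribution, 2x2 row-stochastic transition matrix, and the two Gaussian
#' emission densities.  State order is (1 = "depleted", 2 = "enriched") by
#' construction convention; the label actually used for calling is always
#' re-derived from the fitted parameters by [resolveEnrichedState()] because
#' EM can converge to either labeling.
#'
#' @slot prior Length-2 probability vector, P(S_1 = i).
#' @slot transitions 2x2 row-stochastic matrix, P(S_{b+1} = j | S_b = i).
#' @slot means Length-2 emission means.
#' @slot sds Length-2 positive emission standard deviations.
#'
#' @aliases HMMParams
#' @exportClass HMMParams
setClass("HMMParams",
    representation(
        prior = "numeric",
        transitions = "matrix",
        means = "numeric",
        sds = "numeric"
    )
)

setValidity("HMMParams", function(object) {
    msg <- NULL
    tol <- 1e-6
    if (length(object@prior) != 2L || abs(sum(object@prior) - 1) > tol ||
        any(object@prior < -tol) || any(object@prior > 1 + tol))
        msg <- c(msg, "'prior' must be a length-2 probability vector")
    if (!identical(dim(object@transitions), c(2L, 2L)) ||
        any(abs(rowSums(object@transitions) - 1) > tol) ||
        any(object@transitions < -tol))
        msg <- c(msg, "'transitions' must be a 2x2 row-stochastic matrix")
    if (length(object@means) != 2L || anyNA(object@means))
        msg <- c(msg, "'means' must be a length-2 numeric vector")
    if (length(object@sds) != 2L || anyNA(object@sds) || any(object@sds <= 0))
        msg <- c(msg, "'sds' must be two positive standard deviations")
    if (is.null(msg)) TRUE else msg
})

#' Construct an HMMParams object
#'
#' @param prior Length-2 initial state probabilities.
#' @param transitions 2x2 row-stochastic transition matrix.
#' @param means Length-2 emission means (state order: depleted, enriched).
#' @param sds Length-2 positive emission standard deviations.
#' @return An [HMMParams-class] object.
#' @examples
#' HMMParams(c(0.5, 0.5), matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
#'           means = c(0, 15), sds = c(5, 5))
#' @export
HMMParams <- function(prior = c(0.5, 0.5),
                      transitions = matrix(c(0.9, 0.1, 0.1, 0.9), 2,
                                           byrow = TRUE),
                      means, sds) {
    new("HMMParams", prior = as.numeric(prior),
        transitions = matrix(as.numeric(transitions), 2, 2),
        means = as.numeric(means), sds = as.numeric(sds))
}

#' HMMFit: the result of fitting one chromosome
#'
#' @slot params Fitted [HMMParams-class].
#' @slot converged Whether EM reached the log-likelihood tolerance (and no
#'   emission state collapsed).
#' @slot loglikTrace Log-likelihood after each EM iteration; non-decreasing
#'   up to numerical tolerance.
#' @slot nIterations Number of EM iterations performed.
#'
#' @aliases HMMFit
#' @exportClass HMMFit
setClass("HMMFit",
    representation(
        params = "HMMParams",
        converged = "logical",
        loglikTrace = "numeric",
        nIterations = "integer"
    )
)

HMMFit <- function(params, converged, loglikTrace, nIterations) {
    new("HMMFit", params = params, converged = converged,
        loglikTrace = as.numeric(loglikTrace),
        nIterations = as.integer(nIterations))
}

#' PosteriorTrack: decoded per-bin states and posteriors
#'
#' Per-bin maximum-a-posteriori state labels (after enriched-state
#' resolution) and the posterior probability of the assigned state, for the
#' bins retained in an [ObservationSeries-class].
#'
#' @slot chromosome Chromosome name.
#' @slot binIndices 0-based genomic bin indices, strictly increasing.
#' @slot state Character vector, `"depleted"` or `"enriched"` per bin.
#' @slot posterior Probability of the assigned state per bin (in `[0.5, 1]`
#'   since the assigned state is the argmax of two).
#' @slot binWidth Bin width in bp.
#'
#' @aliases PosteriorTrack
#' @exportClass PosteriorTrack
setClass("PosteriorTrack",
    representation(
        chromosome = "character",
        binIndices = "integer",
        state = "character",
        posterior = "numeric",
        binWidth = "integer"
    )
)

setValidity("PosteriorTrack", function(object) {
    msg <- NULL
    n <- length(object@binIndices)
    if (length(object@state) != n || length(object@posterior) != n)
        msg <- c(msg, "'state' and 'posterior' must match 'binIndices' length")
    if (!all(object@state %in% c("depleted", "enriched")))
        msg <- c(msg, "'state' entries must be 'depleted' or 'enriched'")
    if (n && (any(object@posterior < 0.5 - 1e-9) ||
              any(object@posterior > 1 + 1e-9)))
        msg <- c(msg, "'posterior' of the assigned state must lie in [0.5, 1]")
    if (n > 1L && any(diff(object@binIndices) <= 0L))
        msg <- c(msg, "'binIndices' must be strictly increasing")
    if (is.null(msg)) TRUE else msg
})

PosteriorTrack <- function(chromosome, binIndices, state, posterior,
                           binWidth) {
    new("PosteriorTrack", chromosome = as.character(chromosome),
        binIndices = as.integer(binIndices), state = as.character(state),
        posterior = as.numeric(posterior), binWidth = as.integer(binWidth))
}

#' TruthSet: a synthetic genome with known enrichment
#'
#' Ground truth for validation: chromosome sizes, planted enriched domains,
#' planted narrow-peak summits, and the generator settings.  Serves the role
#' that independently validated (e.g. qPCR-verified) sites play for real
#' data.
#'
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] with the synthetic chromosomes.
#' @slot domains `GRanges` of planted enriched domains.
#' @slot summits `GRanges` (width 1) of planted peak summits.
#' @slot params Named list of generator settings (enrichment fold, etc.).
#' @slot seed Integer seed the truth set was drawn with.
#'
#' @aliases TruthSet
#' @exportClass TruthSet
setClass("TruthSet",
    representation(
        seqinfo = "Seqinfo",
        domains = "GRanges",
        summits = "GRanges",
        params = "list",
        seed = "integer"
    )
)

## ---- accessors ----

#' Accessors for domainHMM classes
#'
#' `chromName()` returns the chromosome a per-chromosome object describes;
#' `binWidth()` the bin width in bp; `counts()` the raw per-bin counts;
#' `obsValues()` and `binIndices()` the observation values and their 0-based
#' genomic bin indices; `stateCalls()` and `statePosteriors()` the decoded
#' labels and posteriors; `hmmPrior()`, `hmmTransitions()`,
#' `emissionMeans()`, `emissionSds()` the model parameters; `fittedParams()`,
#' `converged()`, `loglikTrace()` the components of a fit; `totalReads()`
#' the number of counted reads in a dataset.
#'
#' @param object A domainHMM S4 object.
#' @return The slot value described above.
#' @examples
#' bc <- BinnedCounts("chr1", c(2L, 0L, 5L), binWidth = 1000)
#' counts(bc)
#' binWidth(bc)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromName", function(object) standardGeneric("chromName"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("obsValues", function(object) standardGeneric("obsValues"))
#' @rdname accessors
#' @export
setGeneric("binIndices", function(object) standardGeneric("binIndices"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(object) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("stateCalls", function(object) standardGeneric("stateCalls"))
#' @rdname accessors
#' @export
setGeneric("statePosteriors",
           function(object) standardGeneric("statePosteriors"))
#' @rdname accessors
#' @export
setGeneric("hmmPrior", function(object) standardGeneric("hmmPrior"))
#' @rdname accessors
#' @export
setGeneric("hmmTransitions",
           function(object) standardGeneric("hmmTransitions"))
#' @rdname accessors
#' @export
setGeneric("emissionMeans", function(object) standardGeneric("emissionMeans"))
#' @rdname accessors
#' @export
setGeneric("emissionSds", function(object) standardGeneric("emissionSds"))
#' @rdname accessors
#' @export
setGeneric("fittedParams", function(object) standardGeneric("fittedParams"))
#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("loglikTrace", function(object) standardGeneric("loglikTrace"))

#' @rdname accessors
#' @export
setMethod("counts", "BinnedCounts", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("chromName", "BinnedCounts", function(object) object@chromosome)
#' @rdname accessors
#' @export
setMethod("chromName", "ObservationSeries",
          function(object) object@chromosome)
#' @rdname accessors
#' @export
setMethod("chromName", "PosteriorTrack", function(object) object@chromosome)
#' @rdname accessors
#' @export
setMethod("binWidth", "BinnedCounts", function(object) object@binWidth)
#' @rdname accessors
#' @export
setMethod("binWidth", "BinnedReads", function(object) object@binWidth)
#' @rdname accessors
#' @export
setMethod("binWidth", "ObservationSeries", function(object) object@binWidth)
#' @rdname accessors
#' @export
setMethod("binWidth", "PosteriorTrack", function(object) object@binWidth)
#' @rdname accessors
#' @export
setMethod("obsValues", "ObservationSeries", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("binIndices", "ObservationSeries",
          function(object) object@binIndices)
#' @rdname accessors
#' @export
setMethod("binIndices", "PosteriorTrack", function(object) object@binIndices)
#' @rdname accessors
#' @export
setMethod("totalReads", "BinnedReads", function(object) object@totalReads)
#' @rdname accessors
#' @export
setMethod("stateCalls", "PosteriorTrack", function(object) object@state)
#' @rdname accessors
#' @export
setMethod("statePosteriors", "PosteriorTrack",
          function(object) object@posterior)
#' @rdname accessors
#' @export
setMethod("hmmPrior", "HMMParams", function(object) object@prior)
#' @rdname accessors
#' @export
setMethod("hmmTransitions", "HMMParams", function(object) object@transitions)
#' @rdname accessors
#' @export
setMethod("emissionMeans", "HMMParams", function(object) object@means)
#' @rdname accessors
#' @export
setMethod("emissionSds", "HMMParams", function(object) object@sds)
#' @rdname accessors
#' @export
setMethod("fittedParams", "HMMFit", function(object) object@params)
#' @rdname accessors
#' @export
setMethod("converged", "HMMFit", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("loglikTrace", "HMMFit", function(object) object@loglikTrace)

#' @describeIn BinnedReads-class per-chromosome list of BinnedCounts
#' @param object,x A `BinnedReads` object.
#' @param i Chromosome name or index.
#' @export
setGeneric("chromBins", function(object) standardGeneric("chromBins"))
#' @rdname BinnedReads-class
#' @export
setMethod("chromBins", "BinnedReads", function(object) object@bins)
#' @rdname BinnedReads-class
#' @export
setMethod("[[", "BinnedReads", function(x, i) x@bins[[i]])

#' @describeIn TruthSet-class planted enriched domains as GRanges
#' @param object A `TruthSet` object.
#' @export
setGeneric("trueDomains", function(object) standardGeneric("trueDomains"))
#' @rdname TruthSet-class
#' @export
setMethod("trueDomains", "TruthSet", function(object) object@domains)
#' @describeIn TruthSet-class planted summit positions as width-1 GRanges
#' @export
setGeneric("trueSummits", function(object) standardGeneric("trueSummits"))
#' @rdname TruthSet-class
#' @export
setMethod("trueSummits", "TruthSet", function(object) object@summits)
#' @describeIn TruthSet-class Seqinfo of the synthetic genome
#' @export
setGeneric("truthSeqinfo", function(object) standardGeneric("truthSeqinfo"))
#' @rdname TruthSet-class
#' @export
setMethod("truthSeqinfo", "TruthSet", function(object) object@seqinfo)

## ---- show methods ----

setMethod("show", "BinnedCounts", function(object) {
    cat("BinnedCounts on ", object@chromosome, ": ",
        length(object@counts), " bins of ", object@binWidth, " bp, ",
        sum(object@counts), " reads\n", sep = "")
})

setMethod("show", "BinnedReads", function(object) {
    cat("BinnedReads: ", length(object@bins), " chromosome(s), bin width ",
        object@binWidth, " bp, ", format(object@totalReads, big.mark = ","),
        " counted reads\n", sep = "")
    for (bc in object@bins) {
        cat("  ", chromName(bc), ": ", length(counts(bc)), " bins, ",
            sum(counts(bc)), " reads\n", sep = "")
    }
})

setMethod("show", "ObservationSeries", function(object) {
    n <- length(object@values)
    cat("ObservationSeries on ", object@chromosome, ": ", n,
        " retained bins (", object@binWidth, " bp)\n", sep = "")
    if (n) {
        cat("  value range [", format(min(object@values), digits = 4), ", ",
            format(max(object@values), digits = 4), "], mean ",
            format(mean(object@values), digits = 4), "\n", sep = "")
    }
})

setMethod("show", "HMMParams", function(object) {
    cat("Two-state Gaussian HMM parameters\n")
    cat("  prior:      ", paste(format(object@prior, digits = 4),
        collapse = ", "), "\n", sep = "")
    cat("  transitions:", paste(format(t(object@transitions), digits = 4),
        collapse = " "), "\n", sep = " ")
    cat("  emissions:  state 1 N(", format(object@means[1], digits = 4),
        ", ", format(object@sds[1], digits = 4), "^2); state 2 N(",
        format(object@means[2], digits = 4), ", ",
        format(object@sds[2], digits = 4), "^2)\n", sep = "")
    cat("  enriched state by variance rule: ",
        resolveEnrichedState(object), "\n", sep = "")
})

setMethod("show", "HMMFit", function(object) {
    cat("HMMFit: ", if (object@converged) "converged" else "NOT converged",
        " after ", object@nIterations, " EM iteration(s), log-likelihood ",
        format(tail(object@loglikTrace, 1), digits = 8), "\n", sep = "")
    show(object@params)
})

setMethod("show", "PosteriorTrack", function(object) {
    n <- length(object@binIndices)
    ne <- sum(object@state == "enriched")
    cat("PosteriorTrack on ", object@chromosome, ": ", n, " bins (",
        object@binWidth, " bp), ", ne, " enriched\n", sep = "")
})

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet: ", length(GenomeInfoDb::seqnames(object@seqinfo)),
        " chromosome(s), ", length(object@domains),
        " planted domain(s), ", length(object@summits),
        " summit(s), seed ", object@seed, "\n", sep = "")
})
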