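#' @import methods
NULL

#' DescriptorTable: molecules by named numeric descriptors
#'
#' A dense numeric matrix of descriptor values with molecule identifiers as
#' row names and descriptor names as column names. Row and column names are
#' unique, every value is finite, and there is at least one descriptor
#' column. Descriptor names are opaque, case-sensitive strings, so externally
#' computed tables (e.g. MOE-style names such as \code{PEOE_VSA+4}) coexist
#' with the package's own analog registry.
#'
#' @slot values numeric matrix, rows = molecules, columns = descriptors.
#' @aliases DescriptorTable-class
#' @exportClass DescriptorTable
setClass("DescriptorTable", representation(values = "matrix"))

setValidity("DescriptorTable", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "values must be a numeric matrix")
    if ((nrow(v) > 0L && is.null(rownames(v))) || is.null(colnames(v)))
        msg <- c(msg, "values must carry molecule ids (rownames) and descriptor names (colnames)")
    else {
        if (anyDuplicated(rownames(v)))
            msg <- c(msg, "duplicate molecule ids")
        if (anyDuplicated(colnames(v)))
            msg <- c(msg, "duplicate descriptor names")
        if (any(rownames(v) == "") || any(colnames(v) == ""))
            msg <- c(msg, "empty id or descriptor name")
    }
    if (ncol(v) < 1L)
        msg <- c(msg, "at least one descriptor column is required")
    if (length(v) && !all(is.finite(v)))
        msg <- c(msg, "all descriptor values must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct a DescriptorTable
#'
#' @param values numeric matrix with molecule ids as rownames and descriptor
#'   names as colnames, or a data.frame whose first column \code{id} holds
#'   molecule ids and whose remaining columns are numeric descriptors.
#' @return A \linkS4class{DescriptorTable}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("a", "b", "c"), c("MW", "logP")))
#' DescriptorTable(m)
#' @export
DescriptorTable <- function(values) {
    if (is.data.frame(values)) {
        stopifnot("id" %in% colnames(values)[1])
        ids <- as.character(values[[1]])
        values <- as.matrix(values[, -1, drop = FALSE])
        rownames(values) <- ids
    }
    new("DescriptorTable", values = values)
}

#' FilterEfficiency: class-conditional rates of one range filter
#'
#' Percentages of actives passing (PA, the true-positive rate), inactives
#' passing (PNA, false positives), actives failing (NA, false negatives) and
#' inactives failing (NNA, true negatives), plus the rate-based Matthews
#' correlation coefficient computed from them. PA + NA = 100 and
#' PNA + NNA = 100 by construction.
#'
#' @slot pa,pna,na,nna numeric(1), percentages in [0, 100].
#' @slot mcc numeric(1) in [-1, 1].
#' @aliases FilterEfficiency-class
#' @exportClass FilterEfficiency
setClass("FilterEfficiency",
    representation(pa = "numeric", pna = "numeric", na = "numeric",
                   nna = "numeric", mcc = "numeric"))

setValidity("FilterEfficiency", function(object) {
    r <- c(object@pa, object@pna, object@na, object@nna)
    msg <- character()
    if (length(r) != 4L || any(!is.finite(r)) || any(r < 0) || any(r > 100))
        msg <- c(msg, "rates must be single finite percentages in [0, 100]")
    else {
        if (abs(object@pa + object@na - 100) > 1e-9)
            msg <- c(msg, "PA + NA must equal 100")
        if (abs(object@pna + object@nna - 100) > 1e-9)
            msg <- c(msg, "PNA + NNA must equal 100")
    }
    if (length(object@mcc) != 1L || object@mcc < -1 - 1e-12 ||
        object@mcc > 1 + 1e-12)
        msg <- c(msg, "mcc must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a FilterEfficiency from PA/PNA percentages
#'
#' @param pa percent of actives passing the filter (true-positive rate).
#' @param pna percent of inactives passing the filter (false-positive rate).
#' @param mcc optional precomputed rate-based MCC; computed with
#'   \code{\link{rateMCC}} when missing.
#' @return A \linkS4class{FilterEfficiency}.
#' @examples
#' FilterEfficiency(pa = 86.59, pna = 100 - 77.42)
#' @export
FilterEfficiency <- function(pa, pna, mcc = NULL) {
    if (is.null(mcc)) mcc <- rateMCC(pa = pa, nna = 100 - pna)
    new("FilterEfficiency", pa = pa, pna = pna, na = 100 - pa,
        nna = 100 - pna, mcc = mcc)
}

#' RangeFilter: a conjunction of closed descriptor intervals
#'
#' A molecule passes a filter iff, for every condition, its value for that
#' descriptor lies inside the closed interval [low, high]. Descriptor names
#' are unique within a filter and low <= high for every condition. A trained
#' filter additionally carries its \linkS4class{FilterEfficiency}.
#'
#' @slot conditions data.frame with columns \code{descriptor} (character),
#'   \code{low}, \code{high} (numeric).
#' @slot efficiency a \linkS4class{FilterEfficiency}, or NULL when untrained.
#' @aliases RangeFilter-class
#' @exportClass RangeFilter
setClass("RangeFilter",
    representation(conditions = "data.frame", efficiency = "ANY"),
    prototype(efficiency = NULL))

setValidity("RangeFilter", function(object) {
    cn <- object@conditions
    msg <- character()
    if (!all(c("descriptor", "low", "high") %in% colnames(cn)))
        msg <- c(msg, "conditions needs columns descriptor, low, high")
    else {
        if (nrow(cn) < 1L)
            msg <- c(msg, "a filter needs at least one condition")
        if (anyDuplicated(cn$descriptor))
            msg <- c(msg, "descriptor names must be unique within a filter")
        if (any(cn$low > cn$high))
            msg <- c(msg, "every condition needs low <= high")
    }
    if (!is.null(object@efficiency) && !is(object@efficiency, "FilterEfficiency"))
        msg <- c(msg, "efficiency must be NULL or a FilterEfficiency")
    if (length(msg)) msg else TRUE
})

#' Construct a RangeFilter
#'
#' @param descriptors character vector of descriptor names.
#' @param low,high numeric vectors of interval bounds (closed on both ends),
#'   recycled against \code{descriptors}.
#' @param efficiency optional \linkS4class{FilterEfficiency}.
#' @return A \linkS4class{RangeFilter}.
#' @examples
#' rangeFilter(c("MW", "logP"), low = c(0, -2), high = c(500, 5))
#' @export
rangeFilter <- function(descriptors, low, high, efficiency = NULL) {
    new("RangeFilter",
        conditions = data.frame(descriptor = as.character(descriptors),
                                low = as.numeric(low),
                                high = as.numeric(high),
                                stringsAsFactors = FALSE),
        efficiency = efficiency)
}

#' FilterEnsemble: a trained set of unique range filters
#'
#' The trained model: n unique \linkS4class{RangeFilter}s, each with its
#' training-set efficiency, the descriptor pool they were drawn from, and
#' training metadata (class sizes, split fraction, seed, configuration
#' snapshot, MBI penalty mode).
#'
#' @slot filters list of trained \linkS4class{RangeFilter}s.
#' @slot descriptorPool character, the descriptor universe of the search.
#' @slot trainingMeta named list.
#' @aliases FilterEnsemble-class
#' @exportClass FilterEnsemble
setClass("FilterEnsemble",
    representation(filters = "list", descriptorPool = "character",
                   trainingMeta = "list"))

setValidity("FilterEnsemble", function(object) {
    msg <- character()
    if (length(object@filters) < 1L)
        msg <- c(msg, "an ensemble needs at least one filter")
    ok <- vapply(object@filters, function(f)
        is(f, "RangeFilter") && is(f@efficiency, "FilterEfficiency"),
        logical(1))
    if (!all(ok))
        msg <- c(msg, "every ensemble member must be a trained RangeFilter")
    used <- unique(unlist(lapply(object@filters,
                                 function(f) f@conditions$descriptor)))
    if (length(used) && !all(used %in% object@descriptorPool))
        msg <- c(msg, "every descriptor used by a filter must be in descriptorPool")
    if (all(ok)) {
        keys <- vapply(object@filters, .filterKey, character(1))
        if (anyDuplicated(keys))
            msg <- c(msg, "duplicate filters (same descriptors and ranges)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a FilterEnsemble
#'
#' @param filters list of trained \linkS4class{RangeFilter}s.
#' @param descriptorPool character vector naming the descriptor universe.
#' @param trainingMeta named list of training metadata.
#' @return A \linkS4class{FilterEnsemble}.
#' @export
FilterEnsemble <- function(filters, descriptorPool,
                           trainingMeta = list()) {
    new("FilterEnsemble", filters = filters,
        descriptorPool = as.character(descriptorPool),
        trainingMeta = trainingMeta)
}

#' ScreenResult: MBI scores of a screened molecule set
#'
#' One row per molecule: the Molecular Bioactivity Index, the number of
#' filters passed, and the full pass/fail vector across the ensemble.
#' Results are sorted by decreasing MBI with ties broken by molecule id.
#'
#' @slot ids character, molecule ids in ranked order.
#' @slot mbi numeric MBI scores, same order.
#' @slot passMatrix logical matrix, molecules x filters.
#' @aliases ScreenResult-class
#' @exportClass ScreenResult
setClass("ScreenResult",
    representation(ids = "character", mbi = "numeric",
                   passMatrix = "matrix"))

setValidity("ScreenResult", function(object) {
    msg <- character()
    n <- length(object@ids)
    if (length(object@mbi) != n || (n && nrow(object@passMatrix) != n))
        msg <- c(msg, "ids, mbi and passMatrix rows must agree")
    if (n && !all(is.finite(object@mbi)))
        msg <- c(msg, "MBI scores must be finite")
    if (length(msg)) msg else TRUE
})

#' FingerprintSet: fixed-length binary molecular fingerprints
#'
#' A logical matrix of fingerprint bits (rows = molecules) tagged with the
#' generation scheme. Tanimoto comparisons across schemes are refused.
#'
#' @slot bits logical matrix, molecules x bits, rownames = molecule ids.
#' @slot scheme character(1) naming scheme and length, e.g. "OB-FP2-1024".
#' @aliases FingerprintSet-class
#' @exportClass FingerprintSet
setClass("FingerprintSet",
    representation(bits = "matrix", scheme = "character"))

setValidity("FingerprintSet", function(object) {
    msg <- character()
    if (!is.logical(object@bits))
        msg <- c(msg, "bits must be a logical matrix")
    if (length(object@scheme) != 1L || !nzchar(object@scheme))
        msg <- c(msg, "scheme must be a single non-empty string")
    if (length(msg)) msg else TRUE
})

#' IseConfig: tuning knobs of the iterative stochastic elimination search
#'
#' @slot filterSize integer, number of descriptor conditions per filter.
#' @slot lowerGrid,upperGrid numeric percentile grids (0-100) from which
#'   candidate interval bounds are taken on the active-class distribution.
#' @slot sampleSize integer, solutions sampled per elimination iteration.
#' @slot elimFraction fraction of worst-scoring solutions forming the
#'   "bottom" set used to indict values.
#' @slot topFraction fraction of best solutions whose values are protected.
#' @slot exhaustiveLimit space size at or below which the remaining space is
#'   enumerated exhaustively.
#' @slot restarts number of independent optimizer runs pooled into the
#'   ensemble.
#' @slot mccFloor minimum training-set rate-MCC for ensemble admission.
#' @slot maxEnsemble maximum ensemble size.
#' @slot seed integer RNG seed governing all stochastic steps.
#' @aliases IseConfig-class
#' @exportClass IseConfig
setClass("IseConfig",
    representation(filterSize = "integer", lowerGrid = "numeric",
                   upperGrid = "numeric", sampleSize = "integer",
                   elimFraction = "numeric", topFraction = "numeric",
                   exhaustiveLimit = "numeric", restarts = "integer",
                   mccFloor = "numeric", maxEnsemble = "integer",
                   seed = "integer"))

setValidity("IseConfig", function(object) {
    msg <- character()
    if (object@filterSize < 1L)
        msg <- c(msg, "filterSize must be >= 1")
    if (is.unsorted(object@lowerGrid) || is.unsorted(object@upperGrid))
        msg <- c(msg, "percentile grids must be sorted")
    if (max(object@lowerGrid) >= min(object@upperGrid))
        msg <- c(msg, "every lower percentile must be below every upper percentile")
    if (object@elimFraction <= 0 || object@elimFraction >= 1)
        msg <- c(msg, "elimFraction must lie in (0, 1)")
    if (object@topFraction <= 0 || object@topFraction >= 1)
        msg <- c(msg, "topFraction must lie in (0, 1)")
    if (object@exhaustiveLimit < 1)
        msg <- c(msg, "exhaustiveLimit must be >= 1")
    if (object@restarts < 1L || object@maxEnsemble < 1L)
        msg <- c(msg, "restarts and maxEnsemble must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct an IseConfig
#'
#' Defaults: 4-descriptor filters, percentile grids {0, 2.5, 5, 10, 25} and
#' {75, 90, 95, 97.5, 100} on the active-class distribution, 2000 sampled
#' solutions per iteration, elimination of the bottom 50\% with the top 5\%
#' protected, exhaustive enumeration below 1e5 solutions, 100 restarts, MCC
#' admission floor 0.55 and ensemble cap 50.
#'
#' @param filterSize,lowerGrid,upperGrid,sampleSize,elimFraction,topFraction,exhaustiveLimit,restarts,mccFloor,maxEnsemble,seed
#'   see the class documentation (\linkS4class{IseConfig}).
#' @return An \linkS4class{IseConfig}.
#' @examples
#' iseConfig(seed = 17, restarts = 5)
#' @export
iseConfig <- function(filterSize = 4L,
                      lowerGrid = c(0, 2.5, 5, 10, 25),
                      upperGrid = c(75, 90, 95, 97.5, 100),
                      sampleSize = 2000L,
                      elimFraction = 0.5,
                      topFraction = 0.05,
                      exhaustiveLimit = 1e5,
                      restarts = 100L,
                      mccFloor = 0.55,
                      maxEnsemble = 50L,
                      seed = 1L) {
    new("IseConfig", filterSize = as.integer(filterSize),
        lowerGrid = lowerGrid, upperGrid = upperGrid,
        sampleSize = as.integer(sampleSize), elimFraction = elimFraction,
        topFraction = topFraction, exhaustiveLimit = exhaustiveLimit,
        restarts = as.integer(restarts), mccFloor = mccFloor,
        maxEnsemble = as.integer(maxEnsemble), seed = as.integer(seed))
}

#' BenchmarkSpec: shape of the synthetic planted-box benchmark
#'
#' The generator emulates the statistical shape of a small active class
#' screened against a large putative-inactive library described by a wide
#' pool of numeric 2D descriptors, where only a minority of descriptors carry
#' range-separable signal. Defaults: 97 actives, 2892 inactives, 186
#' descriptors of which 6 are informative, active boxes spanning 25\% of the
#' inactive range, and 5\% of active draws falling outside their box.
#'
#' @slot nActive,nInactive,nDescriptors,nInformative integers.
#' @slot boxWidth fraction of the inactive range covered by each planted box.
#' @slot noiseRate fraction of active draws made outside the planted box.
#' @slot seed integer RNG seed.
#' @aliases BenchmarkSpec-class
#' @exportClass BenchmarkSpec
setClass("BenchmarkSpec",
    representation(nActive = "integer", nInactive = "integer",
                   nDescriptors = "integer", nInformative = "integer",
                   boxWidth = "numeric", noiseRate = "numeric",
                   seed = "integer"))

setValidity("BenchmarkSpec", function(object) {
    msg <- character()
    if (object@nInformative > object@nDescriptors)
        msg <- c(msg, "nInformative must be <= nDescriptors")
    if (object@boxWidth <= 0 || object@boxWidth >= 1)
        msg <- c(msg, "boxWidth must lie in (0, 1)")
    if (object@noiseRate < 0 || object@noiseRate >= 0.5)
        msg <- c(msg, "noiseRate must lie in [0, 0.5)")
    if (object@nActive < 1L || object@nInactive < 1L)
        msg <- c(msg, "class sizes must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a BenchmarkSpec
#'
#' @param nActive,nInactive,nDescriptors,nInformative,boxWidth,noiseRate,seed
#'   see the class documentation (\linkS4class{BenchmarkSpec}).
#' @return A \linkS4class{BenchmarkSpec}.
#' @examples
#' benchmarkSpec(seed = 7)
#' @export
benchmarkSpec <- function(nActive = 97L, nInactive = 2892L,
                          nDescriptors = 186L, nInformative = 6L,
                          boxWidth = 0.25, noiseRate = 0.05, seed = 1L) {
    new("BenchmarkSpec", nActive = as.integer(nActive),
        nInactive = as.integer(nInactive),
        nDescriptors = as.integer(nDescriptors),
        nInformative = as.integer(nInformative),
        boxWidth = boxWidth, noiseRate = noiseRate, seed = as.integer(seed))
}
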