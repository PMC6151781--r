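#' Rate-based Matthews correlation coefficient
#'
#' MCC computed on the normalized (class-conditional) confusion matrix: with
#' tp = PA/100, fn = NA/100, fp = PNA/100, tn = NNA/100,
#' \deqn{MCC = (tp \cdot tn - fp \cdot fn) /
#'   \sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}.}
#' Because rows are normalized to the class marginals, this is the balanced
#' form of the MCC: it weighs both classes equally regardless of how
#' imbalanced the training sets are (e.g. a small active class against a
#' large inactive library). The count-based MCC on raw confusion counts is
#' available via \code{countMCC} for comparison; on strongly imbalanced data
#' the two differ substantially.
#'
#' A degenerate denominator (any marginal zero) yields 0 by convention.
#'
#' @param pa percent of actives passing (true-positive rate), in [0, 100].
#' @param nna percent of inactives failing (true-negative rate), in [0, 100].
#' @return A number in [-1, 1].
#' @examples
#' rateMCC(pa = 86.59, nna = 77.42)   # 0.642 after rounding to 3 decimals
#' rateMCC(pa = 100, nna = 100)       # perfect filter: 1
#' rateMCC(pa = 50, nna = 50)         # uninformative: 0
#' @export
rateMCC <- function(pa, nna) {
    if (!is.finite(pa) || !is.finite(nna) || pa < 0 || pa > 100 ||
        nna < 0 || nna > 100)
        stop("rates must be percentages in [0, 100]")
    tp <- pa / 100; fn <- 1 - tp
    tn <- nna / 100; fp <- 1 - tn
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den <= 0) return(0)
    (tp * tn - fp * fn) / sqrt(den)
}

#' Count-based Matthews correlation coefficient
#'
#' The classical MCC on raw confusion-matrix counts. Provided as the
#' unbalanced alternative to \code{\link{rateMCC}}.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return A number in [-1, 1]; 0 when the denominator is degenerate.
#' @export
countMCC <- function(tp, fp, fn, tn) {
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den <= 0) return(0)
    (tp * tn - fp * fn) / sqrt(den)
}

# canonical dedup key: descriptor set + ranges, order-insensitive
.filterKey <- function(f, digits = 12) {
    cn <- f@conditions
    o <- order(cn$descriptor)
    paste(sprintf("%s:%.*g:%.*g", cn$descriptor[o], digits, cn$low[o],
                  digits, cn$high[o]), collapse = "|")
}

#' Does a molecule pass a range filter?
#'
#' A molecule passes iff, for every condition, its descriptor value lies in
#' the closed interval [low, high] (both endpoints included).
#'
#' @param filter a \linkS4class{RangeFilter}.
#' @param row named numeric vector of descriptor values covering every
#'   descriptor named by the filter.
#' @return logical(1).
#' @examples
#' f <- rangeFilter("MW", 0, 500)
#' filterPasses(f, c(MW = 500))   # closed interval: TRUE
#' filterPasses(f, c(MW = 500.1)) # FALSE
#' @export
filterPasses <- function(filter, row) {
    stopifnot(is(filter, "RangeFilter"))
    cn <- filter@conditions
    miss <- setdiff(cn$descriptor, names(row))
    if (length(miss))
        stop("row is missing descriptor(s): ", paste(miss, collapse = ", "))
    v <- as.numeric(row[cn$descriptor])
    all(v >= cn$low & v <= cn$high)
}

# vectorized pass over a DescriptorTable; returns logical vector per row
.passVector <- function(filter, table) {
    cn <- filter@conditions
    v <- descriptorValues(table)
    miss <- setdiff(cn$descriptor, colnames(v))
    if (length(miss))
        stop("descriptor table is missing descriptor(s): ",
             paste(miss, collapse = ", "))
    ok <- rep(TRUE, nrow(v))
    for (k in seq_len(nrow(cn))) {
        x <- v[, cn$descriptor[k]]
        ok <- ok & x >= cn$low[k] & x <= cn$high[k]
    }
    ok
}

#' Efficiency of a filter on labelled descriptor tables
#'
#' Computes the class-conditional pass rates of a filter: PA = percent of
#' actives passing, PNA = percent of inactives passing (NA and NNA are their
#' complements), plus the rate-based MCC.
#'
#' @param filter a \linkS4class{RangeFilter}.
#' @param actives,inactives \linkS4class{DescriptorTable}s of the two
#'   classes; both must be non-empty and cover the filter's descriptors.
#' @return A \linkS4class{FilterEfficiency}.
#' @examples
#' act <- DescriptorTable(matrix(c(1, 2, 3, 4), 4, 1,
#'     dimnames = list(paste0("a", 1:4), "x")))
#' inact <- DescriptorTable(matrix(c(5, 6, 7, 8, 2), 5, 1,
#'     dimnames = list(paste0("i", 1:5), "x")))
#' filterEfficiency(rangeFilter("x", 0, 4), act, inact)
#' @export
filterEfficiency <- function(filter, actives, inactives) {
    if (nrow(descriptorValues(actives)) == 0L ||
        nrow(descriptorValues(inactives)) == 0L)
        stop("both classes must be non-empty")
    pa <- 100 * mean(.passVector(filter, actives))
    pna <- 100 * mean(.passVector(filter, inactives))
    FilterEfficiency(pa = pa, pna = pna)
}
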