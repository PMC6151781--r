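#' ROC curve and AUC by descending-score sweep
#'
#' Sweeps a decision threshold over the unique scores in descending order
#' and records (false-positive rate, true-positive rate) at every cut. Tied
#' scores move as one block, so the trapezoidal area under the resulting
#' curve equals the Mann-Whitney probability that a random active outscores
#' a random inactive, with ties counted half.
#'
#' @param scores numeric scores (higher = more active).
#' @param labels logical (TRUE = active) or character
#'   ("active"/"inactive") class labels.
#' @return A list: \code{roc}, a data.frame with columns \code{fpr},
#'   \code{tpr} running from (0,0) to (1,1), and \code{auc}.
#' @examples
#' rocAuc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
    y <- .asActive(labels)
    if (!any(y) || all(y))
        stop("both classes must be represented")
    o <- order(scores, decreasing = TRUE)
    y <- y[o]; s <- scores[o]
    # block boundaries at unique score values
    newBlock <- c(TRUE, s[-1] != s[-length(s)])
    tp <- cumsum(y); fp <- cumsum(!y)
    ends <- which(c(newBlock[-1], TRUE))
    tpr <- c(0, tp[ends] / sum(y))
    fpr <- c(0, fp[ends] / sum(!y))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

.asActive <- function(labels) {
    if (is.logical(labels)) return(labels)
    l <- tolower(as.character(labels))
    if (!all(l %in% c("active", "inactive")))
        stop("labels must be logical or 'active'/'inactive'")
    l == "active"
}

#' Enrichment factor at a top fraction of the ranking
#'
#' EF(f) = (fraction of all actives captured within the top
#' \code{ceiling(f * N)} ranks) / f. A random ranking has EF close to 1; a
#' perfect ranking of a 1:1000 active/inactive mix has EF 100 at the top 1%
#' (all actives fit). Molecules tied across the rank cutoff are attributed
#' fractionally (block-averaged), which makes the statistic deterministic
#' under ties. At f = 1 the EF is exactly 1 for any scores.
#'
#' @param scores numeric scores (higher = more active).
#' @param labels logical or "active"/"inactive" labels.
#' @param topFrac fraction in (0, 1].
#' @return numeric(1), the enrichment factor.
#' @examples
#' s <- c(5, 4, 3, 2, 1); l <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
#' enrichmentFactor(s, l, topFrac = 0.4)  # captured 1/2 of actives: EF 1.25
#' @export
enrichmentFactor <- function(scores, labels, topFrac) {
    if (topFrac <= 0 || topFrac > 1)
        stop("topFrac must lie in (0, 1]")
    y <- .asActive(labels)
    if (!any(y)) stop("no actives in the labels")
    N <- length(scores)
    m <- ceiling(topFrac * N)
    o <- order(scores, decreasing = TRUE)
    y <- y[o]; s <- scores[o]
    if (m >= N) captured <- sum(y)
    else if (s[m] != s[m + 1L]) captured <- sum(y[seq_len(m)])
    else {
        # tie block straddles the cutoff: attribute its actives pro rata
        blk <- which(s == s[m])
        above <- blk[1L] - 1L
        captured <- sum(y[seq_len(above)]) +
            (m - above) * sum(y[blk]) / length(blk)
    }
    (captured / sum(y)) / topFrac
}

#' Enrichment curve (captured fraction vs screened fraction)
#'
#' @param scores,labels as in \code{\link{enrichmentFactor}}.
#' @param fractions screened top fractions to evaluate.
#' @return data.frame with columns \code{top_frac}, \code{captured_frac},
#'   \code{ef}.
#' @export
enrichmentCurve <- function(scores, labels,
                            fractions = c(0.001, 0.005, 0.01, 0.02, 0.05,
                                          0.1, 0.2, 0.5, 1)) {
    ef <- vapply(fractions, function(f)
        enrichmentFactor(scores, labels, f), numeric(1))
    data.frame(top_frac = fractions, captured_frac = ef * fractions,
               ef = ef)
}

#' Classification rates and MCC along the score axis
#'
#' For every threshold on a grid (200 uniform points over the observed score
#' range, augmented with every observed unique score), molecules are
#' classified active iff score >= threshold; the true-positive percentage,
#' false-positive percentage and rate-based MCC are reported. Below the
#' minimum score everything passes (tp% = fp% = 100) and the MCC degenerates
#' to 0; above the maximum nothing passes.
#'
#' @param scores,labels as in \code{\link{rocAuc}}.
#' @param gridSize number of uniform grid points (default 200).
#' @return data.frame with columns \code{threshold}, \code{tp_pct},
#'   \code{fp_pct}, \code{mcc}.
#' @export
mccThresholdCurve <- function(scores, labels, gridSize = 200L) {
    y <- .asActive(labels)
    if (!any(y) || all(y))
        stop("both classes must be represented")
    thr <- sort(unique(c(seq(min(scores), max(scores),
                             length.out = gridSize), scores)))
    tp <- vapply(thr, function(t) 100 * mean(scores[y] >= t), numeric(1))
    fp <- vapply(thr, function(t) 100 * mean(scores[!y] >= t), numeric(1))
    mcc <- mapply(function(a, b) rateMCC(pa = a, nna = 100 - b), tp, fp)
    data.frame(threshold = thr, tp_pct = tp, fp_pct = fp, mcc = mcc)
}

#' Descriptor-appearance enrichment within an ensemble
#'
#' Counts how often each descriptor appears across the conditions of all
#' filters in a trained ensemble and relates that count to the expectation
#' under random descriptor choice: expected = (total condition slots) /
#' (descriptor pool size); ratio = count / expected. With 47 filters of 4
#' conditions over a 186-descriptor pool, a descriptor appearing 24 times is
#' 23.7 times more frequent than random (1-decimal rounding).
#'
#' @param ensemble a \linkS4class{FilterEnsemble}.
#' @param poolSize descriptor pool size; defaults to the length of the
#'   ensemble's descriptor pool. Must be at least the number of distinct
#'   descriptors used.
#' @return data.frame (one row per used descriptor, decreasing count) with
#'   columns \code{descriptor}, \code{count}, \code{ratio} (full precision)
#'   and \code{ratio_rounded} (1 decimal).
#' @export
descriptorEnrichment <- function(ensemble, poolSize = NULL) {
    stopifnot(is(ensemble, "FilterEnsemble"))
    used <- unlist(lapply(ensemble@filters,
                          function(f) f@conditions$descriptor))
    if (is.null(poolSize)) poolSize <- length(ensemble@descriptorPool)
    tab <- table(used)
    if (poolSize < length(tab))
        stop("poolSize is smaller than the number of distinct descriptors used")
    slots <- length(used)
    expected <- slots / poolSize
    out <- data.frame(descriptor = names(tab),
                      count = as.integer(tab),
                      ratio = as.integer(tab) / expected,
                      stringsAsFactors = FALSE)
    out$ratio_rounded <- round(out$ratio, 1)
    out[order(-out$count, out$descriptor), , drop = FALSE]
}

#' Full evaluation report for a scored screen
#'
#' Bundles \code{\link{rocAuc}}, \code{\link{mccThresholdCurve}},
#' \code{\link{enrichmentCurve}} and enrichment factors at selected top
#' fractions into one report list (JSON-serializable).
#'
#' @param scores,labels as in \code{\link{rocAuc}}.
#' @param efAt top fractions at which to report enrichment factors.
#' @return A list with elements \code{auc}, \code{roc_points},
#'   \code{mcc_curve}, \code{enrichment_curve}, \code{ef_at}.
#' @export
evaluationReport <- function(scores, labels,
                             efAt = c(0.01, 0.02, 0.05, 0.1)) {
    r <- rocAuc(scores, labels)
    ef <- vapply(efAt, function(f) enrichmentFactor(scores, labels, f),
                 numeric(1))
    list(auc = r$auc, roc_points = r$roc,
         mcc_curve = mccThresholdCurve(scores, labels),
         enrichment_curve = enrichmentCurve(scores, labels),
         ef_at = stats::setNames(as.list(ef), paste0("top_", efAt)))
}
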