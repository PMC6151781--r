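#' Molecular Bioactivity Index of one molecule
#'
#' The MBI of a molecule against an n-filter ensemble is the average over
#' filters of a reward when the molecule passes and a penalty when it fails:
#' \deqn{MBI = \frac{1}{n} \sum_{i=1}^{n}
#'   \left( \delta_{Ai} \frac{PA_i}{PNA_i} -
#'          \delta_{NAi} \cdot penalty_i \right)}
#' where \eqn{\delta_{Ai}} is 1 iff the molecule passes filter i (and
#' \eqn{\delta_{NAi} = 1 - \delta_{Ai}}). The reward PA/PNA is the filter's
#' efficiency factor for actives. Two penalty orientations are provided:
#' \describe{
#'   \item{\code{"nna_over_na"} (default)}{penalty = NNA/NA, the
#'     true-negative to false-negative ratio. With filters of realistic
#'     efficiency this yields score floors of magnitude around -4.}
#'   \item{\code{"na_over_nna"}}{penalty = NA/NNA; yields floors an order of
#'     magnitude smaller (around -0.4).}
#' }
#' A zero denominator (PNA = 0 or, depending on mode, NA = 0 or NNA = 0) is
#' replaced by the half-count pseudocount rate 100 * 0.5 / N of the relevant
#' class, with N taken from the ensemble's training metadata
#' (\code{n_active_train} / \code{n_inactive_train}); this keeps efficiency
#' factors finite and monotone in the evidence.
#'
#' @param ensemble a \linkS4class{FilterEnsemble}.
#' @param row named numeric vector of descriptor values covering every
#'   descriptor used by the ensemble.
#' @param penaltyMode \code{"nna_over_na"} or \code{"na_over_nna"};
#'   defaults to the mode recorded in the ensemble's training metadata.
#' @return A list: \code{mbi} (numeric), \code{passVector} (logical per
#'   filter), \code{nPassed}.
#' @examples
#' f <- rangeFilter("x", 0, 1,
#'     efficiency = FilterEfficiency(pa = 50, pna = 5))
#' ens <- FilterEnsemble(list(f), "x",
#'     trainingMeta = list(n_active_train = 100, n_inactive_train = 1000))
#' mbiScore(ens, c(x = 0.5))$mbi   # 50/5 = 10
#' mbiScore(ens, c(x = 2))$mbi    # fails the filter: -(NNA/NA) = -95/50
#' @export
mbiScore <- function(ensemble, row, penaltyMode = NULL) {
    stopifnot(is(ensemble, "FilterEnsemble"))
    penaltyMode <- .resolvePenaltyMode(ensemble, penaltyMode)
    terms <- .mbiTerms(ensemble, penaltyMode)
    pass <- vapply(ensemble@filters, filterPasses, logical(1), row = row)
    mbi <- mean(ifelse(pass, terms$reward, -terms$penalty))
    list(mbi = mbi, passVector = pass, nPassed = sum(pass))
}

.resolvePenaltyMode <- function(ensemble, penaltyMode) {
    if (is.null(penaltyMode))
        penaltyMode <- ensemble@trainingMeta$penalty_mode
    if (is.null(penaltyMode)) penaltyMode <- "nna_over_na"
    match.arg(penaltyMode, c("nna_over_na", "na_over_nna"))
}

# per-filter reward and penalty terms with half-count pseudocount guards
.mbiTerms <- function(ensemble, penaltyMode) {
    nAct <- ensemble@trainingMeta$n_active_train
    nInact <- ensemble@trainingMeta$n_inactive_train
    pseudo <- function(rate, n) {
        if (rate > 0) return(rate)
        if (is.null(n)) stop("zero rate and no training class size recorded")
        100 * 0.5 / n
    }
    reward <- vapply(ensemble@filters, function(f) {
        e <- f@efficiency
        e@pa / pseudo(e@pna, nInact)
    }, numeric(1))
    penalty <- vapply(ensemble@filters, function(f) {
        e <- f@efficiency
        if (penaltyMode == "nna_over_na") e@nna / pseudo(e@na, nAct)
        else e@na / pseudo(e@nna, nInact)
    }, numeric(1))
    list(reward = reward, penalty = penalty)
}

#' Evaluate the MBI formula on explicit per-filter rates
#'
#' Low-level form of \code{\link{mbiScore}}: evaluates the index directly on
#' per-filter rate quadruples, without requiring a trained ensemble. Useful
#' for hand-worked checks of the formula, where the four rates are treated
#' as free parameters.
#'
#' @param pass logical vector, one entry per filter (delta_Ai).
#' @param pa,pna,na,nna numeric per-filter percentage rates.
#' @param penaltyMode \code{"nna_over_na"} (default) or \code{"na_over_nna"}.
#' @return numeric(1), the MBI.
#' @examples
#' mbiFromRates(TRUE, pa = 50, pna = 5, na = 20, nna = 80)   # 10
#' mbiFromRates(FALSE, pa = 50, pna = 5, na = 20, nna = 80)  # -4
#' @export
mbiFromRates <- function(pass, pa, pna, na, nna,
                         penaltyMode = c("nna_over_na", "na_over_nna")) {
    penaltyMode <- match.arg(penaltyMode)
    n <- length(pass)
    stopifnot(length(pa) == n, length(pna) == n, length(na) == n,
              length(nna) == n)
    reward <- pa / pna
    penalty <- if (penaltyMode == "nna_over_na") nna / na else na / nna
    mean(ifelse(pass, reward, -penalty))
}

#' Score a molecule set against a trained ensemble
#'
#' Computes the MBI of every molecule in a descriptor table and returns the
#' full ranking, sorted by decreasing MBI with ties broken by molecule id
#' (a stable, reproducible ordering). All molecules are emitted; no
#' threshold is applied.
#'
#' @param ensemble a \linkS4class{FilterEnsemble}.
#' @param table a \linkS4class{DescriptorTable} covering the ensemble's
#'   descriptors.
#' @param penaltyMode see \code{\link{mbiScore}}.
#' @return A \linkS4class{ScreenResult}.
#' @export
scoreSet <- function(ensemble, table, penaltyMode = NULL) {
    stopifnot(is(ensemble, "FilterEnsemble"), is(table, "DescriptorTable"))
    penaltyMode <- .resolvePenaltyMode(ensemble, penaltyMode)
    n <- nrow(descriptorValues(table))
    nf <- length(ensemble@filters)
    if (n == 0L)
        return(new("ScreenResult", ids = character(0), mbi = numeric(0),
                   passMatrix = matrix(FALSE, 0, nf)))
    terms <- .mbiTerms(ensemble, penaltyMode)
    pass <- vapply(ensemble@filters, .passVector, logical(n), table = table)
    pass <- matrix(pass, nrow = n)
    mbi <- as.numeric(pass %*% terms$reward -
                      (!pass) %*% terms$penalty) / nf
    ids <- moleculeIds(table)
    o <- order(-mbi, ids)
    rownames(pass) <- ids
    new("ScreenResult", ids = ids[o], mbi = mbi[o],
        passMatrix = pass[o, , drop = FALSE])
}
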