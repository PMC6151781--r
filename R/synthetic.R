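#' Generate a seeded planted-box benchmark
#'
#' Builds a synthetic active/inactive descriptor benchmark with the
#' statistical shape of a small labelled active class screened against a
#' large putative-inactive library over a wide descriptor pool:
#' \itemize{
#'   \item Every descriptor \eqn{j} gets a fixed range \eqn{[lo_j, hi_j]}
#'     (location and span drawn once from the seed); inactive values are
#'     i.i.d. uniform over that range.
#'   \item Uninformative descriptors carry strictly no signal: active values
#'     are drawn from the same uniform distribution as inactives.
#'   \item Each informative descriptor gets a planted box covering
#'     \code{boxWidth} of its range at a seeded position; each active value
#'     is drawn uniformly inside the box with probability 1 - noiseRate,
#'     otherwise uniformly outside the box (within the range).
#' }
#' Uniform marginals give closed-form expectations: the planted box passes
#' an inactive with probability \code{boxWidth}, and an active with
#' probability \code{1 - noiseRate}, so analytic oracles exist for every
#' downstream stage. Generation is fully deterministic per seed.
#'
#' @param spec a \linkS4class{BenchmarkSpec}.
#' @return A list with elements \code{actives} and \code{inactives}
#'   (\linkS4class{DescriptorTable}s of dimension nActive x nDescriptors and
#'   nInactive x nDescriptors) and \code{truth}, a list with
#'   \code{informative} (descriptor names), \code{boxes} (data.frame
#'   descriptor/low/high of every planted box) and \code{ranges} (data.frame
#'   descriptor/low/high of the full descriptor ranges).
#' @examples
#' bench <- generateBenchmark(benchmarkSpec(nActive = 10, nInactive = 50,
#'     nDescriptors = 8, nInformative = 2, seed = 7))
#' dim(bench$actives)
#' bench$truth$informative
#' @export
generateBenchmark <- function(spec) {
    stopifnot(is(spec, "BenchmarkSpec"))
    validObject(spec)
    D <- spec@nDescriptors
    nm <- sprintf("D%03d", seq_len(D))
    set.seed(spec@seed)

    lo <- stats::runif(D, -5, 5)
    span <- stats::runif(D, 0.5, 10)
    hi <- lo + span

    inf_idx <- sort(sample.int(D, spec@nInformative))
    bw <- spec@boxWidth * span[inf_idx]
    blo <- lo[inf_idx] + stats::runif(spec@nInformative) *
        (span[inf_idx] - bw)
    bhi <- blo + bw

    nA <- spec@nActive; nI <- spec@nInactive
    inact <- matrix(stats::runif(nI * D), nI, D)
    inact <- sweep(sweep(inact, 2L, span, "*"), 2L, lo, "+")
    act <- matrix(stats::runif(nA * D), nA, D)
    act <- sweep(sweep(act, 2L, span, "*"), 2L, lo, "+")

    for (k in seq_along(inf_idx)) {
        j <- inf_idx[k]
        inside <- stats::runif(nA) >= spec@noiseRate
        u <- stats::runif(nA)
        inbox <- blo[k] + u * (bhi[k] - blo[k])
        # outside draw: uniform over the range minus the box (piecewise)
        outspan <- span[j] - (bhi[k] - blo[k])
        pos <- u * outspan
        outbox <- ifelse(pos < (blo[k] - lo[j]), lo[j] + pos,
                         bhi[k] + (pos - (blo[k] - lo[j])))
        act[, j] <- ifelse(inside, inbox, outbox)
    }

    dimnames(act) <- list(sprintf("act%04d", seq_len(nA)), nm)
    dimnames(inact) <- list(sprintf("inact%04d", seq_len(nI)), nm)

    list(actives = DescriptorTable(act),
         inactives = DescriptorTable(inact),
         truth = list(
             informative = nm[inf_idx],
             boxes = data.frame(descriptor = nm[inf_idx], low = blo,
                                high = bhi, stringsAsFactors = FALSE),
             ranges = data.frame(descriptor = nm, low = lo, high = hi,
                                 stringsAsFactors = FALSE),
             seed = spec@seed))
}
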