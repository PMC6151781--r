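#' Hashed path fingerprints for a molecule set
#'
#' Computes OpenBabel FP2 fingerprints (hashed linear fragments up to seven
#' atoms, 1024 bits) for a molecule set. The scheme is recorded on the
#' result so that comparisons across schemes can be refused.
#'
#' @param mols a data.frame from \code{\link{readMolecules}} or a named
#'   character vector of SMILES.
#' @return A \linkS4class{FingerprintSet} with scheme \code{"OB-FP2-1024"}.
#' @export
fingerprints <- function(mols) {
    if (is.data.frame(mols))
        smiles <- stats::setNames(mols$smiles, mols$id)
    else {
        smiles <- mols
        if (is.null(names(smiles)))
            names(smiles) <- sprintf("m%d", seq_along(smiles))
    }
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
    valid <- ChemmineR::validSDF(sdf)
    if (!all(valid))
        stop("unparseable molecule(s): ",
             paste(names(smiles)[!valid], collapse = ", "))
    fp <- ChemmineR::fingerprintOB(sdf, "FP2")
    bits <- fp@fpma > 0
    rownames(bits) <- names(smiles)
    new("FingerprintSet", bits = bits, scheme = "OB-FP2-1024")
}

.fpBits <- function(x) {
    if (is(x, "FingerprintSet")) {
        if (nrow(x@bits) != 1L)
            stop("expected a single fingerprint; subset the FingerprintSet")
        list(bits = as.logical(x@bits[1L, ]), scheme = x@scheme)
    } else if (is.logical(x)) {
        list(bits = x, scheme = NA_character_)
    } else if (is.numeric(x)) {
        list(bits = x != 0, scheme = NA_character_)
    } else stop("not a fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' |intersection| / |union| of the set bits. By documented convention two
#' all-zero fingerprints have similarity 1 (identical emptiness). Comparing
#' fingerprints of different schemes or lengths is an error.
#'
#' @param a,b logical bit vectors, or single-molecule
#'   \linkS4class{FingerprintSet}s.
#' @return Similarity in [0, 1].
#' @examples
#' tanimoto(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE)) # 1/3
#' @export
tanimoto <- function(a, b) {
    fa <- .fpBits(a); fb <- .fpBits(b)
    if (!is.na(fa$scheme) && !is.na(fb$scheme) &&
        !identical(fa$scheme, fb$scheme))
        stop("comparison error: fingerprint schemes differ (", fa$scheme,
             " vs ", fb$scheme, ")")
    if (length(fa$bits) != length(fb$bits))
        stop("comparison error: fingerprint lengths differ")
    inter <- sum(fa$bits & fb$bits)
    union <- sum(fa$bits | fb$bits)
    if (union == 0L) return(1)
    inter / union
}

# dense pairwise Tanimoto matrix; all-zero pairs get similarity 1
.pairwiseTanimoto <- function(fps) {
    X <- fps@bits * 1
    inter <- X %*% t(X)
    ones <- rowSums(X)
    union <- outer(ones, ones, "+") - inter
    sim <- ifelse(union == 0, 1, inter / pmax(union, 1))
    sim
}

#' Pairwise diversity profile of a molecule set
#'
#' Computes Tanimoto similarity for all C(n,2) molecule pairs and reports a
#' histogram over similarity bins plus the fraction of pairs below the
#' conventional diversity thresholds (by default 0.7 and 0.9). Bin
#' fractions sum to 1.
#'
#' @param fps a \linkS4class{FingerprintSet} of at least two molecules (or
#'   anything \code{\link{fingerprints}} accepts).
#' @param breaks histogram breakpoints over [0, 1].
#' @param thresholds similarity thresholds at which "fraction below" is
#'   reported.
#' @return A list: \code{histogram} (data.frame bin_low/bin_high/fraction),
#'   \code{below} (named fractions), \code{n_pairs}, \code{scheme}.
#' @export
diversityProfile <- function(fps, breaks = seq(0, 1, by = 0.1),
                             thresholds = c(0.7, 0.9)) {
    if (!is(fps, "FingerprintSet")) fps <- fingerprints(fps)
    n <- nrow(fps@bits)
    if (n < 2L)
        stop("input error: diversity needs at least two molecules")
    sim <- .pairwiseTanimoto(fps)
    pairSim <- sim[upper.tri(sim)]
    h <- cut(pairSim, breaks, include.lowest = TRUE, labels = FALSE,
             right = FALSE)
    # top bin closed on the right so similarity 1 is counted
    h[pairSim >= breaks[length(breaks)]] <- length(breaks) - 1L
    counts <- tabulate(h, nbins = length(breaks) - 1L)
    below <- vapply(thresholds, function(t) mean(pairSim < t), numeric(1))
    list(histogram = data.frame(bin_low = utils::head(breaks, -1),
                                bin_high = utils::tail(breaks, -1),
                                fraction = counts / length(pairSim)),
         below = stats::setNames(below, paste0("below_", thresholds)),
         n_pairs = length(pairSim), scheme = fps@scheme)
}

#' Greedy similarity pruning
#'
#' Single greedy pass in input order: a molecule is kept iff its Tanimoto
#' similarity to every previously kept molecule is strictly below the
#' threshold. Already-diverse sets pass through unchanged.
#'
#' @param fps a \linkS4class{FingerprintSet} (or anything
#'   \code{\link{fingerprints}} accepts).
#' @param threshold similarity threshold in (0, 1].
#' @return Character vector of kept molecule ids.
#' @export
pruneSimilar <- function(fps, threshold = 0.9) {
    if (threshold <= 0 || threshold > 1)
        stop("threshold must lie in (0, 1]")
    if (!is(fps, "FingerprintSet")) fps <- fingerprints(fps)
    sim <- .pairwiseTanimoto(fps)
    ids <- rownames(fps@bits)
    kept <- integer(0)
    for (i in seq_along(ids)) {
        if (!length(kept) || all(sim[i, kept] < threshold))
            kept <- c(kept, i)
    }
    ids[kept]
}

.ruleValue <- function(row, candidates, what) {
    hit <- candidates[candidates %in% names(row)]
    if (!length(hit))
        stop("input error: missing required descriptor for ", what,
             " (any of: ", paste(candidates, collapse = ", "), ")")
    as.numeric(row[[hit[1]]])
}

#' Lipinski and Oprea rule profile of one molecule
#'
#' Counts rule violations from a named descriptor row. Lipinski's rule of
#' five: MW <= 500, logP <= 5, donors <= 5, acceptors <= 10; a molecule
#' "obeys" the rule with at most one violation (the rule's conventional
#' reading). Oprea lead-likeness (the MOE-style clause set, an
#' approximation since definitions vary across the literature): MW <= 450,
#' logP in [-3.5, 4.5], rings <= 4, rotatable bonds <= 10, donors <= 5,
#' acceptors <= 8; "obeys" means zero violations.
#'
#' @param row named numeric vector (or one-row data.frame/list) supplying
#'   MW, logP, donors (HBD/lip_don), acceptors (HBA/lip_acc), rings and
#'   rotatable bonds (rot/b_rotN). Missing inputs raise an error.
#' @return A list: \code{lipinski_violations}, \code{oprea_violations},
#'   \code{passes_lipinski}, \code{passes_oprea}.
#' @examples
#' ruleProfile(c(MW = 180, logP = 1.2, HBD = 1, HBA = 4,
#'               rings = 1, rot = 3))
#' @export
ruleProfile <- function(row) {
    if (is.data.frame(row)) row <- as.list(row[1, , drop = FALSE])
    if (is.numeric(row) && !is.null(names(row))) row <- as.list(row)
    mw <- .ruleValue(row, c("MW", "Weight", "mw"), "molecular weight")
    logp <- .ruleValue(row, c("logP", "SlogP", "logp"), "logP")
    hbd <- .ruleValue(row, c("HBD", "lip_don", "hbd", "a_don"), "donor count")
    hba <- .ruleValue(row, c("HBA", "lip_acc", "hba", "a_acc"),
                      "acceptor count")
    lip <- sum(mw > 500, logp > 5, hbd > 5, hba > 10)
    rings <- .ruleValue(row, c("rings", "nRings"), "ring count")
    rot <- .ruleValue(row, c("rot", "b_rotN", "rotatable"),
                      "rotatable bond count")
    opr <- sum(mw > 450, logp < -3.5 || logp > 4.5, rings > 4, rot > 10,
               hbd > 5, hba > 8)
    list(lipinski_violations = as.integer(lip),
         oprea_violations = as.integer(opr),
         passes_lipinski = lip <= 1L,
         passes_oprea = opr == 0L)
}

#' Rule profiles for every row of a descriptor table
#'
#' @param table a \linkS4class{DescriptorTable} supplying the descriptors
#'   \code{\link{ruleProfile}} needs.
#' @return data.frame, one row per molecule, with id and the four profile
#'   fields.
#' @export
ruleTable <- function(table) {
    v <- descriptorValues(table)
    out <- do.call(rbind, lapply(seq_len(nrow(v)), function(i) {
        p <- ruleProfile(v[i, ])
        data.frame(id = rownames(v)[i],
                   lipinski_violations = p$lipinski_violations,
                   oprea_violations = p$oprea_violations,
                   passes_lipinski = p$passes_lipinski,
                   passes_oprea = p$passes_oprea,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
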