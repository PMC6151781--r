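#' Stratified, seeded train/test split
#'
#' Splits molecules into training and test sets per class (stratified), with
#' the training-set size of each class equal to round-half-up of
#' \code{trainFrac} times the class size. Deterministic for a fixed seed;
#' the two index sets are disjoint and exhaustive.
#'
#' @param labels character or factor vector of class labels, one per
#'   molecule (e.g. "active"/"inactive").
#' @param trainFrac training fraction in (0, 1); default 2/3 (a 66.7/33.3
#'   split, under which 97 actives yield 65 train / 32 test).
#' @param seed integer RNG seed.
#' @return A list with integer index vectors \code{train} and \code{test}.
#' @examples
#' sp <- splitTrainTest(rep("active", 97), trainFrac = 0.667, seed = 1)
#' lengths(sp)  # 65 / 32
#' @export
splitTrainTest <- function(labels, trainFrac = 2 / 3, seed = 1L) {
    if (trainFrac <= 0 || trainFrac >= 1)
        stop("trainFrac must lie in (0, 1)")
    labels <- as.character(labels)
    set.seed(as.integer(seed))
    train <- integer(0)
    for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < 2L)
            stop("class '", cl, "' has fewer than 2 members; cannot split")
        nTrain <- floor(trainFrac * length(idx) + 0.5)  # round half up
        nTrain <- max(1L, min(length(idx) - 1L, nTrain))
        train <- c(train, sort(sample(idx, nTrain)))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
}

#' Candidate interval bounds from active-class percentiles
#'
#' For every descriptor, candidate ranges are the Cartesian pairs of the
#' lower-grid and upper-grid percentiles of the ACTIVE-class distribution
#' (the actives define the activity box; inactives enter only through
#' scoring), deduplicated. A constant descriptor yields a single degenerate
#' candidate with low = high.
#'
#' @param actives \linkS4class{DescriptorTable} of the active class.
#' @param cfg an \linkS4class{IseConfig} supplying the percentile grids.
#' @return Named list (one element per descriptor) of data.frames with
#'   columns \code{low}, \code{high}.
#' @examples
#' act <- DescriptorTable(matrix(1:100, 100, 1,
#'     dimnames = list(sprintf("m%03d", 1:100), "x")))
#' head(candidateRanges(act, iseConfig())$x)
#' @export
candidateRanges <- function(actives, cfg = iseConfig()) {
    v <- descriptorValues(actives)
    if (nrow(v) == 0L) stop("actives table is empty")
    lapply(stats::setNames(seq_len(ncol(v)), colnames(v)), function(j) {
        x <- v[, j]
        lo <- stats::quantile(x, cfg@lowerGrid / 100, names = FALSE)
        hi <- stats::quantile(x, cfg@upperGrid / 100, names = FALSE)
        g <- expand.grid(low = lo, high = hi)
        g <- g[g$low <= g$high, , drop = FALSE]
        unique(g)
    })
}

# elementary symmetric polynomial e_k over weights: the number of distinct
# solutions (k-descriptor subsets x one candidate range each)
.spaceSize <- function(weights, k) {
    w <- weights[weights > 0]
    if (length(w) < k) return(0)
    poly <- c(1, rep(0, k))
    for (wi in w)
        for (j in rev(seq_len(k)))
            poly[j + 1L] <- poly[j + 1L] + wi * poly[j]
    poly[k + 1L]
}

.rateMCCvec <- function(pa, nna) {
    tp <- pa / 100; fn <- 1 - tp
    tn <- nna / 100; fp <- 1 - tn
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    ifelse(den <= 0, 0, (tp * tn - fp * fn) / sqrt(pmax(den, 0)))
}

# score solutions given as an M x k matrix of value indices;
# packAct/packInact: bit-packed class x value pass matrices
.scoreSolutions <- function(S, packAct, packInact) {
    sc <- .scorePackedCpp(S, packAct, packInact)
    sc$mcc <- .rateMCCvec(sc$pa, 100 - sc$pna)
    sc
}

# enumerate every solution over alive values, in chunks; returns the top
# nTop by (mcc desc, lexicographic descriptor-set key)
.enumerateBest <- function(vdesc, alive, packAct, packInact, k, nTop,
                           chunk = 10000L) {
    aliveIdx <- which(alive)
    descs <- unique(vdesc[aliveIdx])
    if (length(descs) < k)
        stop("fewer than filterSize descriptors remain in the search space")
    byDesc <- split(aliveIdx, vdesc[aliveIdx])
    subsets <- utils::combn(sort(as.integer(names(byDesc))), k)
    best <- NULL
    flush <- function(S, best) {
        sc <- .scoreSolutions(S, packAct, packInact)
        keep <- utils::head(order(-sc$mcc), nTop)
        cand <- data.frame(mcc = sc$mcc[keep], pa = sc$pa[keep],
                           pna = sc$pna[keep])
        cand$sol <- lapply(keep, function(r) S[r, ])
        rbindBest <- if (is.null(best)) cand else rbind(best, cand)
        rbindBest[utils::head(order(-rbindBest$mcc), nTop), , drop = FALSE]
    }
    buf <- matrix(0L, 0L, k)
    for (s in seq_len(ncol(subsets))) {
        grid <- as.matrix(expand.grid(byDesc[as.character(subsets[, s])],
                                      KEEP.OUT.ATTRS = FALSE))
        storage.mode(grid) <- "integer"
        buf <- rbind(buf, grid)
        if (nrow(buf) >= chunk) {
            best <- flush(buf, best)
            buf <- matrix(0L, 0L, k)
        }
    }
    if (nrow(buf)) best <- flush(buf, best)
    best
}

#' One run of iterative stochastic elimination
#'
#' Searches the space of range filters (conjunctions of \code{filterSize}
#' descriptor conditions, each condition one of the candidate ranges from
#' \code{\link{candidateRanges}}) for filters maximizing the rate-based MCC
#' on the supplied training tables. Each iteration (1) samples
#' \code{sampleSize} solutions uniformly from the surviving space, (2)
#' scores them, (3) indicts every (descriptor, range) value that is
#' over-represented among the bottom \code{elimFraction} of solutions and
#' absent from the top \code{topFraction}, and eliminates it. When no value
#' qualifies, the worst-scoring value outside the top set is force-dropped
#' so the loop always contracts. Once the surviving space holds at most
#' \code{exhaustiveLimit} solutions it is enumerated exhaustively and the
#' best filters are returned. If the initial space is already below the
#' limit, sampling is skipped entirely. Deterministic for a fixed
#' \code{cfg@seed}.
#'
#' @param actives,inactives training-split \linkS4class{DescriptorTable}s
#'   sharing a descriptor pool (prune it first, see \code{\link{prunePool}}).
#' @param cfg an \linkS4class{IseConfig}.
#' @param nTop number of top filters to return from this run.
#' @param verbose log per-iteration space size and best sampled score.
#' @return List of up to \code{nTop} trained \linkS4class{RangeFilter}s,
#'   ordered by decreasing training MCC.
#' @export
iseOptimize <- function(actives, inactives, cfg = iseConfig(), nTop = 10L,
                        verbose = FALSE) {
    stopifnot(is(cfg, "IseConfig"))
    if (!identical(descriptorNames(actives), descriptorNames(inactives)))
        stop("actives and inactives must share one descriptor pool")
    k <- cfg@filterSize
    cand <- candidateRanges(actives, cfg)
    vdesc <- rep(seq_along(cand), vapply(cand, nrow, integer(1)))
    vlow <- unlist(lapply(cand, `[[`, "low"), use.names = FALSE)
    vhigh <- unlist(lapply(cand, `[[`, "high"), use.names = FALSE)
    V <- length(vdesc)
    dn <- descriptorNames(actives)

    passOf <- function(tab) {
        v <- descriptorValues(tab)
        m <- matrix(0L, nrow(v), V)
        for (u in seq_len(V)) {
            x <- v[, vdesc[u]]
            m[, u] <- as.integer(x >= vlow[u] & x <= vhigh[u])
        }
        m
    }
    packAct <- .packPassBits(passOf(actives))
    packInact <- .packPassBits(passOf(inactives))

    set.seed(cfg@seed)
    alive <- rep(TRUE, V)
    repeat {
        w <- tabulate(vdesc[alive], nbins = length(cand))
        size <- .spaceSize(w, k)
        if (size == 0)
            stop("fewer than filterSize descriptors remain in the search space")
        if (size <= cfg@exhaustiveLimit) break

        aliveDesc <- which(w > 0)
        M <- cfg@sampleSize
        # k distinct descriptors per solution: sample with replacement,
        # then redraw the few rows containing duplicates
        D <- matrix(aliveDesc[sample.int(length(aliveDesc), M * k,
                                         replace = TRUE)], M, k)
        repeat {
            dup <- which(apply(D, 1L, anyDuplicated) > 0L)
            if (!length(dup)) break
            D[dup, ] <- aliveDesc[sample.int(length(aliveDesc),
                                             length(dup) * k,
                                             replace = TRUE)]
        }
        # one uniform surviving range per chosen descriptor; alive value
        # indices are grouped by descriptor because vdesc is sorted
        aliveVals <- which(alive)
        start <- cumsum(w) - w
        S <- matrix(aliveVals[start[D] +
                              pmax(1, ceiling(stats::runif(M * k) * w[D]))],
                    M, k)
        sc <- .scoreSolutions(S, packAct, packInact)
        if (verbose)
            message(sprintf("space %.3g, best sampled MCC %.3f", size,
                            max(sc$mcc)))

        rk <- order(sc$mcc)                           # ascending
        nBottom <- max(1L, floor(cfg@elimFraction * M))
        nTopSol <- max(1L, ceiling(cfg@topFraction * M))
        bottom <- rk[seq_len(nBottom)]
        top <- rk[seq.int(M - nTopSol + 1L, M)]
        cntBottom <- tabulate(S[bottom, ], nbins = V)
        cntTop <- tabulate(S[top, ], nbins = V)
        cntAll <- tabulate(S, nbins = V)
        elim <- alive & cntTop == 0L & cntBottom >= 1L &
            cntBottom > cfg@elimFraction * cntAll

        if (!any(elim)) {
            # forced contraction: drop the worst-mean-scoring value not
            # protected by the top solutions
            meanSc <- rep(NA_real_, V)
            seen <- which(alive & cntAll > 0L & cntTop == 0L)
            if (!length(seen)) seen <- which(alive & cntAll > 0L)
            for (u in seen)
                meanSc[u] <- mean(sc$mcc[which(rowSums(S == u) > 0L)])
            drop1 <- seen[which.min(meanSc[seen])]
            elim[drop1] <- TRUE
        }
        # never let the alive-descriptor count fall below filterSize
        wAfter <- tabulate(vdesc[alive & !elim], nbins = length(cand))
        lostDesc <- which(w > 0 & wAfter == 0)
        if (sum(wAfter > 0) < k) {
            for (d in lostDesc) {
                if (sum(wAfter > 0) >= k) break
                keepBack <- which(elim & vdesc == d)[1L]
                elim[keepBack] <- FALSE
                wAfter[d] <- 1L
            }
        }
        alive <- alive & !elim
    }

    best <- .enumerateBest(vdesc, alive, packAct, packInact, k,
                           as.integer(nTop))
    nA <- nrow(descriptorValues(actives))
    lapply(seq_len(nrow(best)), function(r) {
        sol <- sort(best$sol[[r]])
        rangeFilter(dn[vdesc[sol]], vlow[sol], vhigh[sol],
                    efficiency = FilterEfficiency(pa = best$pa[r],
                                                  pna = best$pna[r]))
    })
}

#' Assemble a filter ensemble from optimizer runs
#'
#' Pools the filters of one or more \code{\link{iseOptimize}} runs,
#' recomputes every filter's efficiency on the full training tables, drops
#' filters below the MCC admission floor, deduplicates filters sharing both
#' descriptor set and all ranges (within 1e-9), and keeps the top
#' \code{maxEnsemble} by MCC, ties broken by fewer conditions and then
#' lexicographic descriptor names.
#'
#' @param runs list of filter lists (one element per run), or a flat list of
#'   \linkS4class{RangeFilter}s.
#' @param cfg an \linkS4class{IseConfig} (admission floor, ensemble cap).
#' @param actives,inactives full training \linkS4class{DescriptorTable}s on
#'   which efficiencies are recomputed.
#' @param trainingMeta optional named list stored in the ensemble.
#' @return A \linkS4class{FilterEnsemble}.
#' @export
assembleEnsemble <- function(runs, cfg, actives, inactives,
                             trainingMeta = list()) {
    pool <- if (length(runs) && is(runs[[1]], "RangeFilter")) runs
            else unlist(runs, recursive = FALSE)
    if (!length(pool)) stop("no filters to assemble")
    pool <- lapply(pool, function(f) {
        f@efficiency <- filterEfficiency(f, actives, inactives)
        f
    })
    mcc <- vapply(pool, function(f) f@efficiency@mcc, numeric(1))
    pool <- pool[mcc >= cfg@mccFloor]
    if (!length(pool))
        stop("no filter reached the MCC admission floor (", cfg@mccFloor,
             "); consider lowering mccFloor")
    keys <- vapply(pool, .filterKey, character(1), digits = 9)
    pool <- pool[!duplicated(keys)]
    mcc <- vapply(pool, function(f) f@efficiency@mcc, numeric(1))
    ncond <- vapply(pool, function(f) nrow(f@conditions), integer(1))
    nameKey <- vapply(pool, function(f)
        paste(sort(f@conditions$descriptor), collapse = "|"), character(1))
    o <- order(-mcc, ncond, nameKey)
    pool <- pool[utils::head(o, cfg@maxEnsemble)]
    meta <- utils::modifyList(
        list(n_active_train = nrow(descriptorValues(actives)),
             n_inactive_train = nrow(descriptorValues(inactives)),
             mcc_floor = cfg@mccFloor, seed = cfg@seed,
             penalty_mode = "nna_over_na"),
        trainingMeta)
    FilterEnsemble(pool, descriptorPool = descriptorNames(actives),
                   trainingMeta = meta)
}

#' Train a filter ensemble end to end
#'
#' Convenience pipeline: stratified split of each class table into training
#' and held-out test portions, \code{restarts} independent
#' \code{\link{iseOptimize}} runs on the training portion (run r uses seed
#' \code{cfg@seed + r}), and \code{\link{assembleEnsemble}} over the pooled
#' filters. The held-out tables are returned for evaluation and are never
#' touched by the optimizer.
#'
#' @param actives,inactives \linkS4class{DescriptorTable}s of the two
#'   classes (full data; the split happens inside).
#' @param cfg an \linkS4class{IseConfig}.
#' @param trainFrac training fraction (default 2/3).
#' @param nTopPerRun filters kept from each run before pooling.
#' @param verbose log progress.
#' @return A list: \code{ensemble} (a \linkS4class{FilterEnsemble}),
#'   \code{test} (list of held-out actives/inactives tables) and
#'   \code{split} (the index sets).
#' @export
trainEnsemble <- function(actives, inactives, cfg = iseConfig(),
                          trainFrac = 2 / 3, nTopPerRun = 10L,
                          verbose = FALSE) {
    spA <- splitTrainTest(rep("active", nrow(descriptorValues(actives))),
                          trainFrac, seed = cfg@seed)
    spI <- splitTrainTest(rep("inactive", nrow(descriptorValues(inactives))),
                          trainFrac, seed = cfg@seed + 1L)
    trA <- actives[spA$train, ]; teA <- actives[spA$test, ]
    trI <- inactives[spI$train, ]; teI <- inactives[spI$test, ]
    runs <- vector("list", cfg@restarts)
    for (r in seq_len(cfg@restarts)) {
        cfgR <- cfg; cfgR@seed <- cfg@seed + r
        runs[[r]] <- iseOptimize(trA, trI, cfgR, nTop = nTopPerRun)
        if (verbose)
            message(sprintf("restart %d/%d: best MCC %.3f", r, cfg@restarts,
                            runs[[r]][[1]]@efficiency@mcc))
    }
    ens <- assembleEnsemble(runs, cfg, trA, trI,
        trainingMeta = list(train_frac = trainFrac,
                            restarts = cfg@restarts,
                            config = .configSnapshot(cfg)))
    list(ensemble = ens, test = list(actives = teA, inactives = teI),
         split = list(actives = spA, inactives = spI))
}

.configSnapshot <- function(cfg) {
    list(filterSize = cfg@filterSize, lowerGrid = cfg@lowerGrid,
         upperGrid = cfg@upperGrid, sampleSize = cfg@sampleSize,
         elimFraction = cfg@elimFraction, topFraction = cfg@topFraction,
         exhaustiveLimit = cfg@exhaustiveLimit, restarts = cfg@restarts,
         mccFloor = cfg@mccFloor, maxEnsemble = cfg@maxEnsemble,
         seed = cfg@seed)
}
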