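test_that("ROC sweep covers the canonical cases", {
    # perfect separation
    r <- rocAuc(c(5, 4, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(r$auc, 1)
    # all scores tied: chance level
    expect_equal(rocAuc(rep(1, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
    # actives {3, 1}, inactives {2, 0}: 3 of 4 pairs won
    expect_equal(rocAuc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc,
                 0.75)
    # curve endpoints and monotonicity
    expect_equal(unlist(r$roc[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$roc[nrow(r$roc), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
    expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("sweep AUC equals the pairwise Mann-Whitney probability", {
    set.seed(14)
    for (i in 1:10) {
        n <- sample(20:200, 1)
        y <- runif(n) < 0.3
        if (!any(y) || all(y)) next
        s <- round(rnorm(n), sample(0:1, 1))  # rounding forces ties
        # brute-force over all active/inactive pairs, ties half-credited
        a <- s[y]; b <- s[!y]
        cmp <- outer(a, b, function(x, z) (x > z) + 0.5 * (x == z))
        expect_equal(rocAuc(s, y)$auc, mean(cmp), tolerance = 1e-12)
    }
})

test_that("sweep AUC agrees with pROC on a random instance", {
    set.seed(5)
    y <- rep(c(TRUE, FALSE), c(40, 160))
    s <- rnorm(200) + y
    ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("enrichment factor reproduces the capture arithmetic", {
    # 65% of actives captured in the top 1% -> 65-fold
    N <- 10000; nAct <- 100
    y <- rep(FALSE, N)
    actIdx <- c(1:65, seq(5000, by = 50, length.out = 35))
    y[actIdx] <- TRUE
    s <- seq(N, 1)                    # rank i has score N - i + 1
    expect_equal(enrichmentFactor(s, y, 0.01), 65)

    # perfect model on a 1:1000 mix: every active fits in the top 1%
    y <- rep(c(TRUE, FALSE), c(10, 10000))
    s <- seq(length(y), 1)
    expect_equal(enrichmentFactor(s, y, 0.01), 100, tolerance = 0.01)

    # EF at the full ranking is exactly 1
    set.seed(3)
    s <- rnorm(500); y <- runif(500) < 0.2
    expect_equal(enrichmentFactor(s, y, 1), 1)
    expect_error(enrichmentFactor(s, rep(FALSE, 500), 0.1), "no actives")
})

test_that("random scores give unit enrichment in expectation", {
    set.seed(77)
    N <- 200; y <- rep(c(TRUE, FALSE), c(20, 180))
    efs <- replicate(1000, enrichmentFactor(runif(N), y, 0.05))
    expect_lt(abs(mean(efs) - 1), 0.1)
})

test_that("ties across the cutoff are attributed fractionally", {
    # 4 molecules tied at the cutoff score, 2 of them active; the top-2
    # cut takes 2/4 of the block's actives
    s <- c(9, 5, 5, 5, 5, 1)
    y <- c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
    got <- enrichmentFactor(s, y, 2 / 6)
    # captured = (0 above block) + 1 slot * (2 actives / 4 in block) = 0.5
    # fraction of actives = 0.5 / 2 = 0.25; EF = 0.25 / (1/3) = 0.75
    expect_equal(got, 0.75)
})

test_that("the MCC-threshold curve has the expected extremes and gap behavior", {
    s <- c(10, 9, 8, 2, 1, 0)
    y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    curve <- mccThresholdCurve(s, y)
    lowest <- curve[1, ]
    expect_equal(lowest$tp_pct, 100); expect_equal(lowest$fp_pct, 100)
    expect_equal(lowest$mcc, 0)
    top <- curve[curve$threshold > 9.99, ][1, ]
    expect_equal(top$tp_pct, 100 / 3, tolerance = 1e-9)
    # every threshold inside the clean gap classifies perfectly
    gap <- curve[curve$threshold > 2 & curve$threshold < 8, ]
    expect_gt(nrow(gap), 0)
    expect_true(all(gap$mcc == 1))
    # above the maximum nothing passes
    hi <- mccThresholdCurve(c(s, 11), c(y, FALSE))
    last <- hi[nrow(hi), ]
    expect_equal(last$tp_pct, 0)
})

test_that("descriptor enrichment reconstructs count/expected ratios", {
    # ensemble geometry: 47 filters x 4 condition slots over a pool of
    # 186 descriptors; expected appearances per descriptor = 188/186
    counts <- c(GCUT_SLOGP_0 = 24, a_ICM = 16, `PEOE_VSA+4` = 12,
                SMR_VSA1 = 10, logS = 9, Nmol = 9, lip_druglike = 9,
                Chi1_C = 8, GCUT_PEOE_0 = 8, opr_leadlike = 7,
                Q_VSA_FPOS = 7, SMR_VSA3 = 7, a_don = 6, a_hyd = 6)
    filler <- stats::setNames(rep(5, 10), sprintf("filler%02d", 1:10))
    slots <- c(counts, filler)          # 138 + 50 = 188 slots
    expect_equal(sum(slots), 47 * 4)

    # round-robin assignment of slots to filters, highest remaining
    # count first, so no filter repeats a descriptor
    remaining <- slots
    filterDescs <- vector("list", 47)
    for (f in 1:47) {
        pick <- names(sort(remaining, decreasing = TRUE))[1:4]
        filterDescs[[f]] <- pick
        remaining[pick] <- remaining[pick] - 1
    }
    expect_true(all(remaining == 0))
    fl <- lapply(seq_along(filterDescs), function(f)
        rangeFilter(filterDescs[[f]], low = rep(f, 4), high = rep(f + 1, 4),
                    efficiency = FilterEfficiency(pa = 90, pna = 10)))
    pool <- c(names(slots), sprintf("unused%03d", 1:(186 - length(slots))))
    ens <- FilterEnsemble(fl, pool)

    enr <- descriptorEnrichment(ens, poolSize = 186)
    got <- stats::setNames(enr$ratio_rounded, enr$descriptor)
    published <- c(`24` = 23.7, `16` = 15.8, `12` = 11.9, `10` = 9.9,
                   `9` = 8.9, `8` = 7.9, `7` = 6.9, `6` = 5.9)
    for (cnt in names(published)) {
        ds <- names(counts)[counts == as.integer(cnt)]
        expect_true(all(got[ds] == published[[cnt]]))
    }

    # pool size equal to the slot count makes the ratio the raw count
    enr1 <- descriptorEnrichment(ens, poolSize = 188)
    expect_equal(enr1$ratio, enr1$count)
    expect_error(descriptorEnrichment(ens, poolSize = 3), "smaller")
})

test_that("the evaluation report bundles all statistics coherently", {
    set.seed(21)
    y <- rep(c(TRUE, FALSE), c(30, 300))
    s <- rnorm(330) + 2 * y
    rep <- evaluationReport(s, y)
    expect_true(rep$auc > 0.5 && rep$auc <= 1)
    expect_equal(rep$enrichment_curve$ef[nrow(rep$enrichment_curve)], 1)
    expect_true(all(c("top_0.01", "top_0.1") %in% names(rep$ef_at)))
})
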