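mkFps <- function(bits, scheme = "test-4") {
    new("FingerprintSet", bits = bits, scheme = scheme)
}

test_that("tanimoto follows set arithmetic with the all-zero convention", {
    expect_equal(tanimoto(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)), 1)
    expect_equal(tanimoto(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
    expect_equal(tanimoto(c(TRUE, TRUE, FALSE, FALSE),
                          c(TRUE, FALSE, TRUE, FALSE)), 1 / 3)
    expect_equal(tanimoto(rep(FALSE, 4), rep(FALSE, 4)), 1)
    expect_error(tanimoto(c(TRUE, TRUE), c(TRUE, TRUE, FALSE)), "lengths")
})

test_that("tanimoto is symmetric and 1 only for identical non-empty fingerprints", {
    set.seed(3)
    for (i in 1:25) {
        a <- runif(16) > 0.5; b <- runif(16) > 0.5
        expect_identical(tanimoto(a, b), tanimoto(b, a))
        if (any(a | b))
            expect_identical(tanimoto(a, b) == 1, identical(a, b))
    }
})

test_that("fingerprint schemes are enforced and match an external implementation", {
    fps <- fingerprints(DRUG_SMILES[1:4])
    expect_identical(fpScheme(fps), "OB-FP2-1024")
    other <- new("FingerprintSet", bits = fps@bits, scheme = "other-1024")
    expect_error(tanimoto(fps[1], other[2]), "schemes differ")

    # cross-check our bit arithmetic against ChemmineR::fpSim
    fpset <- ChemmineR::fingerprintOB(
        suppressWarnings(ChemmineR::smiles2sdf(DRUG_SMILES[1:4])), "FP2")
    for (i in 2:4) {
        ours <- tanimoto(fps@bits[1, ], fps@bits[i, ])
        ref <- ChemmineR::fpSim(fpset[[1]], fpset[[i]], method = "Tanimoto",
                                addone = 0)
        expect_equal(ours, unname(ref))
    }
})

test_that("diversity profile matches a direct pairwise loop", {
    bits <- rbind(a = c(TRUE, TRUE, FALSE, FALSE),
                  b = c(TRUE, FALSE, TRUE, FALSE),
                  c = c(FALSE, FALSE, TRUE, TRUE),
                  d = c(TRUE, TRUE, TRUE, TRUE))
    fps <- mkFps(bits)
    prof <- diversityProfile(fps)
    # oracle: direct double loop
    sims <- c()
    for (i in 1:3) for (j in (i + 1):4)
        sims <- c(sims, tanimoto(bits[i, ], bits[j, ]))
    expect_equal(prof$n_pairs, 6)
    expect_equal(sum(prof$histogram$fraction), 1)
    expect_equal(unname(prof$below["below_0.7"]), mean(sims < 0.7))
    expect_equal(unname(prof$below["below_0.9"]), mean(sims < 0.9))

    # three identical molecules: every pair at similarity 1
    same <- mkFps(matrix(rep(c(TRUE, FALSE, TRUE, FALSE), 3), 3, 4,
                         byrow = TRUE,
                         dimnames = list(c("x", "y", "z"), NULL)))
    prof <- diversityProfile(same)
    expect_equal(prof$histogram$fraction[10], 1)   # all pairs in top bin
    expect_equal(unname(prof$below["below_0.9"]), 0)

    # two disjoint molecules: fraction below 0.7 is 1
    dis <- mkFps(rbind(p = c(TRUE, TRUE, FALSE, FALSE),
                       q = c(FALSE, FALSE, TRUE, TRUE)))
    expect_equal(unname(diversityProfile(dis)$below["below_0.7"]), 1)

    expect_error(diversityProfile(mkFps(bits[1, , drop = FALSE])),
                 "at least two")
})

test_that("greedy similarity pruning keeps the first of each similar group", {
    # two identical molecules: first kept, second removed
    bits <- rbind(m1 = c(TRUE, TRUE, FALSE), m2 = c(TRUE, TRUE, FALSE))
    expect_identical(pruneSimilar(mkFps(bits), 0.9), "m1")

    # an already-diverse set passes through unchanged
    div <- rbind(a = c(TRUE, FALSE, FALSE, FALSE),
                 b = c(FALSE, TRUE, FALSE, FALSE),
                 c = c(FALSE, FALSE, TRUE, FALSE))
    expect_identical(pruneSimilar(mkFps(div), 0.5), c("a", "b", "c"))
    # and the output is threshold-invariant for diverse sets
    expect_identical(pruneSimilar(mkFps(div), 0.9),
                     pruneSimilar(mkFps(div), 0.2))

    # chain instance: B is over-threshold similar to A (removed), C is
    # over-threshold similar to the REMOVED B but under threshold to the
    # kept A, so the greedy pass keeps {A, C}. (Tanimoto distance is a
    # metric, so A~C cannot be pushed arbitrarily low while A~B and B~C
    # stay above 0.9.)
    A <- seq_len(40) %in% 1:20
    B <- seq_len(40) %in% c(1:19, 21)
    C <- seq_len(40) %in% c(2:19, 21, 22)
    expect_equal(tanimoto(A, B), 19 / 21)   # 0.905 >= 0.9
    expect_equal(tanimoto(B, C), 19 / 21)   # 0.905 >= 0.9
    expect_lt(tanimoto(A, C), 0.9)          # 18/22 = 0.818
    chain <- mkFps(rbind(A = A, B = B, C = C))
    expect_identical(pruneSimilar(chain, 0.9), c("A", "C"))
})

test_that("rule profiles count Lipinski and Oprea violations independently", {
    p <- ruleProfile(c(MW = 600, logP = 6, HBD = 6, HBA = 11, rings = 1,
                       rot = 2))
    expect_identical(p$lipinski_violations, 4L)
    expect_false(p$passes_lipinski)

    p <- ruleProfile(c(MW = 180, logP = 1.2, HBD = 1, HBA = 4, rings = 1,
                       rot = 3))
    expect_identical(p$lipinski_violations, 0L)
    expect_identical(p$oprea_violations, 0L)
    expect_true(p$passes_lipinski && p$passes_oprea)

    # between the two rule boxes: drug-like but not lead-like
    p <- ruleProfile(c(MW = 460, logP = 4.0, HBD = 2, HBA = 6, rings = 2,
                       rot = 5))
    expect_true(p$passes_lipinski)
    expect_false(p$passes_oprea)
    expect_identical(p$oprea_violations, 1L)

    expect_error(ruleProfile(c(MW = 100, logP = 1)), "donor")
})

test_that("violation counts are monotone in molecular weight", {
    base <- c(logP = 2, HBD = 2, HBA = 5, rings = 2, rot = 4)
    prev <- c(0L, 0L)
    for (mw in seq(100, 900, by = 100)) {
        p <- ruleProfile(c(MW = mw, base))
        expect_gte(p$lipinski_violations, prev[1])
        expect_gte(p$oprea_violations, prev[2])
        prev <- c(p$lipinski_violations, p$oprea_violations)
    }
})

test_that("rule table profiles computed descriptors end to end", {
    tab <- computeDescriptors(DRUG_SMILES,
        names = c("MW", "logP", "lip_don", "lip_acc", "rings", "b_rotN"))
    rt <- ruleTable(tab)
    expect_identical(nrow(rt), length(DRUG_SMILES))
    expect_true(rt$passes_lipinski[rt$id == "aspirin"])
    expect_true(all(rt$lipinski_violations >= 0 &
                    rt$lipinski_violations <= 4))
})
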