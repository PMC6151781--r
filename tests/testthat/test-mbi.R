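mkEns <- function(rates, nAct = 100, nInact = 1000) {
    fl <- lapply(seq_len(nrow(rates)), function(i)
        rangeFilter(sprintf("d%d", i), i, i + 1,
            efficiency = FilterEfficiency(pa = rates$pa[i],
                                          pna = rates$pna[i])))
    FilterEnsemble(fl, sprintf("d%d", seq_len(nrow(rates))),
                   trainingMeta = list(n_active_train = nAct,
                                       n_inactive_train = nInact,
                                       penalty_mode = "nna_over_na"))
}

test_that("the index formula matches hand-worked examples exactly", {
    # single filter, molecule passes: reward PA/PNA = 50/5
    expect_equal(mbiFromRates(TRUE, pa = 50, pna = 5, na = 20, nna = 80),
                 10, tolerance = 1e-12)
    # same filter, molecule fails, default penalty NNA/NA = 80/20
    expect_equal(mbiFromRates(FALSE, pa = 50, pna = 5, na = 20, nna = 80),
                 -4, tolerance = 1e-12)
    # two filters, pass A fail B: (60/3 - 75/25) / 2
    expect_equal(mbiFromRates(c(TRUE, FALSE), pa = c(60, 40),
                              pna = c(3, 10), na = c(10, 25),
                              nna = c(90, 75)),
                 8.5, tolerance = 1e-12)
})

test_that("penalty orientation sets the score floor scale", {
    # three filters with the published example TP/TN rates; a molecule
    # failing everything sits at the score floor
    rates <- data.frame(pa = c(86.59, 62.88, 81.4),
                        pna = 100 - c(77.42, 97.23, 82.3))
    ens <- mkEns(rates)
    row <- c(d1 = -10, d2 = -10, d3 = -10)   # fails every filter
    floorDefault <- mbiScore(ens, row, penaltyMode = "nna_over_na")$mbi
    floorText <- mbiScore(ens, row, penaltyMode = "na_over_nna")$mbi
    # default orientation: floor of magnitude ~4 (like the published range)
    expect_lt(abs(floorDefault - (-4)), 0.5)
    # text orientation: an order of magnitude smaller
    expect_lt(abs(floorText), 0.5)
    expect_gt(abs(floorDefault / floorText), 5)
})

test_that("scores move monotonically when a filter flips to pass", {
    rates <- data.frame(pa = c(70, 80, 60), pna = c(10, 20, 5))
    ens <- mkEns(rates)
    failAll <- c(d1 = -1, d2 = -1, d3 = -1)
    passOne <- c(d1 = 1.5, d2 = -1, d3 = -1)
    passTwo <- c(d1 = 1.5, d2 = 2.5, d3 = -1)
    s0 <- mbiScore(ens, failAll)$mbi
    s1 <- mbiScore(ens, passOne)$mbi
    s2 <- mbiScore(ens, passTwo)$mbi
    expect_lt(s0, s1); expect_lt(s1, s2)
    expect_identical(mbiScore(ens, passOne)$nPassed, 1L)
})

test_that("MBI is bounded by the extreme per-filter terms", {
    rates <- data.frame(pa = c(90, 50, 75), pna = c(5, 25, 2))
    ens <- mkEns(rates)
    rewards <- rates$pa / rates$pna
    penalties <- (100 - rates$pna) / (100 - rates$pa)
    set.seed(31)
    for (i in 1:30) {
        row <- stats::setNames(runif(3, -2, 5), c("d1", "d2", "d3"))
        s <- mbiScore(ens, row)$mbi
        expect_gte(s, min(-penalties))
        expect_lte(s, max(rewards))
    }
})

test_that("zero rates fall back to half-count pseudocount denominators", {
    ens <- mkEns(data.frame(pa = 100, pna = 0), nAct = 50, nInact = 500)
    # PNA = 0: reward uses 100 * 0.5 / 500 = 0.1 in the denominator
    s <- mbiScore(ens, c(d1 = 1.5))
    expect_equal(s$mbi, 100 / 0.1)
    # NA = 0 (PA = 100): default penalty uses 100 * 0.5 / 50 = 1
    s <- mbiScore(ens, c(d1 = -5))
    expect_equal(s$mbi, -100 / 1)
})

test_that("missing descriptors are reported by name when scoring", {
    ens <- mkEns(data.frame(pa = 80, pna = 10))
    expect_error(mbiScore(ens, c(other = 1)), "d1")
})

test_that("set scoring ranks molecules reproducibly with stable ties", {
    rates <- data.frame(pa = c(80, 70), pna = c(10, 10))
    ens <- mkEns(rates)
    vals <- rbind(zz = c(1.5, 2.5), aa = c(1.5, 2.5), mid = c(1.5, -1),
                  low = c(-1, -1))
    colnames(vals) <- c("d1", "d2")
    res <- scoreSet(ens, DescriptorTable(vals))
    df <- mbiScores(res)
    # pass-all molecules first, tie broken by id; fail-all last
    expect_identical(df$id, c("aa", "zz", "mid", "low"))
    expect_identical(df$n_passed, c(2L, 2L, 1L, 0L))
    expect_true(all(diff(df$mbi) <= 0))
    # pass vector rendered per filter
    expect_identical(as.data.frame(res)$pass_vector,
                     c("11", "11", "10", "00"))

    # empty table gives an empty result
    empty <- DescriptorTable(matrix(numeric(0), 0, 2,
        dimnames = list(NULL, c("d1", "d2"))))
    expect_length(moleculeIds(scoreSet(ens, empty)), 0)
})

test_that("passing a superset of filters never scores lower", {
    rates <- data.frame(pa = c(80, 70, 90), pna = c(10, 15, 5))
    ens <- mkEns(rates)
    sub <- c(d1 = 1.5, d2 = -1, d3 = 3.5)     # passes 1 and 3
    super <- c(d1 = 1.5, d2 = 2.5, d3 = 3.5)  # passes all
    expect_gt(mbiScore(ens, super)$mbi, mbiScore(ens, sub)$mbi)
})
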