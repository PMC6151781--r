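test_that("stratified split sizes follow round-half-up and are deterministic", {
    sp <- splitTrainTest(rep("active", 97), trainFrac = 0.667, seed = 1)
    expect_length(sp$train, 65)
    expect_length(sp$test, 32)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), 1:97)

    # half of four is exactly two whatever the seed
    for (s in 1:5) {
        sp <- splitTrainTest(rep("x", 4), trainFrac = 0.5, seed = s)
        expect_length(sp$train, 2)
    }

    # same seed, same partition; stratification is per class
    lab <- c(rep("active", 10), rep("inactive", 30))
    a <- splitTrainTest(lab, 2 / 3, seed = 7)
    b <- splitTrainTest(lab, 2 / 3, seed = 7)
    expect_identical(a, b)
    expect_length(intersect(a$train, 1:10), 7)     # 6.67 -> 7
    expect_length(intersect(a$train, 11:40), 20)

    expect_error(splitTrainTest(c("a", "b", "b"), 0.5, 1), "fewer than 2")
    expect_error(splitTrainTest(rep("a", 10), 1.2, 1), "trainFrac")
})

test_that("candidate ranges are active-class percentile pairs", {
    cfg <- iseConfig()
    act <- DescriptorTable(matrix(as.numeric(1:100), 100, 1,
        dimnames = list(sprintf("m%03d", 1:100), "x")))
    cr <- candidateRanges(act, cfg)$x
    expect_lte(nrow(cr), 25)                      # 5 x 5 grid, deduplicated
    expect_true(all(cr$low <= cr$high))
    # full-range pair covers the observed extremes
    expect_true(any(cr$low == 1 & cr$high == 100))

    # empirical-percentile oracle at n = 10000 on a uniform sample
    set.seed(2)
    u <- DescriptorTable(matrix(runif(10000), ncol = 1,
        dimnames = list(sprintf("m%05d", 1:10000), "u")))
    cr <- candidateRanges(u, cfg)$u
    expect_true(any(abs(cr$low - 0.25) < 0.02 & abs(cr$high - 0.75) < 0.02))

    # constant descriptor: single degenerate candidate
    const <- DescriptorTable(matrix(c(5, 5, 5, 1, 2, 3), 3, 2,
        dimnames = list(letters[1:3], c("c", "x"))))
    expect_identical(nrow(candidateRanges(const, cfg)$c), 1L)
    expect_equal(candidateRanges(const, cfg)$c$low, 5)
})

test_that("a perfectly separating descriptor yields an MCC-1 filter", {
    toy <- makeToyTables(seed = 4)
    cfg <- iseConfig(filterSize = 2L, seed = 3)
    fl <- iseOptimize(toy$actives, toy$inactives, cfg, nTop = 3)
    best <- efficiencyRates(efficiency(fl[[1]]))
    expect_equal(best[["MCC"]], 1)
    expect_true("sep" %in% conditions(fl[[1]])$descriptor)
})

test_that("on enumerable spaces the optimizer equals the brute-force optimum", {
    # randomized tiny instances, scored independently by a direct
    # enumeration oracle
    for (seed in 1:6) {
        set.seed(seed * 100)
        nd <- sample(3:5, 1)
        act <- matrix(runif(15 * nd), 15, nd,
                      dimnames = list(sprintf("a%02d", 1:15),
                                      sprintf("d%d", 1:nd)))
        inact <- matrix(runif(30 * nd, 0.2, 1.2), 30, nd,
                        dimnames = list(sprintf("i%02d", 1:30),
                                        sprintf("d%d", 1:nd)))
        cfg <- iseConfig(filterSize = 2L, seed = seed,
                         lowerGrid = c(0, 10, 25), upperGrid = c(75, 100))
        fl <- iseOptimize(DescriptorTable(act), DescriptorTable(inact),
                          cfg, nTop = 1)
        got <- efficiencyRates(efficiency(fl[[1]]))[["MCC"]]
        want <- bruteForceBestMCC(DescriptorTable(act),
                                  DescriptorTable(inact), cfg)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("identical config and seed reproduce the run bit for bit", {
    toy <- makeToyTables(nAct = 15, nInact = 30, nNoise = 6, seed = 5)
    cfg <- iseConfig(filterSize = 2L, seed = 9, sampleSize = 200L,
                     exhaustiveLimit = 50)
    a <- iseOptimize(toy$actives, toy$inactives, cfg, nTop = 5)
    b <- iseOptimize(toy$actives, toy$inactives, cfg, nTop = 5)
    expect_length(a, length(b))
    for (i in seq_along(a)) {
        expect_identical(conditions(a[[i]]), conditions(b[[i]]))
        expect_identical(efficiencyRates(efficiency(a[[i]])),
                         efficiencyRates(efficiency(b[[i]])))
    }
})

test_that("the elimination loop contracts spaces above the exhaustive limit", {
    toy <- makeToyTables(nAct = 20, nInact = 40, nNoise = 10, seed = 6)
    cfg <- iseConfig(filterSize = 3L, seed = 2, sampleSize = 300L,
                     exhaustiveLimit = 500)
    fl <- iseOptimize(toy$actives, toy$inactives, cfg, nTop = 3)
    expect_gte(length(fl), 1)
    expect_true(all(vapply(fl, function(f)
        efficiencyRates(efficiency(f))[["MCC"]] >= -1, logical(1))))
})

test_that("ensemble assembly deduplicates, floors and caps", {
    toy <- makeToyTables(seed = 11)
    f1 <- rangeFilter("sep", 0, 1)
    f2 <- rangeFilter("sep", 0, 1)          # identical duplicate
    f3 <- rangeFilter("noise1", 0, 10)      # uninformative, below floor
    cfg <- iseConfig(mccFloor = 0.55, maxEnsemble = 10L)
    ens <- assembleEnsemble(list(list(f1, f3), list(f2)), cfg,
                            toy$actives, toy$inactives)
    expect_identical(nFilters(ens), 1L)
    expect_gte(efficiencyRates(efficiency(filters(ens)[[1]]))[["MCC"]],
               0.55)

    # a filter under the admission floor is excluded even if unique
    cfgHigh <- iseConfig(mccFloor = 1.1)
    expect_error(assembleEnsemble(list(list(f3)), cfgHigh,
                                  toy$actives, toy$inactives),
                 "admission floor")
})

test_that("ensemble size and admission honour the configuration contract", {
    toy <- makeToyTables(nAct = 20, nInact = 40, nNoise = 5, seed = 12)
    cfg <- iseConfig(filterSize = 2L, seed = 4, restarts = 3L,
                     sampleSize = 200L, exhaustiveLimit = 2000,
                     maxEnsemble = 5L, mccFloor = 0.55)
    tr <- trainEnsemble(toy$actives, toy$inactives, cfg, nTopPerRun = 4L)
    ens <- tr$ensemble
    expect_lte(nFilters(ens), 5L)
    mccs <- vapply(filters(ens), function(f)
        efficiencyRates(efficiency(f))[["MCC"]], numeric(1))
    expect_true(all(mccs >= 0.55))
    keys <- vapply(filters(ens), iseScreen:::.filterKey, character(1))
    expect_false(anyDuplicated(keys) > 0)
    # held-out tables are disjoint from training rows
    expect_length(intersect(moleculeIds(tr$test$actives),
        moleculeIds(toy$actives)[tr$split$actives$train]), 0)
})
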