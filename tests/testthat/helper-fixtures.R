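# Shared fixtures and independent oracles, all built in code.

# a small set of well-known drug-like molecules
DRUG_SMILES <- c(
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    metformin = "CN(C)C(=N)N=C(N)N",
    naproxen = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
    glipizide = "Cc1cnc(cn1)C(=O)NCCc1ccc(cc1)S(=O)(=O)NC(=O)NC1CCCCC1",
    tolbutamide = "CCCCNC(=O)NS(=O)(=O)c1ccc(C)cc1")

writeSmiFile <- function(smiles, path = tempfile(fileext = ".smi"),
                         ids = names(smiles)) {
    writeLines(paste(smiles, ids), path)
    path
}

# labelled descriptor tables with one perfectly separating descriptor
# ("sep": actives in [0,1], inactives in [2,3]) plus uniform noise columns
makeToyTables <- function(nAct = 20, nInact = 40, nNoise = 3, seed = 42) {
    set.seed(seed)
    nm <- c("sep", sprintf("noise%d", seq_len(nNoise)))
    act <- cbind(runif(nAct), matrix(runif(nAct * nNoise, 0, 10),
                                     nAct, nNoise))
    inact <- cbind(runif(nInact, 2, 3),
                   matrix(runif(nInact * nNoise, 0, 10), nInact, nNoise))
    dimnames(act) <- list(sprintf("a%02d", seq_len(nAct)), nm)
    dimnames(inact) <- list(sprintf("i%02d", seq_len(nInact)), nm)
    list(actives = DescriptorTable(act), inactives = DescriptorTable(inact))
}

# a random trained ensemble for serialization tests
randomEnsemble <- function(nFilters = 5, seed = 1) {
    set.seed(seed)
    pool <- sprintf("desc%02d", 1:20)
    fl <- lapply(seq_len(nFilters), function(i) {
        nd <- sample(1:4, 1)
        ds <- sample(pool, nd)
        lo <- runif(nd, -5, 0); hi <- lo + runif(nd, 0, 10)
        pa <- runif(1, 50, 100); pna <- runif(1, 0, 50)
        rangeFilter(ds, lo, hi, efficiency = FilterEfficiency(pa, pna))
    })
    FilterEnsemble(fl, pool,
                   trainingMeta = list(n_active_train = 65,
                                       n_inactive_train = 1928,
                                       seed = seed,
                                       penalty_mode = "nna_over_na"))
}

ensembleEqual <- function(a, b) {
    expect_identical(descriptorPool(a), descriptorPool(b))
    expect_equal(nFilters(a), nFilters(b))
    for (i in seq_len(nFilters(a))) {
        expect_identical(conditions(filters(a)[[i]]),
                         conditions(filters(b)[[i]]))
        expect_identical(efficiencyRates(efficiency(filters(a)[[i]])),
                         efficiencyRates(efficiency(filters(b)[[i]])))
    }
}

# independent brute-force search over every k-subset of descriptors and
# every candidate-range combination, scored by direct counting
bruteForceBestMCC <- function(actives, inactives, cfg) {
    cand <- candidateRanges(actives, cfg)
    av <- descriptorValues(actives); iv <- descriptorValues(inactives)
    nm <- colnames(av)
    best <- -Inf
    for (ds in utils::combn(seq_along(nm), cfg@filterSize,
                            simplify = FALSE)) {
        grid <- as.matrix(expand.grid(lapply(ds, function(d)
            seq_len(nrow(cand[[d]])))))
        for (r in seq_len(nrow(grid))) {
            okA <- rep(TRUE, nrow(av)); okI <- rep(TRUE, nrow(iv))
            for (j in seq_along(ds)) {
                rg <- cand[[ds[j]]][grid[r, j], ]
                okA <- okA & av[, ds[j]] >= rg$low & av[, ds[j]] <= rg$high
                okI <- okI & iv[, ds[j]] >= rg$low & iv[, ds[j]] <= rg$high
            }
            tp <- mean(okA); fp <- mean(okI)
            tn <- 1 - fp; fn <- 1 - tp
            den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
            mcc <- if (den <= 0) 0 else (tp * tn - fp * fn) / sqrt(den)
            if (mcc > best) best <- mcc
        }
    }
    best
}

# path to the installed command-line script; runs it with the current
# library paths so the installed package is found
runCli <- function(args) {
    script <- system.file("cli", "isescreen.R", package = "iseScreen")
    out <- suppressWarnings(system2("Rscript", c(script, args),
                                    stdout = TRUE, stderr = TRUE,
                                    env = paste0("R_LIBS=",
                                        paste(.libPaths(), collapse = ":"))))
    list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
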