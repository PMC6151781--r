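# Internal atom-level machinery behind the descriptor registry: molecule
# graph extraction from ChemmineR SDF objects, implicit hydrogens,
# Gasteiger-Marsili partial charges, approximate per-atom van der Waals
# surface areas (Labute-style), coarse atomic logP / molar-refractivity
# contribution tables, Burden-matrix eigenvalues and topological indices.
# All of these are documented analogs of MOE-style 2D descriptors, not
# reimplementations of them.

.BONDI <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
            P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

.VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2, Cl = 1,
              Br = 1, I = 1, H = 1)

# coarse atomic contributions (heavy atom; implicit H folded in separately)
.LOGP_C <- c(C = 0.13, N = -0.60, O = -0.64, S = 0.40, P = -0.50,
             F = 0.42, Cl = 0.65, Br = 0.86, I = 1.22, B = 0.05, H = 0.12)
.LOGP_C_AROM <- c(C = 0.29, N = -0.49, O = 0.06, S = 0.42)
.MR_C <- c(C = 2.42, N = 1.85, O = 1.64, S = 7.37, P = 6.92, F = 0.95,
           Cl = 5.84, Br = 8.74, I = 13.95, B = 3.50, H = 1.03)

# Gasteiger-Marsili PEOE parameters (a, b, c) by element and hybridization
.PEOE_PARAMS <- list(
    "H"     = c(7.17, 6.24, -0.56),
    "C.3"   = c(7.98, 9.18, 1.88),
    "C.2"   = c(8.79, 9.32, 1.51),
    "C.1"   = c(10.39, 9.45, 0.73),
    "N.3"   = c(11.54, 10.82, 1.36),
    "N.2"   = c(12.87, 11.15, 0.85),
    "N.1"   = c(15.68, 11.70, -0.27),
    "O.3"   = c(14.18, 12.92, 1.39),
    "O.2"   = c(17.07, 13.79, 0.47),
    "F"     = c(14.66, 13.85, 2.31),
    "Cl"    = c(11.00, 9.69, 1.35),
    "Br"    = c(10.08, 8.47, 1.16),
    "I"     = c(9.90, 7.96, 0.96),
    "S.3"   = c(10.14, 9.13, 1.38),
    "S.2"   = c(10.88, 9.49, 1.33),
    "P.3"   = c(8.90, 8.24, 0.96))

.mdlCharge <- function(code) {
    # MDL V2000 charge codes: 0 none, 1 +3, 2 +2, 3 +1, 5 -1, 6 -2, 7 -3
    map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
             `6` = -2, `7` = -3)
    out <- map[as.character(code)]
    out[is.na(out)] <- 0
    unname(out)
}

# molecule graph context from a single-molecule SDF
.molContext <- function(sdf, smiles = "") {
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    sym <- gsub("_.*", "", rownames(ab))
    nAtoms <- length(sym)
    a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
    ord <- as.integer(bb[, 3])
    fc <- if ("C6" %in% colnames(ab)) .mdlCharge(ab[, "C6"])
          else rep(0, nAtoms)

    bondSum <- integer(nAtoms); degree <- integer(nAtoms)
    for (b in seq_along(a1)) {
        bondSum[a1[b]] <- bondSum[a1[b]] + ord[b]
        bondSum[a2[b]] <- bondSum[a2[b]] + ord[b]
        degree[a1[b]] <- degree[a1[b]] + 1L
        degree[a2[b]] <- degree[a2[b]] + 1L
    }
    val <- .VALENCE[sym]; val[is.na(val)] <- 4
    nH <- pmax(0L, as.integer(val + ifelse(sym %in% c("C", "N", "O", "P"),
                                           fc, 0) - bondSum))

    arom <- rep(FALSE, nAtoms)
    ringAtoms <- rep(FALSE, nAtoms)
    rg <- tryCatch(
        suppressWarnings(ChemmineR::rings(sdf, upper = 10, type = "all",
                                          arom = TRUE)),
        error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    if (length(rg$RINGS)) {
        for (k in seq_along(rg$RINGS)) {
            idx <- as.integer(sub(".*_", "", rg$RINGS[[k]]))
            ringAtoms[idx] <- TRUE
            if (isTRUE(rg$AROMATIC[k])) arom[idx] <- TRUE
        }
    }

    nbr <- vector("list", nAtoms)
    for (b in seq_along(a1)) {
        nbr[[a1[b]]] <- c(nbr[[a1[b]]], a2[b])
        nbr[[a2[b]]] <- c(nbr[[a2[b]]], a1[b])
    }

    list(symbols = sym, nAtoms = nAtoms, bonds = data.frame(
             a1 = a1, a2 = a2, order = ord), fc = fc, nH = nH,
         degree = degree, bondSum = bondSum, aromatic = arom,
         inRing = ringAtoms, neighbors = nbr, smiles = smiles)
}

.hybridization <- function(ctx) {
    hyb <- rep(3L, ctx$nAtoms)
    nDouble <- integer(ctx$nAtoms); nTriple <- integer(ctx$nAtoms)
    b <- ctx$bonds
    for (k in seq_len(nrow(b))) {
        if (b$order[k] == 2L) {
            nDouble[b$a1[k]] <- nDouble[b$a1[k]] + 1L
            nDouble[b$a2[k]] <- nDouble[b$a2[k]] + 1L
        } else if (b$order[k] == 3L) {
            nTriple[b$a1[k]] <- nTriple[b$a1[k]] + 1L
            nTriple[b$a2[k]] <- nTriple[b$a2[k]] + 1L
        }
    }
    hyb[nDouble >= 1L | ctx$aromatic] <- 2L
    hyb[nTriple >= 1L | nDouble >= 2L] <- 1L
    hyb
}

# iterative partial equalization of orbital electronegativity; returns
# heavy-atom charges with implicit-hydrogen charges folded in
.gasteigerCharges <- function(ctx, iterations = 8L) {
    hyb <- .hybridization(ctx)
    key <- ifelse(ctx$symbols %in% c("C", "N", "O", "S", "P"),
                  paste0(ctx$symbols, ".", hyb), ctx$symbols)
    par <- lapply(key, function(k) {
        p <- .PEOE_PARAMS[[k]]
        if (is.null(p)) p <- .PEOE_PARAMS[["C.3"]]
        p
    })
    hPar <- .PEOE_PARAMS[["H"]]
    q <- as.numeric(ctx$fc)       # start from formal charges
    qH <- lapply(ctx$nH, function(n) rep(0, n))
    chiPlus <- vapply(par, sum, numeric(1))
    chiPlusH <- sum(hPar)
    damp <- 1
    for (t in seq_len(iterations)) {
        damp <- damp * 0.5
        chi <- vapply(seq_along(par), function(i) {
            p <- par[[i]]; p[1] + p[2] * q[i] + p[3] * q[i]^2
        }, numeric(1))
        chiH <- lapply(seq_along(qH), function(i)
            hPar[1] + hPar[2] * qH[[i]] + hPar[3] * qH[[i]]^2)
        dq <- rep(0, ctx$nAtoms)
        b <- ctx$bonds
        for (k in seq_len(nrow(b))) {
            i <- b$a1[k]; j <- b$a2[k]
            d <- if (chi[j] > chi[i]) chiPlus[i] else chiPlus[j]
            tr <- (chi[j] - chi[i]) / d * damp
            dq[i] <- dq[i] + tr
            dq[j] <- dq[j] - tr
        }
        for (i in seq_along(qH)) {
            if (!ctx$nH[i]) next
            for (h in seq_len(ctx$nH[i])) {
                d <- if (chiH[[i]][h] > chi[i]) chiPlus[i] else chiPlusH
                tr <- (chiH[[i]][h] - chi[i]) / d * damp
                dq[i] <- dq[i] + tr
                qH[[i]][h] <- qH[[i]][h] - tr
            }
        }
        q <- q + dq
    }
    q + vapply(qH, sum, numeric(1))
}

# approximate per-heavy-atom accessible van der Waals surface area
.atomVSA <- function(ctx) {
    r <- .BONDI[ctx$symbols]; r[is.na(r)] <- 1.70
    vapply(seq_len(ctx$nAtoms), function(i) {
        area <- 4 * pi * r[i]^2
        caps <- 0
        for (j in ctx$neighbors[[i]]) {
            d <- 0.85 * (r[i] + r[j])
            d <- max(abs(r[i] - r[j]) + 0.01, min(d, r[i] + r[j] - 0.01))
            h <- r[i] - (d^2 + r[i]^2 - r[j]^2) / (2 * d)
            if (h > 0) caps <- caps + 2 * pi * r[i] * h
        }
        if (ctx$nH[i] > 0) {
            rh <- .BONDI[["H"]]
            d <- 0.85 * (r[i] + rh)
            h <- r[i] - (d^2 + r[i]^2 - rh^2) / (2 * d)
            if (h > 0) caps <- caps + ctx$nH[i] * 2 * pi * r[i] * h
        }
        max(0, area - caps)
    }, numeric(1))
}

# per-heavy-atom logP and MR contributions, implicit H folded in
.atomLogP <- function(ctx) {
    base <- .LOGP_C[ctx$symbols]; base[is.na(base)] <- 0
    aromAdj <- .LOGP_C_AROM[ctx$symbols]
    use <- ctx$aromatic & !is.na(aromAdj)
    base[use] <- aromAdj[use]
    unname(base + ctx$nH * .LOGP_C[["H"]])
}

.atomMR <- function(ctx) {
    base <- .MR_C[ctx$symbols]; base[is.na(base)] <- 2.0
    unname(base + ctx$nH * .MR_C[["H"]])
}

# all-pairs topological distances by repeated BFS (heavy atoms)
.graphDistances <- function(ctx) {
    n <- ctx$nAtoms
    D <- matrix(Inf, n, n)
    diag(D) <- 0
    for (s in seq_len(n)) {
        frontier <- s; d <- 0
        while (length(frontier)) {
            d <- d + 1
            nxt <- unique(unlist(ctx$neighbors[frontier]))
            nxt <- nxt[D[s, nxt] == Inf]
            if (!length(nxt)) break
            D[s, nxt] <- d
            frontier <- nxt
        }
    }
    D
}

.nComponents <- function(ctx) {
    n <- ctx$nAtoms
    seen <- rep(FALSE, n); comp <- 0L
    for (s in seq_len(n)) {
        if (seen[s]) next
        comp <- comp + 1L
        frontier <- s; seen[s] <- TRUE
        while (length(frontier)) {
            nxt <- unique(unlist(ctx$neighbors[frontier]))
            nxt <- nxt[!seen[nxt]]
            seen[nxt] <- TRUE
            frontier <- nxt
        }
    }
    comp
}

# Burden-style eigenvalue summaries: diagonal = atomic property,
# off-diagonal 0.1 * bond order for bonded pairs, 0.001 otherwise
.bcutValues <- function(ctx, prop) {
    n <- ctx$nAtoms
    if (n == 1L) return(rep(prop[1], 4))
    B <- matrix(0.001, n, n)
    b <- ctx$bonds
    for (k in seq_len(nrow(b))) {
        v <- 0.1 * b$order[k]
        B[b$a1[k], b$a2[k]] <- v
        B[b$a2[k], b$a1[k]] <- v
    }
    diag(B) <- prop
    ev <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
    stats::quantile(ev, probs = c(0, 1 / 3, 2 / 3, 1), names = FALSE)
}

# graph-distance variant: off-diagonal 1 / d^2
.gcutValues <- function(ctx, prop) {
    n <- ctx$nAtoms
    if (n == 1L) return(rep(prop[1], 4))
    D <- .graphDistances(ctx)
    G <- 1 / pmax(D, 1)^2
    G[!is.finite(G)] <- 0
    diag(G) <- prop
    ev <- sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    stats::quantile(ev, probs = c(0, 1 / 3, 2 / 3, 1), names = FALSE)
}

.chiIndices <- function(ctx) {
    d <- ctx$degree
    carbons <- ctx$symbols == "C"
    chi0 <- sum(1 / sqrt(d[d > 0]))
    chi0c <- sum(1 / sqrt(d[d > 0 & carbons]))
    b <- ctx$bonds
    dd <- d[b$a1] * d[b$a2]
    chi1 <- sum(1 / sqrt(dd[dd > 0]))
    cc <- carbons[b$a1] & carbons[b$a2]
    chi1c <- sum(1 / sqrt(dd[dd > 0 & cc]))
    c(Chi0 = chi0, Chi1 = chi1, Chi0_C = chi0c, Chi1_C = chi1c)
}

# entropy (bits) of the element distribution over heavy atoms + implicit H
.atomInfoContent <- function(ctx) {
    counts <- c(table(ctx$symbols), H = sum(ctx$nH))
    counts <- counts[counts > 0]
    p <- counts / sum(counts)
    -sum(p * log2(p))
}

# potential tetrahedral stereocenters: carbon with four distinct one-bond
# substituent signatures (implicit H counted as a substituent)
.chiralCount <- function(ctx) {
    sig <- vapply(seq_len(ctx$nAtoms), function(i)
        paste(ctx$symbols[i], ctx$degree[i], ctx$nH[i], sep = "."),
        character(1))
    n <- 0L
    for (i in seq_len(ctx$nAtoms)) {
        if (ctx$symbols[i] != "C") next
        subst <- c(sig[ctx$neighbors[[i]]], rep("H", ctx$nH[i]))
        if (length(subst) == 4L && !anyDuplicated(subst))
            n <- n + 1L
    }
    n
}
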